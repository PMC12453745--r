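shit
fuck
fucking
fucked
damn
damned
dammit
hell
crap
bastard
bitch
asshole
ass
piss
pissed
bullshit
goddamn
screwed
sucks
wtf
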