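token,synonym
sad,blue
unhappy,down
tired,weary
hopeless,despairing
depressed,dejected
miserable,wretched
lonely,isolated
empty,hollow
worthless,useless
exhausted,drained
anxious,nervous
crying,weeping
pain,ache
dark,gloomy
broken,shattered
happy,glad
love,adore
great,terrific
wonderful,marvelous
excited,thrilled
joy,delight
fun,enjoyable
beautiful,gorgeous
grateful,thankful
hopeful,optimistic
calm,relaxed
proud,pleased
smile,grin
friend,buddy
sunny,bright
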