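token,class,prob
abandon,0,0.85
abuse,0,0.9
ache,1,0.75
afraid,1,0.8
agony,0,0.92
alone,1,0.8
amazing,4,0.9
angry,1,0.85
anguish,0,0.9
annoy,1,0.7
anxious,1,0.85
appreciate,3,0.8
awesome,4,0.9
awful,0,0.9
bad,1,0.8
beautiful,4,0.85
best,4,0.9
better,3,0.7
bitter,1,0.75
bless,3,0.8
blue,1,0.6
bored,1,0.65
breakdown,0,0.85
bright,3,0.7
broken,0,0.85
brilliant,4,0.88
burden,1,0.8
calm,3,0.7
care,3,0.7
celebrate,4,0.85
cheer,3,0.8
cherish,4,0.8
comfort,3,0.75
confident,3,0.8
confused,1,0.6
content,3,0.7
crap,1,0.8
crash,1,0.6
crazy,1,0.6
cried,0,0.85
cry,0,0.85
crying,0,0.88
cursed,0,0.8
cut,1,0.6
damn,1,0.75
dark,1,0.7
dead,0,0.9
death,0,0.9
defeated,0,0.85
delight,4,0.88
depressed,0,0.95
depression,0,0.95
despair,0,0.92
destroyed,0,0.85
devastated,0,0.9
diagnose,1,0.6
die,0,0.9
disappointed,1,0.8
disaster,0,0.85
disgust,0,0.8
distress,0,0.85
down,1,0.6
drained,1,0.75
dread,0,0.85
dream,3,0.6
dull,1,0.6
dying,0,0.9
easy,3,0.6
ecstatic,4,0.9
embarrassed,1,0.7
empty,0,0.82
encourage,3,0.8
energetic,3,0.75
enjoy,3,0.85
excellent,4,0.92
excited,4,0.85
exhausted,1,0.8
fail,0,0.8
failure,0,0.88
fantastic,4,0.9
fear,1,0.8
fine,3,0.55
fought,1,0.6
free,3,0.65
fresh,3,0.6
friend,3,0.65
fuck,1,0.8
fun,3,0.85
glad,3,0.8
gloom,0,0.8
good,3,0.8
gorgeous,4,0.85
grateful,4,0.85
great,4,0.85
grief,0,0.9
grieve,0,0.88
guilt,0,0.82
guilty,0,0.82
happy,3,0.85
hate,0,0.9
heartbroken,0,0.9
heaven,4,0.8
hell,0,0.8
helpless,0,0.85
hope,3,0.75
hopeful,3,0.8
hopeless,0,0.92
horrible,0,0.9
hurt,0,0.82
hurting,0,0.85
ill,1,0.7
insomnia,1,0.8
inspire,4,0.8
insult,0,0.8
isolated,0,0.82
joy,4,0.9
kill,0,0.9
kind,3,0.75
laugh,3,0.85
lazy,1,0.6
lonely,0,0.85
lose,1,0.7
loser,0,0.8
loss,1,0.75
lost,1,0.75
love,4,0.9
loved,4,0.85
lovely,4,0.85
low,1,0.6
lucky,3,0.75
mad,1,0.75
marvelous,4,0.85
meaningless,0,0.85
miserable,0,0.9
misery,0,0.9
miss,1,0.6
mourn,0,0.85
nervous,1,0.75
nice,3,0.75
nightmare,0,0.85
numb,0,0.8
okay,2,0.6
optimistic,3,0.8
overwhelmed,1,0.8
pain,0,0.85
painful,0,0.85
panic,0,0.85
paradise,4,0.8
peace,3,0.8
perfect,4,0.9
pessimistic,1,0.8
pleasant,3,0.8
pleased,3,0.8
poor,1,0.65
positive,3,0.75
pretty,3,0.7
proud,4,0.82
regret,1,0.78
relaxed,3,0.75
relief,3,0.75
sad,1,0.85
sadness,0,0.88
satisfied,3,0.8
scared,1,0.8
shame,0,0.8
shine,3,0.7
shit,1,0.8
sick,1,0.75
sleepless,1,0.78
smile,3,0.85
sob,0,0.82
sorrow,0,0.88
sorry,1,0.7
strong,3,0.7
struggle,1,0.78
stuck,1,0.7
stupid,1,0.72
suffer,0,0.85
suffering,0,0.88
suicide,0,0.95
sunny,3,0.7
super,4,0.8
sweet,3,0.78
terrible,0,0.9
terrific,4,0.85
thankful,4,0.85
therapy,1,0.55
thrilled,4,0.88
tired,1,0.7
tough,1,0.65
tragedy,0,0.88
trapped,0,0.82
trouble,1,0.72
ugly,1,0.75
unhappy,0,0.85
upset,1,0.8
useless,0,0.85
victory,4,0.85
warm,3,0.7
weak,1,0.7
weep,0,0.82
welcome,3,0.7
well,3,0.6
win,3,0.8
wonderful,4,0.9
worn,1,0.6
worried,1,0.8
worry,1,0.78
worse,1,0.8
worst,0,0.88
worthless,0,0.9
wound,1,0.7
wreck,0,0.78
wrong,1,0.7
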