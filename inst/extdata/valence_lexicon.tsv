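# emospect mini valence lexicon (authored for this package; scale -4..4)
term	valence
amazing	2.8
awesome	3.0
excellent	3.0
fantastic	2.9
wonderful	2.8
great	2.5
good	1.8
nice	1.6
fine	1.2
effective	1.9
effectively	1.7
helps	1.5
helped	1.5
helpful	1.8
improvement	1.6
improved	1.7
improves	1.6
love	3.2
loved	2.9
lovely	2.4
happy	2.7
happier	2.5
pleased	2.0
pleasant	1.8
satisfied	2.1
satisfying	2.0
recommend	1.7
recommended	1.6
perfect	2.9
perfectly	2.6
best	3.2
better	1.9
impressive	2.2
impressed	2.1
reliable	1.7
reliably	1.5
comfortable	1.5
easy	1.4
easier	1.3
safe	1.3
safely	1.2
success	2.2
successful	2.3
successfully	2.1
glad	2.0
grateful	2.3
thankful	2.2
thanks	1.6
delighted	2.6
delightful	2.5
delight	2.3
enjoy	2.0
enjoyed	2.0
enjoyable	2.1
positive	1.8
positively	1.6
calm	1.3
calmer	1.2
relief	1.6
relieved	1.7
confident	1.8
confidence	1.7
strong	1.3
stronger	1.4
superb	2.0
solid	1.0
decent	0.5
okay	0.25
thrilled	2.6
excited	2.0
excitement	1.9
amazed	2.3
astonished	1.9
hopeful	1.7
hope	1.4
hopes	1.3
optimistic	1.8
worth	1.4
worthwhile	1.6
valuable	1.5
benefit	1.4
benefits	1.4
beneficial	1.6
pleasure	2.1
joyful	2.5
joy	2.4
cheerful	2.2
content	1.4
contented	1.5
smooth	1.2
smoothly	1.2
convenient	1.3
convenience	1.2
affordable	1.2
fresh	1.1
energetic	1.5
energized	1.6
vigorous	1.4
youthful	1.3
miracle	2.7
miraculous	2.8
magic	2.0
incredible	2.6
outstanding	2.8
remarkable	2.3
satisfactory	1.3
adequate	0.8
dependable	1.5
trustworthy	1.6
favorite	1.9
favourable	1.7
win	1.8
winner	2.0
winning	1.9
super	2.2
terrific	2.7
fabulous	2.7
brilliant	2.6
splendid	2.4
marvelous	2.5
gratified	1.9
reassured	1.5
restored	1.4
rejuvenated	1.8
revitalized	1.7
bad	-2.2
badly	-2.0
terrible	-2.9
terribly	-2.6
horrible	-2.8
horribly	-2.6
awful	-2.0
worst	-3.3
worse	-2.0
poor	-1.0
poorly	-1.2
mediocre	-0.5
iffy	-0.25
disappointed	-2.0
disappointing	-2.1
disappointment	-2.0
useless	-2.2
ineffective	-1.9
fail	-2.0
failed	-2.1
fails	-2.0
failure	-2.3
problem	-1.5
problems	-1.6
issue	-1.1
issues	-1.2
pain	-1.9
painful	-2.1
hurt	-1.8
hurts	-1.8
ache	-1.4
aches	-1.4
headache	-1.6
headaches	-1.7
nausea	-1.7
nauseous	-1.8
dizzy	-1.4
dizziness	-1.5
sick	-1.8
sicker	-1.9
severe	-1.8
severely	-1.9
unpleasant	-1.7
uncomfortable	-1.6
nasty	-2.0
hate	-2.9
hated	-2.7
hates	-2.8
angry	-2.2
anger	-2.0
annoyed	-1.7
annoying	-1.8
annoyance	-1.6
irritated	-1.7
irritating	-1.8
frustrating	-1.9
frustrated	-1.8
frustration	-1.8
sad	-1.9
sadness	-1.8
depressed	-2.2
depressing	-2.1
depression	-2.0
anxious	-1.5
anxiety	-1.4
nervous	-1.3
scared	-1.9
scary	-1.8
afraid	-1.8
terrified	-2.6
terror	-2.4
fear	-1.6
fearful	-1.7
worried	-1.5
worry	-1.4
worries	-1.5
regret	-1.9
regrets	-1.9
regretted	-2.0
waste	-1.7
wasted	-1.8
expensive	-1.1
costly	-1.0
avoid	-1.3
avoided	-1.2
danger	-1.9
dangerous	-2.0
risky	-1.4
risk	-1.1
risks	-1.2
embarrassing	-1.6
embarrassed	-1.5
embarrassment	-1.6
miserable	-2.4
misery	-2.3
upset	-1.8
upsetting	-1.9
unhappy	-2.0
dissatisfied	-1.9
dreadful	-2.5
dread	-1.9
troubling	-1.5
trouble	-1.4
troubles	-1.5
harsh	-1.5
harm	-1.7
harmful	-1.8
damage	-1.6
damaged	-1.6
weak	-1.2
weaker	-1.3
tired	-1.1
exhausted	-1.6
exhausting	-1.5
suffer	-2.0
suffered	-2.1
suffering	-2.1
unbearable	-2.5
intolerable	-2.4
awkward	-1.2
confusing	-1.2
confused	-1.1
doubt	-1.1
doubtful	-1.3
doubts	-1.2
skeptical	-1.0
mess	-1.5
messy	-1.4
gross	-1.8
vile	-2.3
disgusting	-2.4
disgusted	-2.3
shame	-1.8
ashamed	-1.7
lousy	-1.9
pathetic	-2.2
dismal	-2.0
grim	-1.7
bleak	-1.6
hopeless	-2.2
helpless	-1.9
desperate	-1.8
desperation	-1.9
agony	-2.4
agonizing	-2.5
crushed	-2.0
devastated	-2.7
devastating	-2.6
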