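# emospect demonstration emotion lexicon (synthetic, illustrative)
# three tiers: 6 fixed primaries -> secondary -> tertiary; synonyms pipe-separated
# n_subclasses: 41
# n_synonyms: 142
label	tier	parent	synonyms
joy	primary		joyous
love	primary		
surprise	primary		surprised|surprising
sadness	primary		sad
fear	primary		
anger	primary		
cheerfulness	secondary	joy	cheerful|cheery|merry
delight	tertiary	cheerfulness	delighted|delightful
happiness	tertiary	cheerfulness	happy|glad|gladness|joyful|jolly
elation	tertiary	cheerfulness	elated|euphoria|euphoric|ecstatic|ecstasy
contentment	secondary	joy	content|contented
satisfaction	tertiary	contentment	satisfied|satisfying|pleased|gratified
relief	tertiary	contentment	relieved|reassured
optimism	secondary	joy	optimistic
hope	tertiary	optimism	hopeful|hopefulness
eagerness	tertiary	optimism	eager|enthusiasm|enthusiastic|excited|excitement
affection	secondary	love	adore|adoration|fondness|tenderness
liking	tertiary	affection	caring|cherish
attraction	tertiary	affection	allure|charmed|smitten
lust	secondary	love	desire|passion|passionate
arousal	tertiary	lust	aroused
longing	secondary	love	yearning|pining
amazement	secondary	surprise	amazed|amazing|astonished|astonishment|astounded
wonder	tertiary	amazement	wondrous|awe|awestruck
shock	secondary	surprise	shocked|stunned|startled
disbelief	tertiary	shock	unbelievable|incredulous
grief	secondary	sadness	grieving|mourning|bereft
heartbroken	tertiary	grief	heartbreak|heartache
sorrow	tertiary	grief	sorrowful|woe|anguish
disappointment	secondary	sadness	disappointed|disappointing|let down|letdown
displeasure	tertiary	disappointment	displeased|dissatisfied|dissatisfaction
gloom	secondary	sadness	gloomy|down|downhearted|blue|blues
depression	tertiary	gloom	depressed|depressing|despair|hopeless|miserable|misery
loneliness	tertiary	gloom	lonely|isolated
suffering	secondary	sadness	suffer|suffered|hurting
agony	tertiary	suffering	agonizing|torment
nervousness	secondary	fear	nervous|anxiety|anxious|uneasy|unease|jittery
worry	tertiary	nervousness	concern|concerned|apprehensive|dread
horror	secondary	fear	horrified|horrible|terror|terrified
panic	tertiary	horror	panicked|panicky|alarm|alarmed
fright	secondary	fear	frightened|scared|scary|afraid|fearful
rage	secondary	anger	angry|furious|fury|outrage|outraged|enraged
wrath	tertiary	rage	livid|seething
irritation	secondary	anger	irritated|irritating|annoyed|annoying|annoyance|aggravated
frustration	tertiary	irritation	frustrated|frustrating
disgust	secondary	anger	disgusted|disgusting|revolted|revulsion
resentment	tertiary	disgust	resentful|bitter|bitterness
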