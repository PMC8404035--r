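token	polarity
good	0.6
great	0.8
excellent	0.9
amazing	0.9
wonderful	0.9
fantastic	0.9
brilliant	0.8
happy	0.7
happier	0.7
glad	0.6
relieved	0.6
relief	0.6
hopeful	0.5
hope	0.4
encouraging	0.6
encouraged	0.6
positive	0.5
improving	0.6
improved	0.7
improvement	0.6
better	0.5
recovered	0.7
recovering	0.5
recovery	0.5
stable	0.4
calm	0.4
comfortable	0.5
helpful	0.6
helped	0.5
supportive	0.6
support	0.4
reassuring	0.6
reassured	0.6
grateful	0.7
thankful	0.7
delighted	0.9
pleased	0.7
success	0.7
successful	0.7
effective	0.5
working	0.3
clear	0.4
clearing	0.4
healed	0.7
healing	0.5
remission	0.7
painless	0.6
easy	0.4
easier	0.4
fine	0.4
okay	0.3
ok	0.3
smooth	0.4
lucky	0.5
enjoy	0.6
enjoying	0.6
loving	0.7
bad	-0.6
worse	-0.7
worsening	-0.7
worst	-0.9
terrible	-0.9
horrible	-0.9
awful	-0.8
dreadful	-0.8
pain	-0.6
painful	-0.7
hurts	-0.6
hurting	-0.6
ache	-0.5
aching	-0.5
sore	-0.5
agony	-0.9
unbearable	-0.9
miserable	-0.8
suffering	-0.8
suffer	-0.7
scared	-0.7
scary	-0.7
frightened	-0.7
frightening	-0.7
terrified	-0.9
afraid	-0.6
worried	-0.6
worrying	-0.6
worry	-0.5
anxious	-0.6
anxiety	-0.6
panic	-0.7
panicking	-0.7
stressed	-0.6
stressful	-0.6
upset	-0.6
crying	-0.7
cried	-0.7
tears	-0.5
depressed	-0.8
depressing	-0.7
hopeless	-0.8
helpless	-0.7
desperate	-0.8
devastated	-0.9
devastating	-0.9
frustrated	-0.6
frustrating	-0.6
angry	-0.6
annoyed	-0.5
annoying	-0.5
exhausted	-0.6
exhausting	-0.6
tired	-0.4
fatigue	-0.4
nasty	-0.6
severe	-0.5
serious	-0.4
blind	-0.7
blindness	-0.8
losing	-0.5
loss	-0.5
lost	-0.5
failed	-0.7
failing	-0.6
failure	-0.7
relapse	-0.6
relapsed	-0.6
struggling	-0.6
struggle	-0.5
difficult	-0.5
hard	-0.4
unwell	-0.5
sick	-0.5
nausea	-0.5
vomiting	-0.6
dizzy	-0.4
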