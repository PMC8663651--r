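# SYNTHETIC stand-in for a thesaurus-derived pain keyword expansion list
# (51 entries). The original expansion list is not published; these are
# ordinary English pain synonyms assembled from general-purpose thesauri.
# One keyword per line; lines starting with '#' are comments.
ache
agony
anguish
discomfort
distress
soreness
twinge
sting
pang
cramp
spasm
throb
tenderness
irritation
inflammation
stiffness
suffering
misery
torment
hurt
affliction
malaise
smart
burn
prickle
tightness
pressure
strain
sprain
bruise
wound
laceration
rawness
chafing
grinding
pulsation
stitch
crick
kink
numbness
tingle
shock
jolt
gripe
colic
neuralgia
backache
earache
headache
heartache
toothache
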