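# SYNTHETIC stand-in for a list of common pain conditions. The original
# condition list is not published; these are common pain conditions drawn
# from general clinical vocabulary. One condition per line; '#' comments.
migraine
headache
arthritis
osteoarthritis
rheumatoid arthritis
fibromyalgia
sciatica
neuropathy
endometriosis
gout
tendonitis
bursitis
toothache
backache
back pain
neck pain
shoulder pain
knee pain
joint pain
nerve pain
chronic pain
menstrual cramps
kidney stones
ulcer
shingles
cystitis
ibs
crohn's disease
lupus
multiple sclerosis
cancer
chemotherapy
surgery
injury
fracture
sprain
whiplash
tmj
carpal tunnel
plantar fasciitis
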