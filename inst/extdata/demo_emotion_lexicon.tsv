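# Built-in demonstration affect lexicon (hand-written, synthetic).
# Format: token<TAB>channel<TAB>intensity — the plug-in format for any
# affect-intensity lexicon. Channels: anger, fear, sadness, joy, valence.
token	channel	intensity
furious	anger	0.8
angry	anger	0.7
rage	anger	0.9
irritated	anger	0.5
annoyed	anger	0.4
terrified	fear	0.85
scared	fear	0.7
afraid	fear	0.65
anxious	fear	0.6
worried	fear	0.5
nervous	fear	0.55
heartbroken	sadness	0.75
miserable	sadness	0.7
sad	sadness	0.6
hopeless	sadness	0.8
depressed	sadness	0.75
crying	sadness	0.65
delighted	joy	0.7
happy	joy	0.65
relieved	joy	0.5
grateful	joy	0.6
awful	valence	0.2
terrible	valence	0.15
horrible	valence	0.15
unbearable	valence	0.1
excruciating	valence	0.08
fine	valence	0.6
good	valence	0.7
great	valence	0.8
wonderful	valence	0.85
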