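# degree modifiers: increment added to |valence| of the next scored token
term	increment
very	0.3
really	0.25
extremely	0.4
absolutely	0.35
totally	0.3
incredibly	0.4
so	0.2
quite	0.15
remarkably	0.3
exceptionally	0.4
slightly	-0.2
somewhat	-0.15
marginally	-0.25
barely	-0.3
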