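grapheme	phoneme	probability
p	p	1.0
u	ʊ	0.6
u	ʌ	0.3
t	t	1.0
sh	ʃ	1.0
s	s	0.95
h	h	0.9
oo	uː	0.8
o	ɒ	0.7
ea	iː	0.6
ea	ɛ	0.3
m	m	1.0
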