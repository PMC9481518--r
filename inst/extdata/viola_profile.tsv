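langsdorffii	9
tracheliifolia	7
grahamii	7
palustris721	4
blanda	4
palustris933	4
glabella	2
macloskeyi	2
repens	2
verecunda	2
Viola	2
Rubellium	1
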