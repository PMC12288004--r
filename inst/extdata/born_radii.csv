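element,radius
H,1.2
C,1.7
N,1.55
O,1.5
F,1.5
P,1.85
S,1.8
Cl,1.7
Br,1.85
I,1.98
Na,1.87
K,2.66
Ar,1.88
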