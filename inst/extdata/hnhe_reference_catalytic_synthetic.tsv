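family	position	residue
IHMU	74	D
IHMU	75	H
IHMU	96	N
PACI	49	D
PACI	50	H
PACI	80	N
GVE2	99	D
GVE2	100	H
GVE2	130	H
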