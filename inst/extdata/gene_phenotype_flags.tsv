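gene	neurological	motor	intellectual_disability	dysmorphism
IQSEC2	1	1	1	0
KCNMA1	1	1	1	0
POLR1C	0	1	1	0
GNPAT	1	1	1	1
PGAP3	0	1	1	0
HNRNPU	1	1	1	0
PLP1	1	1	1	0
ADSL	1	1	1	0
ACTG1	0	1	1	1
ATP1A3	1	1	1	0
CHD3	0	1	1	0
NIPBL	1	0	1	1
NGLY1	1	1	1	0
SMAD6	0	1	1	1
NKX6-2	1	1	1	0
TCF4	1	0	1	1
PAH	1	0	1	0
SCN2A	1	1	1	0
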