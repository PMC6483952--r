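trait	h2	sigma2_g
MY	0.33	213490
FY	0.29	330.10
PY	0.29	181.30
STA	0.54	5.50
OFL	0.11	0.89
USU	0.20	0.37
NRK	0.02	0.0045
PRP	0.05	1171.50
OMC	0.08	557.40
SCS	0.32	28737
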