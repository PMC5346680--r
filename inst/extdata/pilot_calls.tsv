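id	cdna	af
P01	c.35G>A	0.003
P02	c.35G>A	0.0045
P03	c.35G>A	0.008
P04	c.35G>A	0.012
P05	c.35G>T	0.016
P06	c.14A>G	0.021
P07	c.14A>G	0.026
P07	c.28G>A	0.004
P37	c.35G>T	0.029
P38	c.34G>C	0.115
B01	c.35G>A	0.009
B12	c.31G>C	0.004
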