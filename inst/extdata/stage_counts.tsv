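stage	series	total	detected
local	pilot	6	1
regional	pilot	17	1
systemic	pilot	16	7
unknown	pilot	1	0
local	validation	33	3
regional	validation	126	24
systemic	validation	119	38
unknown	validation	119	18
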