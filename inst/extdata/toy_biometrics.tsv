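animal_id	stage	TL_cm	TW_g	BW_g
a1	glass	6.5	0.22	0.004
a2	glass	6.9	0.25	0.005
a3	glass	6.1	0.20	0.003
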