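segment_id	stage	animal_id	arc_length_um
s1	glass	a1	10
s2	glass	a2	12.5
s3	glass	a3	20
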