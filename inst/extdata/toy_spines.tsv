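segment_id	stage	total_length_um	has_head	head_diameter_um	neck_max_diameter_um	neck_length_um
s1	glass	1.2	TRUE	0.8	0.4	0.3
s1	glass	2.0	TRUE	0.5	0.2	1.5
s1	glass	0.7	FALSE	0	0	0
s1	glass	12.0	FALSE	0	0	0
s2	glass	1.1	TRUE	0.7	0.35	0.2
s2	glass	1.3	TRUE	0.9	0.45	0.4
s2	glass	1.0	TRUE	0.6	0.3	0.25
s2	glass	2.5	TRUE	0.4	0.15	1.8
s2	glass	0.5	FALSE	0	0	0
s3	glass	3.0	TRUE	0.45	0.2	2.2
s3	glass	2.2	TRUE	0.5	0.25	1.6
s3	glass	11.0	FALSE	0	0	0
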