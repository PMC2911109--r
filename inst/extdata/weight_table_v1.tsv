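feature	position	base	weight
position_base	1	G	1
position_base	1	C	1
position_base	3	A	2
position_base	10	T	2
position_base	13	G	-2
position_base	19	A	3
position_base	19	T	2
position_base	19	G	-3
position_base	19	C	-3
gc_window	NA	NA	4
at_15_19	NA	NA	1
no_internal_repeat	NA	NA	2
min_raw	NA	NA	-5
max_raw	NA	NA	19
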