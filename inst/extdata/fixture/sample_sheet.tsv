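sample_id	stage	replicate	genome_mapped_reads
y1	young	1	2000000
y2	young	2	2000000
y3	young	3	2000000
i1	intermediate	1	2000000
i2	intermediate	2	2000000
i3	intermediate	3	2000000
m1	mature	1	2000000
m2	mature	2	2000000
m3	mature	3	2000000
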