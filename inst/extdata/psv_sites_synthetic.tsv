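pos	smn1_base	smn2_base	exon_group
1100	G	A	exon1_6
2300	A	G	exon1_6
3600	T	C	exon1_6
4800	C	T	exon1_6
6100	C	T	exon7_8
6550	G	A	exon7_8
7200	C	T	exon7_8
7650	T	G	exon7_8
8400	A	G	exon7_8
8800	C	T	exon7_8
9100	G	A	exon7_8
9500	A	G	exon7_8
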