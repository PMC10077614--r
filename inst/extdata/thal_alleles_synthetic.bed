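chr16	200000	219300	--SEA	0	.	deletion
chr16	150000	153800	-a3.7	0	.	deletion
chr16	260000	264200	-a4.2	0	.	deletion
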