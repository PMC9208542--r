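chr14	100000	103000	GgDNase1L2	0	+
chr14	103630	106630	GgDNase1	0	+
chr1	50000	61000	Uox	0	-
chr1	61200	66200	DNase2b	0	+
chrX	20000	32000	DNase1L1	0	-
chrX	32400	41000	Tafazzin	0	+
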