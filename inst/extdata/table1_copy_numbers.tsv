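# Published per-class TE copy numbers for the selfing/outcrossing genome pair
# (A. thaliana vs A. lyrata): copy number, copies per Mbp, percent of genome.
genome	te_class	copy_number	copies_per_mbp	pct_genome
A_thaliana	LTR	6784	56.9	6.9
A_thaliana	non-LTR	2243	18.8	1.2
A_thaliana	DNA	12631	106.0	6.7
A_thaliana	unknown	1198	10.1	0.2
A_thaliana	Total	22856	200.6	15.0
A_lyrata	LTR	18558	89.8	12.9
A_lyrata	non-LTR	6844	33.1	2.6
A_lyrata	DNA	40118	194.1	9.0
A_lyrata	unknown	4422	21.4	0.7
A_lyrata	Total	69942	343.4	25.2
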