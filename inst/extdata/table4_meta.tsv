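lineage	snp20	age_mean_printed	age_sd_printed
A	TTGATCAAGC-CACCCAGCGC	16335	1966
B	TTGATCGAGC-CACCCAGCGC	9272	1352
D	TTGATCAAGC-GACCCAGCGC	11837	1871
G	TTGATCGAGC-GACCCAGCGC	9254	1411
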