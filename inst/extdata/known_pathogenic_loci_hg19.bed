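# Demo known-pathogenic-locus file (BED4 + flag), GRCh37/hg19, 0-based half-open.
# Approximate boundaries of recurrent CNV syndrome loci; replace with a curated
# list for production use. Column 5: "dominant" marks loci tiered pathogenic
# regardless of inheritance; "." marks variable-expressivity loci tiered
# likely_pathogenic.
chr1	146527986	147394444	1q21.1_distal	.
chr15	23683782	28446765	15q11.2-q13.1	dominant
chr16	15511654	16293689	16p13.11	.
chr16	29649996	30199854	16p11.2_proximal	.
chr22	18912230	21465672	22q11.21	dominant
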