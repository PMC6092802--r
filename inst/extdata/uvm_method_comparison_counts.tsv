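# Published per-cluster Above/Below splits of the TCGA uveal-melanoma
# cohort under the diploid-referenced ("differential") versus the
# cohort-referenced ("relative") Z-score, with the published chi-square P
# of the 2x2 contrast. Non-numeric P entries are the publication's
# qualitative verdicts for the copy-neutral control gene.
gene	cluster	diff_above	diff_below	rel_above	rel_below	printed_p
BAP1	1	5	10	14	1	0.0007
RPS19	1	15	0	15	0	Identical
BAP1	2	13	10	22	1	0.0019
RPS19	2	10	13	10	13	Identical
BAP1	3	0	22	4	18	0.0359
RPS19	3	7	15	11	11	Not Different
BAP1	4	0	20	6	14	0.0079
RPS19	4	2	18	2	18	Identical
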