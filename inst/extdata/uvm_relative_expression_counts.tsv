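# Published per-cluster Above/Below counts for relative (cohort-average
# referenced) expression in the TCGA uveal-melanoma cohort (n = 80; SCNA
# clusters of 15/23/22/20), with the published pooled clusters 1&2 vs 3&4
# two-tailed Fisher P. Rows whose published P is inconsistent with their
# own printed counts are annotated in `note`.
gene	above1	below1	above2	below2	above3	below3	above4	below4	printed_p	note
MCM2	12	3	20	3	3	19	5	15	<0.0001
MCM3	7	8	10	13	7	15	12	8	1.0000
MCM4	2	13	6	17	11	11	18	2	<0.0001
MCM5	9	6	16	7	11	11	4	16	0.0133
MCM6	6	9	9	14	15	7	19	1	0.0002
MCM7	3	12	17	6	11	11	11	9	1.0000
CDC45	5	10	6	17	14	8	15	5	0.0007
GINS1	5	10	8	15	6	16	15	5	0.1074	published P inconsistent with printed counts
GINS2	8	7	11	12	14	8	9	11	0.8229
GINS3	11	4	11	12	8	14	11	9	0.2735
GINS4	6	9	12	11	11	11	9	11	1.0000
MCM10	3	12	9	14	9	13	15	5	0.0261
CIZ1	12	3	15	8	13	9	2	18	0.0019
PCNA	8	7	4	19	8	14	17	3	0.0147
FEN1	5	10	9	14	11	11	17	3	0.0132
LIG1	1	14	10	13	16	6	15	5	0.0001
POLD1	7	8	17	6	7	15	6	14	0.0067
POLE	4	11	14	9	11	11	16	4	0.1761
HUS1	7	8	9	14	12	10	18	2	0.0124
RAD9A	9	6	10	13	13	9	16	4	0.1105
RAD1	8	7	10	13	10	12	16	4	0.2609
RAD17	8	7	9	14	9	13	16	4	0.2624
ATR	11	4	10	13	6	16	13	7	0.5021
CHEK1	4	11	8	15	12	10	15	5	0.0041
ATRIP	11	4	19	4	6	16	2	18	0.0001
MLH1	11	4	13	10	7	15	11	9	0.0781
MLH3	6	9	9	14	12	10	16	4	0.0242
MSH2	7	8	12	11	9	13	16	4	0.5004
MSH3	8	7	11	12	9	13	16	4	0.5004
MSH6	4	11	13	10	10	12	16	4	0.0357	published P inconsistent with printed counts
PMS1	6	9	9	14	9	13	16	4	0.1165
PMS2	8	7	15	8	11	11	14	6	1.0000
EXO1	8	7	10	13	4	18	13	7	0.6526
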