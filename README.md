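# relexpr

Relative exon expression, subtype association and survival for
copy-number-subtyped tumor cohorts — built around the TCGA uveal-melanoma
(UVM) setting, where 80 tumors fall into four somatic copy-number
alteration (SCNA) clusters (sizes 15/23/22/20) and clusters 3&4 are
monosomic for chromosome 3.

UVM has no matched normal tissue for RNA-seq, so "high" or "low"
expression needs an explicit reference. For exon *e* and case *i*, with
*x* = log2(RPKM + c), the package computes

    z_ei = (x_ei − mean_i(x_e)) / sd_i(x_e)

under two references: the whole tumor cohort (the "average alteration
level" — *relative* expression) or only the tumors diploid at the gene's
locus (*differential* expression, the cBioPortal convention). Gene scores
are unweighted exon means; cases are placed **Above** (score > 0) or
**Below** the reference. Per gene, Above/Below counts per cluster are
pooled into a 2×2 table — clusters 1&2 vs 3&4 — and tested with a
two-tailed Fisher exact test (GraphPad-style tie handling) or an
uncorrected Pearson chi-square; expression groups are compared on
disease-specific survival by Kaplan–Meier, log-rank (Mantel–Cox) and the
O/E hazard ratio. A junction-coverage detector (threshold 4 reads)
screens for exon-skipping isoforms such as CIZ1 Δexon4 and MLH3
Δexon5/Δexon7. A synthetic cohort generator reproduces the whole data
structure — monosomy-3 dosage, 8q gain, cluster-dependent hazards,
injected skip junctions — so every stage is testable without protected
data. Intended users: computational biologists reanalyzing exon-level
TCGA-style quantifications or benchmarking dichotomized-expression
association pipelines.

## Worked example

```r
library(relexpr)

cohort <- generate_cohort(synthetic_config(seed = 1))  # 80 cases, 15/23/22/20
res <- run_analysis(cohort)
res$summary[res$summary$gene %in% c("MCM2", "PCNA", "RPS19"),
            c("gene", "cluster1", "cluster3", "fisher_p",
              "worse_survival", "logrank_p", "hr")]
#>   gene     cluster1      cluster3 fisher_p worse_survival logrank_p    hr
#>   MCM2 15/0 (100/0)  0/22 (0/100) 1.03e-23          Below  7.55e-06 0.218
#>   PCNA 2/13 (13/87)  22/0 (100/0) 3.43e-19          Above  3.60e-05 4.166
#>  RPS19  7/8 (47/53) 11/11 (50/50) 8.23e-01           <NA>  7.17e-01 1.126
```

Each `a/b (p/q)` cell counts cases Above/Below the cohort average in that
cluster (with percentages). MCM2 sits on chromosome 3: the injected
monosomy in clusters 3&4 drops every monosomic case Below (pooled Fisher
P ≈ 10⁻²³), and the Below group has significantly worse disease-specific
survival (hazard ratio of Above vs Below 0.22). PCNA carries an injected
copy-number-independent +0.8 log2 effect and moves the opposite way;
RPS19 is a copy-neutral null and shows nothing. The skipping report
recovers the injected isoforms:

```r
head(as.data.frame(res$skipping), 3)
#>       case_id gene skipped_exons supporting_reads flank_upstream flank_downstream
#>  TCGA-SY-0001 CIZ1             4                9              3                5
#>  TCGA-SY-0002 CIZ1             4               23              3                5
#>  TCGA-SY-0002 MLH3             5                8              4                6
```

The bundled published per-cluster counts reproduce the original
association statistics:

```r
rp <- reproduce_printed_tables()
rp[rp$gene %in% c("MCM5", "CIZ1", "MSH6"), ]
#>  gene  a  b  c  d recomputed_p printed_p match
#>  MCM5 25 13 15 27    1.329e-02    0.0133  TRUE
#>  CIZ1 27 11 15 27    1.893e-03    0.0019  TRUE
#>  MSH6 17 21 26 16    1.778e-01    0.0357 FALSE
```

31 of 33 rows match at 4-decimal rounding (or satisfy the printed bound);
the two mismatching rows carry published P values inconsistent with their
own printed counts and are annotated as such in the bundled file. A thin
CLI over the same functions lives at `inst/cli/relexpr`
(`simulate` / `analyze` / `reproduce-tables` / `detect-skipping`).

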