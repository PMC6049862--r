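# lncscape

Integrative analysis of the long non-coding RNA (lncRNA) regulatory
landscape in tumor transcriptomes, modelled on glioblastoma expression
studies.

Beyond protein-coding genes, tumors dysregulate thousands of lncRNAs. A
single expression study can interrogate their regulatory roles on several
levels at once: transcriptional co-regulation of nearby (*cis*, here within
±500 kb) and distant (*trans*) genes, hosting of miRNA hairpins inside
lncRNA loci, competition for shared miRNAs (ceRNA or "sponge" activity), and
prognostic value. lncscape packages that entire workflow — with a
ground-truth synthetic-data generator so every stage is testable without any
external download — for bioinformaticians analyzing tumor-vs-control
expression cohorts with genomic annotation.

## What it computes

| stage | method |
|---|---|
| normalization | quantile normalization (rank → mean of column-sorted values, tie-averaged); median-of-ratios size factors for counts; Present/Marginal detection-flag filter |
| differential expression | per-feature Welch t-test on log2 values, log2 FC = difference of group means, Benjamini–Hochberg FDR, per-stage FC/p/FDR gates |
| positional subtypes | six classes relative to protein-coding genes (intergenic, intronic antisense, intron sense overlapping, natural antisense, exon sense overlapping, bidirectional at TSS distance ≤ 1 kb), plus removal of exon-sense lncRNAs wholly contained in mRNA exons |
| co-expression | sample-wise Spearman rho with t-approximation p; *cis* pairs (±500 kb, inclusive) kept at p < 0.05; *trans* pairs additionally require \|rho\| > 0.9; lncRNA–lncRNA self-crosses drop self-pairs and collapse symmetric duplicates |
| miRNA hosts | interval intersection (≥ 1 bp, same strand by default) of lncRNA spans with miRNA coordinates; concordantly regulated pairs retained and annotated with host–miRNA correlation |
| sponge modules | lncRNA –\| miRNA –\| mRNA triplets: predicted lncRNA–miRNA and validated miRNA–mRNA arms both negatively correlated, all three members upregulated, lncRNA–mRNA positively correlated, and lncRNA abundance significantly above the mRNA (one-sided Wilcoxon signed-rank) |
| survival | univariate Cox screen over eligible lncRNAs; risk score of a sample = Σ (Cox coefficient × log2 expression); median-split stratification, Kaplan–Meier + log-rank, multivariate Cox against age/G-CIMP/IDH1/MGMT |

## Worked example

Simulate a 150-tumor / 22-control cohort with 20 planted sponge triplets,
500 decoy chains and a 5-lncRNA survival signature, then run the full
pipeline:

```r
library(lncscape)
ds  <- simulate_gbm_dataset(n_tumor = 150, n_control = 22,
                            n_sponge = 20, n_decoy = 500, seed = 1)
res <- run_pipeline(ds, pipeline_config(rng_seed = 1), out_dir = "out")

res$subtype_summary
#>                    subtype count percentage
#> 1   exon_sense_overlapping    10       9.43
#> 2        natural_antisense    13      12.26
#> 3 intron_sense_overlapping    11      10.38
#> 4       intronic_antisense    13      12.26
#> 5            bidirectional     8       7.55
#> 6               intergenic    51      48.11

nrow(res$sponge_modules)
#> [1] 20           # the 20 planted triplets; none of the 500 decoys survive

res$signature[, c("feature_id", "coefficient", "hazard_ratio", "p_value")]
#>     feature_id coefficient hazard_ratio      p_value
#> 14     LNC0019  -0.4308962    0.6499264 1.634781e-05
#> 15     LNC0020   0.3572657    1.4294156 2.478092e-04
#> 13     LNC0018   0.4032513    1.4966829 4.793548e-04
#> 134    LNC0213   0.3419989    1.4077587 2.271274e-03
#> 92     LNC0100  -0.2922793    0.7465600 3.267601e-03

res$stratification$median_survival
#>      high       low
#>  5.882083 20.610387     # months; low-risk patients live ~3.5x longer
res$stratification$logrank_p
#> [1] 1.29e-07
```

The subtype table is the pie-chart view of the dysregulated lncRNAs (the
intergenic class dominates, as in real tumor data). Negative Cox
coefficients mark protective lncRNAs (higher expression, lower hazard);
positive ones mark risk lncRNAs. The risk score splits the cohort at its
median into groups whose Kaplan–Meier curves separate at log-rank
p ≈ 10⁻⁷, and the multivariate fit confirms the score is prognostic
independent of age, G-CIMP, IDH1 and MGMT status
(`res$multivariate$results`).

Every stage's table is also written to `out/` as TSV alongside a
`run_summary.json` with per-stage counts, thresholds, seed and version.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end from scratch against the installed
package: a microarray-style cohort (19 tumors / 9 controls) for the DE,
classification, network and host stages, and an RNA-Seq-style cohort
(150 tumors) for the sponge and survival stages, logging the headline counts
of each run and writing the JSON report to `--out`.

## Layout

- `R/` — implementation (data model and I/O; normalization and DE; subtype
  classifier; co-expression; host mapper; sponge inference; survival
  signature; synthetic-data generator; pipeline orchestration)
- `tests/testthat/` — unit, property and acceptance suites (all fixtures
  generated in code)
- `vignettes/lncrna-regulatory-landscape.Rmd` — the methods vignette: model
  assumptions, parameter meanings, numerical choices, generator scope,
  limitations
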