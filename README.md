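# ctaei — cell-type-specific allelic expression imbalance from bulk RNA-seq

Allelic expression imbalance (AEI) — a gene's two alleles being expressed
unequally within one individual — is a direct signature of cis-regulatory
variation. Bulk RNA-seq measures it as allele-specific read counts at
heterozygous transcribed SNPs, but averages over the cell types in the
tissue: imbalance confined to one cell type is diluted, and two cell types
imbalanced in opposite directions can cancel exactly at the bulk level.

`ctaei` is for geneticists and computational biologists who have bulk
RNA-seq allele counts for many individuals and a single-cell reference for
the tissue, and want to know *which cell type* carries the imbalance. It
implements a two-step regression procedure:

1. **Deconvolution** — cell-type proportions `p_jk` per bulk sample by
   non-negative least squares against a single-cell signature
   (`build_reference()`, `estimate_proportions()`), under the model
   `X_jg = m_j * sum_k p_jk * S_k * theta_gk`.
2. **Allelic regression** — per transcribed SNP, the allelic read-count
   difference is regressed on size-factor-scaled proportions,

   ```
   X_jT - X_jt = alpha + sum_k m_j p_jk S_k theta^k + eps_j
   ```

   and `H0: theta^k = 0` is tested per cell type with a t statistic
   (`test_aei()`), with Benjamini–Hochberg FDR across all SNP-by-cell-type
   tests. A covariate extension tests whether clinical factors shift
   cell-type-specific AEI via proportion-by-covariate interactions
   (`test_daei()`), e.g. disease status or HbA1c.

The package also provides the traditional bulk-level binomial-logit
comparator (`bulk_glm_test()`, `bulk_glm_covariate_test()`), a
resampling-based gene-set enrichment test (`enrichment_resampling()`), an
analytic calculator for the fraction of individuals misaligned when the
transcribed SNP tags the regulatory variant imperfectly
(`misalignment_proportion()`), and the full pseudo-bulk benchmark
simulator with ground truth and power/type-I scoring (`simulate_dataset()`,
`simulate_two_condition()`, `evaluate_benchmark()`).

## Worked example

Simulate an islet-like benchmark (60 individuals, 5,000 cells each, six
cell types, one transcribed SNP per gene), then run the cell-type AEI
analysis with true proportions:

```r
library(ctaei)

cfg <- sim_config(n_snps = 400, n_individuals = 60, seed = 7)
sim <- simulate_dataset(cfg)
sim
#> Simulated pseudo-bulk benchmark dataset
#>   individuals: 60  genes/SNPs: 400  cell types: 6
#>   mean per-SNP bulk coverage: 634.2 reads

design <- build_design(compute_size_factors(sim$bulk), sim$proportions)
fit <- test_aei(sim$counts, design)
fit
#> Cell-type-specific AEI fit
#>   SNPs: 400  cell types: 6  tests: 2400 of 2400
#>   significant at q < 0.05: 241

head(as.data.frame(fit), 3)
#>      snp_id    gene_id cell_type  n   estimate       se  statistic df          p          q code
#> 1 snp_00001 gene_00001     alpha 60  -88.87721 264.0776 -0.3365572 53 0.73777971 0.95252836   ok
#> 2 snp_00001 gene_00001      beta 60 -439.08735 134.8881 -3.2551965 53 0.00197713 0.02099607   ok
#> 3 snp_00001 gene_00001     delta 60 -189.44382 292.2177 -0.6482969 53 0.51959195 0.91444183   ok
```

Each row is one cell type of one SNP: `estimate` is the allelic
expression difference attributable to that cell type (negative = the
alternative allele is favoured; here the first SNP's imbalance localizes
to beta cells), `p` its two-sided t-test p-value on `df = n - (K+1)`
degrees of freedom, `q` the BH-adjusted value. Scoring against the
simulator's ground truth:

```r
evaluate_benchmark(fit, sim$truth)
#> Benchmark evaluation (p < 0.05, 2400 tests)
#> Overall power by true AEI magnitude bin:
#>        bin   n     power
#>  [0.5,0.6) 219 0.6392694
#>  [0.6,0.7) 142 0.7253521
#>    [0.7,1]  39 0.8461538
#> Type I error by cell type:
#>  cell_type   n type1_error
#>      alpha 386  0.03886010
#>       beta 361  0.08310249
#>      delta 344  0.02906977
#>     ductal 325  0.06769231
#>      gamma 340  0.06470588
#>   stellate 244  0.02868852
#> Direction recovery among detected tests: 0.996
```

Power rises with the true imbalance (85% in the [0.7, 1) bin here) while
false positives on unaffected cell types sit near the nominal 5% (the
per-type rates above are noisy at 400 SNPs). Deconvolution of the same
bulk matrix against the simulated single-cell reference recovers the true
proportions closely (`cor = 0.977` pooled over samples and cell types),
and the analytic LD calculator quantifies the cost of imperfect tagging:

```r
misalignment_proportion(maf_t = 0.3, maf_r = 0.3, r2 = c(0.2, 0.5, 1))
#> [1] 0.06417029 0.01801515 0.00000000
```

For real data the workflow is identical with files instead of simulator
output: `read_allele_counts()` + `filter_allele_counts()` (minor allele
count ≥ 5, total ≥ 20, minor fraction ≥ 5%, ≥ 20 surviving individuals
per SNP), `read_expression()` + `compute_size_factors()`, a proportions
matrix from `estimate_proportions()` or any external deconvolution tool,
then `test_aei()` / `test_daei()`.

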