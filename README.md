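# methdrift

Grade-associated DNA methylation drift in donor-paired methylation arrays.

Atherosclerotic lesions accumulate DNA methylation changes as they progress.
`methdrift` identifies **grade-CpGs**: array probes whose
atherosclerotic-versus-normal methylation difference, measured within
donor-matched aortic sample pairs, drifts monotonically with the lesion's
histological grade (AHA grades III–VII). It is aimed at epigenomics analysts
working with paired Illumina-450k-style Beta matrices and a per-donor
severity covariate, and at methodologists who want a fully simulated
test bed for paired drift screens.

## The method

For each probe, Beta values β ∈ [0, 1] are logit-transformed to M values,
*M* = log₂(β / (1 − β)), and the intra-pair difference
ΔM = M(A) − M(N) is computed per donor. A probe is called a grade-CpG when
all three criteria hold:

1. **Effect size** — |mean ΔBeta(grade VII) − mean ΔBeta(grade III)| > 0.05
   (strict).
2. **Correlation** — Spearman ρ of ΔM against numeric grade (3–7) with
   p < 0.05; no significant Spearman correlation of ΔM with donor age, sex
   or post-mortem time; and a significant partial-F grade term in the
   least-squares fit ΔM ~ grade + age + sex + post-mortem time.
3. **Baseline stability** — no significant Welch-t difference between the
   normal-tissue M values of grade-VII and grade-III donors, excluding
   probes whose reference tissue itself moves with grade.

Direction is *hyper* (progressive hypermethylation) when ρ > 0. The
array-wide Bonferroni threshold (0.05 / n tested) is reported alongside the
per-probe screen. Downstream analyses cover genomic context (gene
compartments, CpG-island relation, baseline methylation strata, SNP
proximity, gene-set overlap), Ward biclustering of the called ΔBeta matrix,
and integration with heterologous expression data (case-insensitive
ortholog matching, fold-change filtering, per-compartment Pearson
correlation of ρ against log₂ fold change) plus WGBS concordance.

A synthetic-cohort generator (`simulate_cohort_data()`) plants grade-drift,
constant-offset, covariate-confounded and baseline-unstable probe classes
with known ground truth, so every stage is testable without external data.

## Worked example

```r
library(methdrift)

sim   <- simulate_cohort_data(generator_config(seed = 42))
calls <- call_grade_cpgs(sim$beta, sim$cohort, sim$annotation, sim$blacklist)
calls
#> grade-CpG calls: 188 / 9950 tested probes (50 blacklisted, 0 missing-dropped)
#>   50.5% hypermethylated with grade; mean extreme |Delta-Beta| 0.146
#>   Bonferroni threshold 5.03e-06; 0 probe(s) below it
```

The default cohort has 15 donor pairs (nine at grade VII) and 10,000 probes
with 100 hypermethylating and 100 hypomethylating drift probes planted at a
ΔBeta amplitude of 0.15, among constant, confounded and unstable decoys.
188 calls at ~93% precision is the expected operating point under the
default measurement noise; the decoy classes are rejected by the covariate
and stability screens.

Per-probe records are a tidy tibble:

```r
dplyr::select(tidy(calls), probe_id, rho, p_grade, extreme_effect,
              direction, is_grade_cpg)
#> # A tibble: 9,950 × 6
#>   probe_id    rho  p_grade extreme_effect direction is_grade_cpg
#>   <chr>     <dbl>    <dbl>          <dbl> <chr>     <lgl>
#> 1 cg000001 -0.309 0.263           0.0218  hypo      FALSE
#> 2 cg000002  0.804 0.000307        0.135   hyper     TRUE
#> 3 cg000003 -0.351 0.199           0.00824 hypo      FALSE
#> # …
```

`glance(calls)` gives the one-row run summary (counts, % hyper, effect
range, Bonferroni report); `autoplot(calls)` draws the ρ-versus-effect
landscape. Clustering and integration chain off the same objects:

```r
called <- dplyr::filter(tidy(calls), is_grade_cpg)$probe_id
bc <- ward_bicluster(
  intra_pair_delta(dplyr::filter(sim$beta, probe_id %in% called),
                   sim$cohort, "Beta"))
autoplot(bc)                       # low/high-grade donor blocks

de  <- simulate_expression_data(sim$truth, sim$annotation,
                                coupling_slope = -1, noise_sd = 0.3, seed = 7)
def <- filter_de(de, 2)
map <- map_orthologs(unique(unlist(sim$annotation$gene_symbols)), def$gene)
compartment_correlation(tidy(calls), sim$annotation, def, map)
#> # A tibble: 1 × 4
#>   group        n      r        p
#> 1 Promoter    23 -0.988 2.04e-18
```

A negative promoter correlation means promoter hypermethylation tracks
reduced expression of the orthologous gene — the canonical regulatory
reading.

The same stages run from a shell via the wrapper in `inst/scripts/`:

```sh
Rscript inst/scripts/methdrift all --config config.yaml --out results/
```

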