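# coevomut

Detects co-evolving residue pairs in ortholog multiple sequence alignments
and tests whether those *correlated positions* are enriched in
disease-associated point mutations — the statistical machinery behind the
observation that co-evolution, like conservation, marks functionally
vulnerable sites in human proteins. It is aimed at computational biologists
studying the genotype–phenotype link of missense variants, and at anyone
who needs a tested, seeded implementation of OMES co-evolution scoring plus
log-odds enrichment statistics over per-residue annotations.

## The statistics

**Co-evolution.** For alignment columns $i, j$, over the $n$ rows ungapped
at both columns, with joint counts $N_{obs}(x,y)$ and expected counts
$N_{ex}(x,y) = C_i(x)\,C_j(y)/n$ from the column marginals:

$$\mathrm{OMES}(i,j) = \sum_{(x,y)\ \mathrm{observed}} \frac{(N_{obs}(x,y) - N_{ex}(x,y))^2}{n}$$

Per protein of length $L$, the top $L \times k$ pairs (default $k = 5$)
are selected; a position is *correlated* if it appears in at least one
selected pair.

**Enrichment.** Every analysis reduces to a 2×2 table — $n$ residues, $d$
disease-labelled, $c$ predictor-positive, $dc$ both — summarized by the
base-2 log rate ratio

$$\mathrm{LOD} = \log_2\frac{dc/c}{d/n}$$

with one-sided Fisher exact tests, a 1000-fold permutation null of the
disease labels, and a column bootstrap for robustness. Conservation
(BLOSUM62-based and fractional identity), structural contacts (side-chain
5.5 Å / Cβ 8.0 Å, sequence window 10), solvent accessibility classes,
correlation-network degree, and evolutionarily tolerated (benign)
substitutions provide the stratifications and the negative control.

A synthetic-data module generates ortholog clusters with planted
co-evolving pairs, conserved columns, label enrichment, and toy 3D
structures with known ground truth, so every statistic is validated by
parameter recovery. See the methods vignette
(`vignettes/coevolution-disease-enrichment.Rmd`) for models, assumptions
and design choices.

## Worked example

The bundled demo generates a small synthetic cohort (8 proteins × 120
positions, 6 planted co-evolving pairs each, disease labels enriched
1.66-fold at planted positions) and runs the full pipeline:

```r
library(coevomut)
res <- run_pipeline(demo_config(seed = 1))
tidy(res$global)
#> # A tibble: 1 × 8
#>       n     d     c    dc  fold   lod p_fisher defined
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>    <dbl> <lgl>
#> 1   960   154    96    24  1.56 0.640   0.0114 TRUE
glance(res$permutation)
#> # A tibble: 1 × 7
#>   observed p_empirical null_mean null_sd null_q025 null_q975  reps
#>      <dbl>       <dbl>     <dbl>   <dbl>     <dbl>     <dbl> <dbl>
#> 1    0.640      0.0149  -0.00740   0.297    -0.623     0.515   200
```

Of 960 residues, 154 carry a disease label and 96 are called correlated;
24 are both, i.e. a correlated residue is 1.56× as likely to be a disease
site as a random residue (LOD 0.64, near the planted $\log_2 1.66 = 0.73$
given the cohort's sampling error of about ±0.25). The observed LOD sits
outside the permutation background (empirical p ≈ 0.015). `res` also
carries per-protein LODs, conservation sweeps, the k-sweep, the
degree-stratified LODs and a machine-readable report; rerunning with the
same seed reproduces every output byte for byte.

Plot helpers: `autoplot(res$permutation)`, `plot_per_protein_lods()`,
`plot_conservation_sweep()`, `plot_k_sweep()`, `plot_degree_lod()`.

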