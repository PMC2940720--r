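---
title: "Residue co-evolution and disease-mutation enrichment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue co-evolution and disease-mutation enrichment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(coevomut)
library(dplyr)
```

## The question

Point mutations that swap a single amino acid can be harmless or can cause
severe inherited disease. Evolutionary conservation of a position is the
classical predictor of its vulnerability. This package implements a second,
complementary signal: *co-evolution*. If two alignment columns change in a
coordinated way across orthologs, the positions are likely coupled —
structurally (a physical contact maintained by compensatory substitutions)
or functionally (an allosteric path, a shared binding surface). The package
quantifies whether such correlated positions are enriched in known
disease-mutation sites, beyond what conservation alone explains.

The pipeline goes from (1) pre-aligned ortholog clusters with a designated
human reference row, and (2) per-residue disease/functional labels, to
co-evolution calls, conservation scores, structural stratifications, and
log-odds enrichment statistics with permutation and bootstrap nulls.
Because genome-scale mutation databases and curated ortholog sets are
licensed resources, a synthetic-data module generates inputs with the same
statistical structure and known ground truth; every recovery claim below is
a claim about that generator.

## Alignment preprocessing

Automatically derived ortholog clusters carry fragments and near-duplicate
sequences that bias column statistics. Four filters run in order:

* **Coverage** (`coverage_filter()`, default 0.80): a non-reference row
  must cover at least 80% of the reference's positions. Fragments mimic
  conservation (their aligned part is the conserved core) and waste rows.
* **Redundancy** (`redundancy_filter()`, default 0.90): while any pair of
  rows exceeds 90% identity, one member — never the reference — is removed
  at random (seeded; pairs visited in row order, so a seed fully determines
  the result). Identity is computed on the alignment projection, over
  columns where at least one member is ungapped; for the near-identical
  pairs this filter targets, this is equivalent to re-aligning the pair and
  much cheaper.
* **Size gate** (`size_gate()`, default 30): column-pair statistics on
  fewer than ~30 rows are noise; a stringent analysis uses 125.
* **Cap** (`cap_sample()`, default 300): clusters above 300 rows are cut to
  the reference plus a seeded sample of 299, bounding the quadratic cost of
  pair scoring.

All filters are idempotent, keep the reference row, and never touch
columns. The coverage filter is applied to the alignment as given (not to a
re-trimmed alignment); for the synthetic inputs the two are identical.

## The OMES co-evolution statistic

For columns $i, j$ of an alignment, let $n$ be the number of rows ungapped
at both columns (*pairwise-complete*: rows are dropped per pair, not
listwise, preserving power in patchy alignments), $N_{obs}(x,y)$ the count
of rows showing residues $(x, y)$, and $C_i(x), C_j(y)$ the column
marginals over those rows. With $N_{ex}(x,y) = C_i(x) C_j(y) / n$,

$$\mathrm{OMES}(i,j) \;=\; \sum_{(x,y)\,\text{observed}}
  \frac{\big(N_{obs}(x,y) - N_{ex}(x,y)\big)^2}{n},$$

a chi-square-style goodness-of-fit quantity in which the sum runs over
residue pairs actually observed. It is symmetric, invariant under row
permutation, and zero for any pair involving a constant column. Only
columns that map to reference positions are scored — disease labels live on
the reference — and pairs with fewer than `min_valid = 10` complete rows
are skipped as degenerate. The all-pairs scan is compiled (Rcpp); the test
suite checks it against an independent brute-force R implementation to
1e-9 on a thousand random alignments.

Per protein of reference length $L$, the top $L \times k$ pairs by score
are selected (`select_top_pairs()`; ties broken deterministically by score,
then position). A position is **correlated** if it appears in at least one
selected pair. The constant $k = 5$ is the field's common default;
`k_sweep()` recomputes the selection and the global LOD across $k$ values —
on real-scale data the LOD rises steeply up to $k \approx 5$–$10$ and then
flattens, and the correlated sets are nested in $k$ by construction. No
minimum sequence separation is imposed at selection time (a separation
window belongs to the *contact* analysis, not the correlation analysis);
`omes_pairs(min_separation=)` exposes one for users who want it.

## Conservation scores

Two per-position measures, both relative to the human reference residue
$a_r$ and both in $[0, 1]$:

* **BLOSUM conservation** $S_B = \max\!\big(0, \sum_s B(a_r, a_s) \,/\,
  \big((N - 1 - g)\, B(a_r, a_r)\big)\big)$, summing BLOSUM62 scores
  between the reference residue and every ungapped ortholog residue in the
  column and normalizing by the maximum attainable sum ($g$ counts ortholog
  gaps). BLOSUM scores can be negative, hence the clamp at zero.
* **Fractional identity** $S_I$: the fraction of ungapped ortholog residues
  identical to the reference.

Gaps are excluded from numerator and denominator in both measures (the
natural reading for $S_I$, mirroring $S_B$'s explicit gap term). Columns
where every ortholog is gapped are undefined and are excluded from
conservation-stratified analyses rather than imputed.

`conservation_filter()` supports both stratification directions:
`at_most t` removes the top conserved columns (testing whether the
correlation signal survives without them), `at_least t` uses conservation
itself as the predictor. `conservation_sweep()` walks a grid of cutoffs —
$t \in \{1.00, 0.95, \ldots, 0.05\}$ by default; the grid is a package
choice, any decreasing grid works — and recomputes the LOD at each step.

## The enrichment statistic

Everything funnels into a 2×2 table per analysis: $n$ residues in the
universe, $d$ disease-labelled, $c$ predictor-positive (correlated,
conserved, in contact, ...), $dc$ both. The **LOD** is the base-2 log of
the rate ratio

$$\mathrm{LOD} = \log_2 \frac{dc/c}{d/n},$$

i.e. how many times more likely a predictor-positive residue is to carry a
disease label than a random residue. The rate-ratio (relative-risk) form,
not the odds ratio, is used throughout: it reproduces the published
summary tables at printed precision from their printed counts, which the
odds-ratio form does not. $dc = 0$ yields $-\infty$ (flagged), the
convention used for per-protein scores; $c = 0$ or $d = 0$ is an error.

Significance is assessed two ways:

* **Fisher's exact test** (`fisher_test()`), one-sided (`greater`) by
  default since the hypothesis is enrichment; two-sided by flag.
* **Permutation null** (`permutation_null()`): disease tags are shuffled
  over the entire residue universe and the LOD recomputed (1000 reps by
  default), giving the empirical background the observed value is judged
  against. The empirical p uses the add-one correction
  $(1 + \#\{null \ge obs\})/(reps + 1)$, so it is never zero. Under a full
  shuffle the overlap count is exactly hypergeometric; the test suite
  checks the null's quartiles against that closed form.

Robustness of the observed LOD is assessed by a **column bootstrap**
(`column_bootstrap()`): reference positions are resampled with replacement
within each protein and the pooled LOD recomputed, yielding a percentile
interval. No multiple-testing correction is applied across strata or sweep
points — each stratum value is reported raw, as is conventional for these
descriptive sweeps — and this is deliberately documented rather than
hidden.

Per-protein LODs (`per_protein_lods()`) flag the arithmetic annoyance of
small proteins: with one or two known disease mutations the chance that
none lands in a correlated position is large, producing $-\infty$ scores
that are excluded from summary statistics rather than averaged.

## Structural stratification

`contact_map()` declares residues $i, j$ in contact when the smallest
distance between their usable atoms is at most the threshold *and*
$|i - j| > 10$ (the window removes trivial contacts inside helices and
turns). Two atom selections: all non-hydrogen side-chain atoms at 5.5 Å
(glycine falls back to Cα), or Cβ-only at 8.0 Å (glycine again Cα).
`contact_overlap()` reports which selected pairs coincide with contacts
and extracts the non-contact correlated positions for the negative-space
analysis. `classify_accessibility()` converts accessible surface area to
relative solvent accessibility using the Tien et al. (2013) theoretical
maxima and discretizes at RSA ≤ 0.09 (buried) and ≥ 0.36 (exposed); the
cutoffs are exposed as arguments since conventions differ, and downstream
conclusions should be checked against nearby cutoffs. DSSP output is
consumed as a file (`read_accessibility_tsv()`); the package never runs
DSSP, nor computes ASA from coordinates.

## Benign substitutions as a negative control

`extract_benign()` collects amino-acid differences observed in orthologs at
least 95% identical to the reference (covering at least 80% of it):
substitutions evolution has tolerated in a near-identical context, hence
very unlikely to be disease-causing. These positions should be *depleted*
among correlated positions; `benign_control_lod()` recomputes the
enrichment statistic with them as the label, expecting a clearly negative
LOD where the co-evolution signal marks functional constraint. Taxon
filtering (e.g. restricting to mammals) is delegated to the cluster
manifest; the package does not resolve taxonomy.

## The synthetic generator

`generate_cluster()` builds an alignment from a `sim_config()` with three
disjoint column classes:

* **Background** columns: each ortholog row keeps the reference residue
  with probability `base_identity` (default 0.5), otherwise draws uniformly
  from the other 19 amino acids. A per-column categorical model — not
  tree-based evolution — is deliberately simple and sufficient for testing
  column statistics.
* **Conserved** columns: the same model at `conserved_identity`
  (default 0.98).
* **Planted co-evolving pairs**: each row draws one of the
  `coupling_states` (default (A,V) / (S,T)); with probability
  `coupling_fidelity` both columns show the matched state, otherwise the
  second column switches to a *different* state. Fidelity 1 makes the two
  columns' state partitions identical row by row; fidelity 0.5 with two
  states makes them exactly independent, which the tests verify against
  construction-independent cross pairs.

Gaps are inserted at `gap_rate` in ortholog rows only — the reference row
is always gap-free, so reference-position bookkeeping stays total and
alignment columns coincide with reference positions. Planted pair members
are placed with sequence separation above the contact window so the
structural analyses never mask them. `assign_disease_labels()` labels
background positions at `background_disease_rate` (default 0.019, the
background rate scale of the genome-wide survey data this emulates) and
planted-pair positions at `disease_fold` times that rate (default 1.66,
the enrichment scale observed in such data), clamped at 1 with a warning.
`generate_toy_structure()` lays residues on a line at 3.8 Å backbone
spacing with one pseudo side-chain atom each and moves the side-chain atom
of one pair partner to 4.0 Å for the chosen fraction of pairs; contact
pairs end below 5.5 Å, all other planted pairs stay above 8.0 Å, so both
contact definitions agree on the planted pairs by construction.

What the generator does **not** emulate: phylogenetic correlation between
rows (every row is independent given the column model), indel structure
(gaps are iid), compositional biases, and any coupling between conservation
and disease labels (conserved columns are labelled at the background rate).
Passing recovery tests therefore show that the statistics recover planted
signal under the stated noise model — not that real mutation databases
behave this way.

## Recovery experiments: design and problem sizes

The test suite runs four planted-truth experiments; their parameters were
fixed by power analysis before running and are not tuned:

* **Oracle equivalence**: 1000 random alignments (10–50 rows, 5–30
  columns, 10% gaps, alphabet size 4–20); the compiled scan must match the
  brute-force oracle within 1e-9.
* **Pair recovery**: 10 clusters of 100 rows × 200 columns, 8 planted
  pairs at fidelity 0.95; precision of the top-8 selection must reach 0.9.
* **LOD recovery**: 200 proteins × 250 positions (50,000 residues), 2
  planted pairs per protein, fidelity 0.99, fold 1.66. Two sizing
  constraints drive the design: the LOD denominator is the *global* rate,
  which includes the enriched subset, so the planted fraction must be small
  (here 1.6%, an expected attenuation of −0.015 LOD); and the planted
  subset's label count must have small relative error, so the label rate is
  elevated to 0.55 (expected count ≈ 730, binomial error ≈ 0.016 LOD). The
  recovered global LOD must land within ±0.05 of $\log_2 1.66 = 0.731$.
  The selection size equals the planted pair count per protein: the
  experiment measures enrichment recovery at matched selection, while the
  dilution behaviour of over-selection is measured separately by the
  k-sweep.
* **Null calibration**: 20 cohorts at fold 1 (8 proteins × 150 positions
  each); the observed LOD must fall inside the central 95% of its own
  1000-permutation null in at least 18 of 20 — the binomial tolerance
  acknowledges that a 95% interval misses 5% of the time.

## Worked demo

`demo_config()` bundles a small cohort (8 proteins × 120 positions, 60
rows, 6 planted pairs at fidelity 0.95, fold 1.66 over a 0.15 background
rate — elevated so a cohort this small has enough labels to stratify) and
`run_pipeline()` executes every stage:

```{r demo}
res <- run_pipeline(demo_config(seed = 1))
tidy(res$global)
glance(res$permutation)
res$k_sweep
```

The demo selects as many pairs as were planted; the k-sweep shows what
over-selection does to the LOD. At a cohort this size the global LOD has a
sampling error of roughly ±0.25, so individual runs scatter visibly around
the planted value — the 50,000-residue recovery experiment above is the
calibrated check. Writing the same configuration to disk twice produces
byte-identical outputs; all stochastic steps derive from the single master
seed.

## Numerical and interface choices

* Positions are 1-based on the human reference in every interface
  (mutation nomenclature style); alignment columns are internal and
  converted at the boundary. Reference-gap columns map to no position and
  are excluded from scoring.
* `-Inf` LODs are carried, flagged, and excluded from summaries — never
  silently dropped or imputed.
* Published summary tables whose counts are reproduced by
  `reproduce_published_tables()` are shipped as a plain-text fixture; two
  of the printed LOD values in the original tables disagree with their own
  printed counts in the third decimal (0.735 vs a computed 0.7376 for the
  stringent-cutoff row, 0.78 vs 0.7891 for one conservation-filtered row);
  the recomputation reports the value implied by the counts.
* Known limitations: no tree-aware correlation statistic (OMES is
  deliberately tree-agnostic; tree-aware variants are extension points),
  no mutual-information/DCA/APC scoring, no ASA computation, no aligner
  invocation, and the generator's independence assumptions listed above.
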