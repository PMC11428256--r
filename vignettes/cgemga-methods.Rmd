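---
title: "Conserved gene-expression modules by genetic-algorithm biclustering: models and methods"
author: "cgemga package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved gene-expression modules by genetic-algorithm biclustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgemga)
```

## The problem

Bulk and single-cell RNA-seq experiments routinely produce expression
matrices with thousands of genes measured over hundreds of samples. Genes
that drive a disease process are often co-expressed only in a *subset* of
samples — a tumour subtype, a treatment arm — so clustering methods that
demand coherence across *all* samples miss them. Biclustering searches for
submatrices (a subset of genes crossed with a subset of samples) that are
internally coherent.

`cgemga` implements one family of biclustering models: **conserved
gene-expression modules** (xmotifs). Expression values are discretized
per gene into a small number of *states* (by default three: low, baseline,
high). A conserved module is a set of gene–state pairs $G$ together with a
sample set $C$ such that every sample in $C$ shows exactly the paired
state for every gene in $G$. On top of this combinatorial definition the
package scores candidate modules with the **Mean Squared Residue**,

$$
H(I,J) \;=\; \frac{1}{|I||J|}\sum_{i\in I,\,j\in J}
\bigl(a_{ij} - a_{iJ} - a_{Ij} + a_{IJ}\bigr)^2 ,
$$

where $a_{iJ}$, $a_{Ij}$ and $a_{IJ}$ are the row, column and grand means
of the submatrix over the *continuous* values. $H$ is zero exactly when
the submatrix is additive ($a_{ij} = r_i + c_j$) and grows with
incoherence. MSR is always computed on the original expression values:
discretized states are categorical, and a residue of integer state codes
would be scale-arbitrary.

## Search algorithms

### The seed mechanism

Both searches are driven by *seeds*. A seed is a sample $c$ plus a
discriminating sample set $D$ of size $s_d$ containing $c$. The seed
induces a module deterministically (`build_module()`):

* $G$ = every gene whose state agrees with its state in $c$ across all of
  $D$;
* $C$ = every sample that agrees with $c$ on all gene–states in $G$.

$C$ always contains $D$, and enlarging $D$ can only shrink $G$. An empty
$G$ matches all samples vacuously; such modules are never selected.
Modules whose $C$ covers less than a fraction $\alpha$ of the samples are
discarded ($\alpha$ is always measured against the *original* sample
count, so the filter keeps its meaning during iterative extraction).

### Baseline CGEM

`find_largest_module()` draws `num_seeds` random seeds and keeps the
module with the most conserved genes (ties: larger $|C|$, then lower MSR,
then discovery order — the chain is fixed so results are reproducible and
so exhaustive enumeration is a valid oracle). `extract_biclusters()`
repeats the search, removing the matched samples of each module found,
and finally flags the module with the largest area $|G|\times|C|$.

### CGEMGA

`run_cgemga()` replaces random seed drawing with a genetic algorithm.
A chromosome is the integer vector $[c, d_2, \dots, d_{s_d}]$ — a seed.
Each of `num_restarts` restarts evolves a population under tournament
selection, single-point crossover, per-locus mutation (resampling an index
among unused samples, with repair of duplicates) and elitism, stopping at
`max_generations` or after `patience` generations without improvement.
The per-restart winner is the best module over every chromosome the
restart evaluated; winners are pooled across restarts, best first, and
the best restart's fitness trace is reported.

### The fitness function

Fitness is based on the MSR of the induced module, with two corrections
that the implementation forced:

1. **Single-gene degeneracy.** Any $1\times n$ or $n\times 1$ submatrix
   has $H = 0$ identically, so the raw-MSR optimum is always a degenerate
   single-gene module. Modules with fewer than `min_genes` (default 2)
   conserved genes get the $+\infty$ sentinel, like the $\alpha$ filter.
2. **Small-module bias.** Under an additive model with i.i.d. noise of
   variance $\sigma^2$, the raw MSR of a module has expectation
   $\sigma^2(1-1/|I|)(1-1/|J|)$ and an estimation spread that grows as
   the residual degrees of freedom $df = (|I|-1)(|J|-1)$ shrink.
   A search that minimizes raw MSR over thousands of variable-size
   candidates therefore collapses onto tiny submatrices twice over: their
   expected MSR is smaller, and the minimum over many high-variance
   estimates is smaller still (a winner's-curse effect; both effects are
   easy to reproduce on the synthetic benchmark below). Fitness is
   therefore the upper confidence bound of the residual variance,
   $$\mathrm{fit} = \frac{H\,|I||J|}{\chi^2_{q}(df)},$$
   with level $q$ Bonferroni-adjusted for the search's evaluation budget
   ($q = 0.05 / (\text{restarts}\times\text{population}\times
   (\text{generations}+1))$). At fixed module size this is a monotone
   transform of $H$ — the ordering the method prescribes — while across
   sizes it compares modules fairly. Reported modules always carry their
   raw MSR; the adjustment only steers the search.

Ties in fitness are broken toward the larger module area, and ties among
identical restart winners toward the earlier-converging restart.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `num_states` (q) | 3 | expression states per gene; 3 distinguishes down/baseline/up |
| `method` | `equal_width` | per-gene interval construction (see below) |
| `alpha` | 0.05 | minimum fraction of samples a module must cover |
| `discriminating_size` (s_d) | 7 | seed set size, following the xmotif lineage |
| `num_seeds` / `num_restarts` (n_s) | 10 | multistarts / GA restarts |
| `population_size` (n) | 50 | chromosomes per generation |
| `max_generations` (MAX) | 100 | generation cap per restart |
| `crossover_prob` | 0.8 | single-point crossover probability |
| `mutation_prob` | 0.1 | per-locus mutation probability |
| `elitism_count` | 1 | elites copied unchanged |
| `tournament_size` | 3 | selection pressure; 3 gives the takeover speed needed for convergence within a few generations |
| `min_genes` | 2 | smallest informative module |
| `patience` | 10 | early-stop stall length |

All values are dimensionless; expression values are assumed
pre-normalized (log-scale) and are never transformed by the package.

**Why equal-width intervals by default.** A conserved module concentrates
many samples of its genes in a single state, so the state's occupancy
exceeds $1/q$. Per-gene quantile (equal-frequency) cuts are *forced* to
fall inside such a state and split it, destroying exactly the
conservation the search is looking for. Equal-width cuts on the per-gene
range do not have this failure mode. Equal-frequency binning remains
available (`discretize(..., method = "equal_frequency")`, type-7
quantile cuts, duplicate cuts collapsed) and is the better choice when
states should adapt to skewed per-gene distributions *without* a
dominant block. Intervals are left-closed; a value exactly at a cut joins
the upper interval; constant genes collapse to a single state. Missing
values are rejected at load — the method defines no imputation rule and
failing loudly is safer than inventing one.

## The synthetic benchmark

`simulate_planted_matrix()` generates the self-contained test bed:

* **Background**: each cell's state is uniform over the $q$ states
  (`"shuffled"` gives balanced states per gene instead); the continuous
  value is uniform within the state's interval. State centers sit
  `state_separation = 2` apart — a four-fold change between adjacent
  states on a log2 scale, a realistic strong-regulation contrast.
* **Planted block**: `module_genes` genes hold one fixed state across
  `module_samples` samples; continuous values are state-center + per-gene
  offset + per-sample offset (uniform on ±0.1) + Gaussian noise
  (`noise_sd`). The block is additive, so its MSR is 0 at `noise_sd = 0`
  and the MSR optimum coincides with the planted truth. The ±0.1 offset
  range keeps planted cells at least ~0.6 units from the nearest
  discretization cut, so states survive noise up to about
  `noise_sd = 0.25` almost surely (margin ≈ 2.4 standard deviations).

`recovery_score()` reports gene and sample Jaccard overlap with the
planted truth; `make_census()` builds a synthetic driver-gene census
(planted genes plus decoys) so the Fisher's-exact enrichment evaluation
can be exercised end to end.

What the generator does *not* emulate: realistic marginal expression
distributions, gene–gene correlation outside the block, batch structure,
or dropout. Passing the benchmark shows the pipeline recovers an
identifiable planted signal; it does not certify performance on real
tumour data.

## Evaluation

`build_contingency()` classifies the gene universe against a census
(census genes the experiment could not have found are dropped first), and
`fisher_exact()` computes the exact hypergeometric tail in log-factorial
space — one-sided enrichment (`"greater"`) by default, since that is the
only direction with biological meaning here; two-sided is available
behind a flag. `summarize_runs()` reports mean ± sample standard
deviation of per-run p-values and MSR values in the conventional
"1.54 × 10^-4" scientific format, flagging significance at p < 0.05.

## Numerical and design notes

* MSR accumulates in row-major order with vectorized column operations;
  results are bit-reproducible on identical input and agree with a naive
  double-loop evaluation to well below 1e-10.
* All randomness flows from a single `rng_seed` per entry point;
  identical seeds give byte-identical module exports.
* `s_d` is clamped to the number of available samples; during iterative
  extraction the remaining-sample pool shrinks but α keeps referring to
  the original sample count.
* The sentinel fitness for filtered modules is `+Inf`; a restart whose
  every chromosome is sentinel is discarded, and a run in which every
  restart is discarded returns an empty module list with a warning
  record rather than an error.
* Test-bed scale: the bundled checks use 200-gene × 40-sample matrices
  with one planted 20 × 12 module (plus 60 × 20 instances in the unit
  tests) — large enough for the search to face ~10^7 possible seeds,
  small enough that exhaustive oracles remain feasible on the small
  instances.

## Known limitations

* Raw MSR favours small modules under noise; the confidence-bound
  fitness removes the systematic part of that bias, but extremely noisy
  data (`noise_sd` ≳ 0.5 at the default scale, i.e. noise comparable to
  half the state separation) still degrades recovery, mainly because the
  discretized states themselves flip.
* One module is reported per restart; overlapping or nested modules are
  only found if different restarts converge to them.
* The α and `min_genes` filters are hard thresholds, not significance
  tests; the enrichment stage, not the search, carries the statistical
  guarantees.
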