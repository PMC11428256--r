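# cgemga

Biclustering of gene-expression matrices through **conserved
gene-expression modules**, with a genetic-algorithm search (CGEMGA) on
top of the classic multistart baseline (CGEM).

## The problem and the model

Disease-relevant genes are often co-expressed only in a subset of
samples, which global clustering cannot see. `cgemga` looks for
*conserved modules* (xmotifs): after discretizing each gene's expression
into a few states (low / baseline / high by default), a module is a set
of gene–state pairs `G` plus a sample set `C` such that every sample in
`C` shows exactly the paired state for every gene in `G`.

Candidate modules are scored by the **Mean Squared Residue** of the
underlying continuous submatrix,

    H(I,J) = 1/(|I||J|) * sum_{i in I, j in J} (a_ij - a_iJ - a_Ij + a_IJ)^2,

which is 0 for perfectly additive (coherently co-expressed) blocks.

Two searches are provided:

* **CGEM** (`find_largest_module()`, `extract_biclusters()`): random
  seeds, keep the module with the most conserved genes, iteratively
  remove matched samples.
* **CGEMGA** (`run_cgemga()`): a genetic algorithm evolves *seeds*
  (a sample plus a discriminating sample subset) under an MSR-based
  fitness with tournament selection, crossover, mutation and elitism.
  The fitness is the upper confidence bound of the module's residual
  variance — a monotone transform of MSR at fixed module size that stays
  fair across sizes (see the methods vignette for the derivation).

Discovered gene sets are evaluated against a driver-gene census with
Fisher's exact test (`build_contingency()`, `fisher_exact()`), and a
planted-module simulator (`simulate_planted_matrix()`) plus Jaccard
recovery scoring (`recovery_score()`) make the whole pipeline testable
without external data.

## Worked example

```r
library(cgemga)

# a 200-gene x 40-sample matrix with one planted 20 x 12 module
sim  <- simulate_planted_matrix(planted_module_spec(noise_sd = 0.1, rng_seed = 42))
disc <- discretize(sim$values)                       # q = 3, equal-width
res  <- run_cgemga(disc, sim$values, ga_params(rng_seed = 42))
res
#> cgemga_result: 10 module(s) from 10 restart(s), 7888 fitness evaluations
#>   best: |G| = 20, |C| = 12, MSR = 0.007996 (converged at generation 4)

best <- res$modules[[1]]
recovery_score(best, sim$truth)
#>   gene_jaccard sample_jaccard
#>              1              1

census <- make_census(sim$truth, extra_decoys = 100)
tab <- build_contingency(best$gene_ids, census, rownames(sim$values))
tab
#> contingency_table (N = 200):
#>           census not census
#> found         20          0
#> not found    100         80
format_scientific(fisher_exact(tab, "greater"))
#> [1] "1.83 × 10^-5"
```

The best module recovers the planted block exactly (both Jaccard indices
are 1), its MSR is small (the block is additive up to the simulated
noise), the GA's best fitness stopped improving at generation 4, and the
recovered genes are significantly enriched for the synthetic census at
p < 0.05.

The same pipeline is scriptable from the shell:

```sh
cgemga simulate --out fixtures/ --seed 42 --decoys 100
cgemga run --input fixtures/matrix.tsv --algorithm cgemga --seed 42 --out outdir/
cgemga evaluate --modules outdir/cgemga_modules.json \
                --census fixtures/census.txt --universe fixtures/matrix.tsv
cgemga bench --instances 10 --noise 0.25
```

(the `cgemga` executable is installed under `exec/` in the package
library; call it via `Rscript $(Rscript -e 'cat(system.file("exec","cgemga",package="cgemga"))')`).

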