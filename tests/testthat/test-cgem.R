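# a 5x5 state matrix in which genes 1:3 share their seed states across
# samples 1:3 only; genes 4:5 and samples 4:5 break agreement
toy_states <- function() {
  st <- matrix(0L, 5, 5)
  st[1, ] <- c(1L, 1L, 1L, 0L, 2L)
  st[2, ] <- c(2L, 2L, 2L, 2L, 0L)
  st[3, ] <- c(0L, 0L, 0L, 1L, 1L)
  st[4, ] <- c(0L, 1L, 2L, 0L, 1L)
  st[5, ] <- c(2L, 0L, 1L, 1L, 0L)
  st
}

test_that("build_module matches the agreement predicate on a toy matrix", {
  disc <- as_disc(toy_states())
  mod <- build_module(disc, 1, 1:3)
  expect_equal(mod$genes, 1:3)
  expect_equal(mod$states, c(1L, 2L, 0L))
  expect_equal(mod$samples, 1:3)
  oracle <- module_oracle(toy_states(), 1, 1:3)
  expect_equal(mod$genes, oracle$G)
  expect_equal(mod$samples, oracle$C)
})

test_that("a singleton discriminating set matches full state vectors", {
  st <- toy_states()
  st[, 5] <- st[, 1]  # make sample 5 a clone of sample 1
  disc <- as_disc(st)
  mod <- build_module(disc, 1, 1)
  expect_equal(mod$genes, 1:5)  # every gene agrees with itself at c
  expect_equal(mod$samples, c(1L, 5L))
})

test_that("a fully conserved matrix yields the all-covering module", {
  st <- matrix(rep(c(0L, 1L, 2L), 4), 3, 4)
  disc <- as_disc(st)
  mod <- build_module(disc, 2, c(1, 2, 3, 4))
  expect_equal(mod$genes, 1:3)
  expect_equal(mod$samples, 1:4)
})

test_that("an empty G yields vacuous agreement over all samples", {
  st <- rbind(c(0L, 1L, 2L), c(1L, 2L, 0L))
  disc <- as_disc(st)
  mod <- build_module(disc, 1, 1:3)
  expect_equal(mod$n_genes, 0L)
  expect_equal(mod$samples, 1:3)
})

test_that("module msr agrees with direct msr on the continuous values", {
  set.seed(21)
  x <- random_matrix(8, 6)
  disc <- discretize(x, 2)
  mod <- build_module(disc, 1, c(1, 3), values = x)
  if (mod$n_genes > 0)
    expect_equal(mod$msr, msr(x, mod$genes, mod$samples))
})

test_that("returned modules satisfy soundness and sample maximality", {
  set.seed(22)
  for (rep in 1:10) {
    st <- matrix(sample(0:1, 10 * 7, replace = TRUE), 10, 7)
    disc <- as_disc(st)
    c0 <- sample(7, 1)
    D <- unique(c(c0, sample(7, 3)))
    mod <- build_module(disc, c0, D)
    if (mod$n_genes == 0) next
    for (s in mod$samples)
      expect_true(all(st[mod$genes, s] == mod$states))
    for (s in setdiff(seq_len(7), mod$samples))
      expect_false(all(st[mod$genes, s] == mod$states))
  }
})

test_that("enlarging D never enlarges G", {
  set.seed(23)
  for (rep in 1:10) {
    st <- matrix(sample(0:2, 12 * 8, replace = TRUE), 12, 8)
    disc <- as_disc(st)
    c0 <- sample(8, 1)
    D1 <- unique(c(c0, sample(8, 2)))
    D2 <- unique(c(D1, sample(8, 3)))
    g1 <- build_module(disc, c0, D1)$genes
    g2 <- build_module(disc, c0, D2)$genes
    expect_true(all(g2 %in% g1))
  }
})

test_that("exhaustive multistart equals brute-force enumeration", {
  set.seed(24)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    m <- sample(5:8, 1)
    x <- random_matrix(n, m)
    disc <- discretize(x, 2)
    s_d <- sample(2:3, 1)
    params <- search_params(num_seeds = 1, discriminating_size = s_d,
                            alpha = 0.05)
    got <- find_largest_module(disc, x, params,
                               seeds = enumerate_seeds(seq_len(m), s_d))
    oracle <- largest_module_oracle(disc$states, x, s_d, 0.05)
    if (is.null(oracle)) {
      expect_null(got)
    } else {
      expect_equal(got$genes, oracle$G)
      expect_equal(got$samples, oracle$C)
      expect_equal(got$msr, oracle$msr)
    }
  }
})

test_that("alpha = 1 only admits modules covering every sample", {
  st <- matrix(sample(0:2, 6 * 6, replace = TRUE), 6, 6)
  st[1:2, ] <- 1L  # two genes conserved everywhere
  disc <- as_disc(st)
  x <- random_matrix(6, 6, seed = 25)
  mod <- find_largest_module(disc, x, search_params(alpha = 1, rng_seed = 1))
  if (!is.null(mod)) expect_equal(mod$samples, 1:6)
})

test_that("the multistart search is reproducible under a fixed seed", {
  x <- random_matrix(15, 10, seed = 26)
  disc <- discretize(x, 2)
  p <- search_params(num_seeds = 5, discriminating_size = 3, rng_seed = 99)
  m1 <- find_largest_module(disc, x, p)
  m2 <- find_largest_module(disc, x, p)
  expect_identical(m1, m2)
})

test_that("iterative extraction recovers two disjoint conserved blocks", {
  # samples 1:4 share one state vector, samples 5:8 another; a noise gene
  # keeps the matrix from being globally trivial
  st <- matrix(0L, 6, 8)
  st[1:5, 1:4] <- matrix(rep(c(0L, 1L, 2L, 1L, 0L), 4), 5, 4)
  st[1:5, 5:8] <- matrix(rep(c(2L, 0L, 1L, 0L, 2L), 4), 5, 4)
  st[6, ] <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L)
  disc <- as_disc(st)
  x <- random_matrix(6, 8, seed = 27)
  res <- extract_biclusters(disc, x,
                            search_params(num_seeds = 40,
                                          discriminating_size = 3,
                                          alpha = 0.25, rng_seed = 5),
                            max_modules = 5)
  expect_length(res$modules, 2)
  covered <- sort(unlist(lapply(res$modules, function(m) m$samples)))
  expect_equal(covered, 1:8)
  sizes <- sort(vapply(res$modules, function(m) m$n_samples, integer(1)))
  expect_equal(sizes, c(4L, 4L))
  expect_true(res$best %in% c(1L, 2L))
})

test_that("extraction ends after one module when all samples are identical", {
  st <- matrix(rep(c(0L, 1L), 5), 2, 5)
  disc <- as_disc(st)
  x <- random_matrix(2, 5, seed = 28)
  res <- extract_biclusters(disc, x, search_params(rng_seed = 1))
  expect_length(res$modules, 1)
  expect_equal(res$modules[[1]]$samples, 1:5)
})

test_that("a filter that nothing survives yields an empty extraction", {
  # no gene conserved across all samples, so alpha = 1 removes everything
  st <- rbind(c(0L, 1L, 2L, 0L), c(1L, 0L, 1L, 2L))
  disc <- as_disc(st)
  x <- random_matrix(2, 4, seed = 29)
  res <- extract_biclusters(disc, x, search_params(alpha = 1, rng_seed = 2))
  expect_length(res$modules, 0)
  expect_true(is.na(res$best))
})

test_that("seeds out of range are rejected", {
  disc <- as_disc(toy_states())
  expect_error(build_module(disc, 9, 1:2), "out of range")
  expect_error(build_module(disc, 1, c(1, 12)), "out of range")
  expect_error(build_module(disc, 4, 1:2, active = 1:3), "out of range")
})
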