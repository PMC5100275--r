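# Coalescent and sequence-evolution engine: closed-form expectations of the
# n-coalescent (time in 4Ne units), JC calibration E[pi] = theta, and the
# determinism/substream contracts.

tree_height_of <- function(gen) gen$node_time[2 * gen$n_tips - 1]

test_that("pairwise TMRCA and tree height match coalescent theory", {
  cfg2 <- model_config("panmictic", theta_site = 0.01, n_loci = 1,
                       locus_len = 10, n_haplotypes = 2, seed = 1)
  tm <- vapply(1:20000, function(i) tree_height_of(simulate_genealogy(cfg2, i)), 0)
  # E[T2] = 0.5 in 4Ne units, sd(T2) = 0.5 -> se ~ 0.0035
  expect_lt(abs(mean(tm) - 0.5), 0.015)

  cfg4 <- model_config("panmictic", theta_site = 0.01, n_loci = 1,
                       locus_len = 10, n_haplotypes = 4, seed = 2)
  h4 <- vapply(1:20000, function(i) tree_height_of(simulate_genealogy(cfg4, i)), 0)
  # E[height] = 1/12 + 1/6 + 1/2 = 0.75
  expect_lt(abs(mean(h4) - 0.75), 0.02)
})

test_that("genealogies are ultrametric with valid topology", {
  cfg <- model_config("structured", theta_site = 0.01, divergence_t = 0.8,
                      n_loci = 1, locus_len = 10, seed = 3)
  for (i in 1:50) {
    gen <- simulate_genealogy(cfg, i)
    expect_identical(gen$n_tips, 4L)
    expect_true(all(gen$node_time >= 0))
    expect_true(all(gen$node_time[1:4] == 0))
    # every non-root node has a parent with a later (older) time
    for (v in 1:6)
      expect_gt(gen$node_time[gen$parent[v]], gen$node_time[v] - 1e-12)
  }
})

test_that("cross-deme coalescences never predate the population split", {
  cfg <- model_config("structured", theta_site = 0.01, divergence_t = 2.5,
                      n_loci = 1, locus_len = 10, seed = 4)
  for (i in 1:200) {
    gen <- simulate_genealogy(cfg, i)
    for (i1 in 1:2) for (i2 in 3:4)
      expect_gte(radbias:::pair_tmrca(gen, i1, i2), 2.5)
  }
})

test_that("theta = 0 yields identical haplotypes", {
  g <- simulate_genome(model_config("panmictic", theta_site = 0, n_loci = 5,
                                    locus_len = 300, seed = 5))
  for (i in 1:5)
    expect_length(unique(g$sequences[i, ]), 1L)
})

test_that("JC mutation is calibrated so mean pairwise diversity equals theta", {
  # E[per-site pairwise difference] = theta in the low-theta limit; at
  # theta = 0.01 the exact finite-site value is E[p] = theta/(1 + 4 theta/3)
  # (path length b ~ Exp(1), p = 3/4 (1 - exp(-4 theta b / 3)))
  theta <- 0.01
  cfg <- model_config("panmictic", theta_site = theta, n_loci = 200,
                      locus_len = 10000, seed = 6)
  g <- simulate_genome(cfg)
  pw <- function(a, b) {
    ra <- charToRaw(a); rb <- charToRaw(b)
    sum(ra != rb) / length(ra)
  }
  pairs <- combn(4, 2)
  d <- mean(vapply(seq_len(cfg$n_loci), function(i)
    mean(vapply(seq_len(ncol(pairs)), function(p)
      pw(g$sequences[i, pairs[1, p]], g$sequences[i, pairs[2, p]]), 0)), 0))
  expected <- theta / (1 + 4 * theta / 3)
  expect_lt(abs(d - expected) / expected, 0.08)
})

test_that("high theta saturates per the JC tree-conditional expectation", {
  # dual route: realized mismatch fraction between two haplotypes vs the
  # closed-form JC expectation 3/4 (1 - exp(-4 theta b / 3)) evaluated on
  # the same genealogies (re-drawn independently from the locus substreams)
  cfg <- model_config("panmictic", theta_site = 0.1, n_loci = 150,
                      locus_len = 5000, seed = 7)
  g <- simulate_genome(cfg)
  d <- mean(vapply(seq_len(cfg$n_loci), function(i) {
    ra <- charToRaw(g$sequences[i, 1]); rb <- charToRaw(g$sequences[i, 2])
    mean(ra != rb)
  }, 0))
  expected <- mean(vapply(seq_len(cfg$n_loci), function(i) {
    b <- 2 * radbias:::pair_tmrca(simulate_genealogy(cfg, i), 1, 2)
    0.75 * (1 - exp(-4 * 0.1 * b / 3))
  }, 0))
  expect_lt(abs(d - expected) / expected, 0.05)
  expect_lt(d, 0.12) # well below the unsaturated value E[p] -> theta only at low theta
})

test_that("heterogeneous theta classes are assigned deterministically in proportion", {
  cls <- data.frame(proportion = c(0.7, 0.2, 0.1),
                    theta = c(0.01, 0.005, 0.001))
  cfg <- model_config("heterogeneous", theta_classes = cls, n_loci = 1000,
                      locus_len = 100, seed = 8)
  th <- radbias:::theta_by_locus(cfg)
  expect_identical(as.integer(table(factor(th, levels = c(0.001, 0.005, 0.01)))),
                   c(100L, 200L, 700L))
  # weighted-mean theta: 0.7 + 0.2/2 + 0.1/10 of theta_ref pattern
  expect_equal(cfg$theta_true, sum(cls$proportion * cls$theta))
})

test_that("weighted-mean theta of the 70/20/10 mixture equals 0.81 theta_ref", {
  cls <- data.frame(proportion = c(0.7, 0.2, 0.1),
                    theta = 0.02 * c(1, 1 / 2, 1 / 10))
  cfg <- model_config("heterogeneous", theta_classes = cls, n_loci = 10,
                      locus_len = 100, seed = 1)
  expect_equal(cfg$theta_true, 0.81 * 0.02)
})

test_that("simulation is deterministic and per-locus substreams are stable", {
  cfg <- model_config("panmictic", theta_site = 0.02, n_loci = 6,
                      locus_len = 400, seed = 9)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$sequences, g2$sequences)
  # growing n_loci must not perturb earlier loci
  cfg_big <- model_config("panmictic", theta_site = 0.02, n_loci = 9,
                          locus_len = 400, seed = 9)
  g3 <- simulate_genome(cfg_big)
  expect_identical(g3$sequences[1:6, ], g1$sequences)
})

test_that("realized diversity scales linearly with theta on a log grid", {
  # log-log regression of whole-locus pairwise diversity on theta
  grid <- 10^seq(-3, -1.5, length.out = 4)
  d <- vapply(seq_along(grid), function(gi) {
    cfg <- model_config("panmictic", theta_site = grid[gi], n_loci = 150,
                        locus_len = 2000, seed = 100 + gi)
    g <- simulate_genome(cfg)
    mean(vapply(seq_len(cfg$n_loci), function(i) {
      ra <- charToRaw(g$sequences[i, 1]); rb <- charToRaw(g$sequences[i, 3])
      sum(ra != rb) / length(ra)
    }, 0))
  }, 0)
  slope <- coef(lm(log10(d) ~ log10(grid)))[2]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(model_config("heterogeneous", n_loci = 10, locus_len = 100),
               "theta_classes")
  expect_error(model_config("heterogeneous",
                            theta_classes = data.frame(proportion = c(0.5, 0.4),
                                                       theta = c(0.01, 0.001)),
                            n_loci = 10, locus_len = 100),
               "sum to 1")
  expect_error(model_config("structured", theta_site = 0.01, n_loci = 10,
                            locus_len = 100), "divergence_t")
  expect_error(model_config("panmictic", n_loci = 10, locus_len = 100),
               "theta_site")
})
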