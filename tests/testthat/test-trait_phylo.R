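two_leaf_tree <- function(l1 = 1, l2 = 1) {
  ape::read.tree(text = sprintf("(A:%g,B:%g);", l1, l2))
}

traits_df <- function(species, t1, t2)
  data.frame(species = species, trait1 = t1, trait2 = t2,
             stringsAsFactors = FALSE)

test_that("zero rates with identical states give log(1/4)", {
  tr <- two_leaf_tree()
  td <- traits_df(c("A", "B"), c(1, 1), c(0, 0))
  m <- independent_model(0, 0, 0, 0)
  expect_equal(combined_loglik(tr, td, m), log(0.25), tolerance = 1e-9)
  # differing states are impossible without change
  td2 <- traits_df(c("A", "B"), c(1, 0), c(0, 0))
  expect_equal(combined_loglik(tr, td2, m), -Inf)
})

test_that("generators are valid and the independent one is a Kronecker sum", {
  m <- independent_model(0.3, 0.7, 0.2, 0.9)
  Q <- model_generator(m)
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
  A <- matrix(c(-0.3, 0.7, 0.3, -0.7), 2, 2)   # trait 1
  B <- matrix(c(-0.2, 0.9, 0.2, -0.9), 2, 2)   # trait 2
  K <- kronecker(A, diag(2)) + kronecker(diag(2), B)
  expect_equal(unname(Q), K, tolerance = 1e-12)
  d <- dependent_model(1:8)
  Qd <- model_generator(d)
  expect_equal(unname(rowSums(Qd)), rep(0, 4), tolerance = 1e-12)
  expect_equal(Qd["00", "11"], 0)   # dual transitions forbidden
  expect_equal(Qd["11", "00"], 0)
  expect_error(dependent_model(-(1:8)), ">= 0")
})

test_that("pruning matches ancestral-state enumeration on small trees", {
  set.seed(41)
  for (i in 1:6) {
    tr <- ape::rtree(4)
    td <- traits_df(tr$tip.label, sample(0:1, 4, TRUE),
                    sample(0:1, 4, TRUE))
    m <- if (i %% 2 == 0) independent_model(runif(1), runif(1), runif(1),
                                            runif(1))
         else dependent_model(runif(8, 0.05, 2))
    Q <- model_generator(m)
    states <- 1L + 2L * td$trait1 + td$trait2
    want <- oracle_trait_loglik(tr, states[match(tr$tip.label,
                                                 td$species)],
                                Q, rep(0.25, 4))
    expect_equal(combined_loglik(tr, td, m), want, tolerance = 1e-8)
  }
})

test_that("independent joint likelihood is the sum of marginal likelihoods", {
  set.seed(42)
  tr <- ape::rtree(8)
  td <- traits_df(tr$tip.label, sample(0:1, 8, TRUE), sample(0:1, 8, TRUE))
  m <- independent_model(0.4, 0.6, 1.1, 0.3)
  joint <- combined_loglik(tr, td, m)
  m1 <- genoverlap:::binary_trait_loglik(
    tr, td$trait1[match(tr$tip.label, td$species)], 0.4, 0.6)
  m2 <- genoverlap:::binary_trait_loglik(
    tr, td$trait2[match(tr$tip.label, td$species)], 1.1, 0.3)
  expect_equal(joint, m1 + m2, tolerance = 1e-9)
})

test_that("likelihood is invariant to leaf rotation and label order", {
  set.seed(43)
  tr <- ape::rtree(6)
  td <- traits_df(tr$tip.label, sample(0:1, 6, TRUE), sample(0:1, 6, TRUE))
  m <- dependent_model(runif(8, 0.1, 1.5))
  base <- combined_loglik(tr, td, m)
  expect_equal(combined_loglik(ape::rotateConstr(tr, rev(tr$tip.label)),
                               td, m), base, tolerance = 1e-9)
  td2 <- td[sample(6), ]
  expect_equal(combined_loglik(tr, td2, m), base, tolerance = 1e-9)
})

test_that("huge rates drive the likelihood to the stationary limit", {
  tr <- ape::rtree(5)
  td <- traits_df(tr$tip.label, sample(0:1, 5, TRUE), sample(0:1, 5, TRUE))
  m <- independent_model(80, 80, 80, 80)
  # symmetric fast rates: every leaf is an independent uniform draw
  expect_equal(combined_loglik(tr, td, m), 5 * log(0.25),
               tolerance = 0.02)
})

test_that("simulation follows the model law", {
  tr <- two_leaf_tree(1, 1)
  # zero rates: all leaves share the root state
  s0 <- simulate_traits(tr, independent_model(0, 0, 0, 0), seed = 1L)
  expect_equal(length(unique(paste(s0$trait1, s0$trait2))), 1L)
  # long symmetric branches: leaf marginals near 1/2 per trait
  tr_long <- two_leaf_tree(60, 60)
  m <- independent_model(1, 1, 1, 1)
  draws <- vapply(1:400, function(i)
    simulate_traits(tr_long, m, seed = 1000L + i)$trait1[1L], numeric(1))
  expect_gt(mean(draws), 0.5 - 3 * sqrt(0.25 / 400))
  expect_lt(mean(draws), 0.5 + 3 * sqrt(0.25 / 400))
  # empirical transitions on one branch match P(t)
  m2 <- independent_model(0.8, 0.3, 0, 0)
  P <- genoverlap:::Matrix_expm(model_generator(m2) * 1)
  from0 <- vapply(1:400, function(i) {
    s <- simulate_traits(two_leaf_tree(1, 1e-9), m2, seed = 2000L + i)
    if (s$trait1[s$species == "B"] == 0) s$trait1[s$species == "A"]
    else NA_real_
  }, numeric(1))
  phat <- mean(from0, na.rm = TRUE)          # P(0 -> 1) over t = 1
  p_true <- P[1L, 3L] + P[1L, 4L]   # states 00 -> {10, 11}
  n <- sum(!is.na(from0))
  expect_lt(abs(phat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("fit_pagel honours nesting, determinism and recovers dependence", {
  set.seed(44)
  tr <- ape::rcoal(12)
  tr$edge.length <- tr$edge.length * 2
  td <- simulate_traits(tr, independent_model(1, 1, 1, 1), seed = 3L)
  fit <- fit_pagel(tr, td, n_starts = 4L, seed = 5L)
  expect_gte(fit$dependent$loglik, fit$independent$loglik)
  expect_equal(fit$lrt$df, 4L)
  expect_gte(fit$lrt$p_value, 0)
  fit2 <- fit_pagel(tr, td, n_starts = 4L, seed = 5L)
  expect_identical(fit$dependent$loglik, fit2$dependent$loglik)

  # strongly coupled traits on a larger tree: dependence is detected in
  # most replicates (small calibration of the full 500-rep acceptance run)
  dep <- dependent_model(c(q12 = 0.1, q13 = 0.1, q21 = 2, q24 = 2,
                           q31 = 2, q34 = 2, q42 = 0.1, q43 = 0.1))
  hits <- 0L
  n_rep <- 12L
  for (i in seq_len(n_rep)) {
    set.seed(300 + i)
    trb <- ape::rcoal(24)
    trb$edge.length <- trb$edge.length * 4
    tdb <- simulate_traits(trb, dep, seed = 400L + i)
    if (length(unique(tdb$trait1)) < 2L ||
        length(unique(tdb$trait2)) < 2L) next
    f <- fit_pagel(trb, tdb, n_starts = 3L, seed = 500L + i)
    if (f$lrt$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})
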