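two_tip_tree <- function(t1, t2) {
  read_phylogeny(text = sprintf("(A:%f,B:%f);", t1, t2))
}

test_that("the symmetric two-state chain has its closed-form probabilities", {
  # q01 = q10 = 1: P(same state after t) = (1 + exp(-2t)) / 2,
  # so at t = ln(2)/2 a lineage keeps its state with probability 3/4
  t <- log(2) / 2
  p_same <- (1 + exp(-2 * t)) / 2
  expect_equal(p_same, 0.75)
  tr <- two_tip_tree(t, t)
  model <- rate_model("independent", c(1, 1, 1e-9, 1e-9))
  # character B is frozen; character A likelihood is the 2-state sum:
  # L = 1/2 sum_r P_t(r -> sA) P_t(r -> sB)
  ll <- mk_loglik(tr, c(A = 1, B = 1), c(A = 0, B = 0), model)
  manual_a <- 0.5 * (p_same^2 + (1 - p_same)^2)
  expect_equal(ll, log(manual_a) + log(0.5), tolerance = 1e-6)
})

test_that("with all rates zero the likelihood is the root prior alone", {
  tr <- two_tip_tree(1, 1)
  model <- rate_model("dependent", rep(0, 8))
  ll <- mk_loglik(tr, c(A = 1, B = 1), c(A = 1, B = 1), model)
  expect_equal(ll, log(1 / 4))
  # impossible data under a frozen chain
  ll2 <- mk_loglik(tr, c(A = 1, B = 0), c(A = 1, B = 1), model)
  expect_equal(ll2, -Inf)
})

test_that("pruning equals brute-force summation over internal states", {
  skip_if_not_installed("Matrix")
  set.seed(71)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    tr <- simulate_tree(n, 1)
    kind <- sample(c("independent", "dependent"), 1)
    model <- rate_model(kind, runif(ifelse(kind == "independent", 4, 8),
                                    0.05, 3))
    h <- simulate_characters(tr, model)
    ta <- stats::setNames(h$tip_states$trait_a, h$tip_states$tip)
    tb <- stats::setNames(h$tip_states$trait_b, h$tip_states$tip)
    expect_equal(mk_loglik(tr, ta, tb, model),
                 brute_force_loglik(tr, ta, tb, model), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to traversal order of the children", {
  set.seed(81)
  tr <- simulate_tree(12, 1)
  model <- rate_model("dependent", runif(8, 0.1, 2))
  h <- simulate_characters(tr, model)
  ta <- stats::setNames(h$tip_states$trait_a, h$tip_states$tip)
  tb <- stats::setNames(h$tip_states$trait_b, h$tip_states$tip)
  base <- mk_loglik(tr, ta, tb, model)
  rotated <- ape::rotate(tr, node = 14L)
  expect_equal(mk_loglik(rotated, ta, tb, model), base, tolerance = 1e-10)
  reordered <- ape::reorder.phylo(tr, "pruningwise")
  expect_equal(mk_loglik(reordered, ta, tb, model), base, tolerance = 1e-10)
})

test_that("the dependent model never fits worse than the independent model", {
  set.seed(91)
  for (i in 1:5) {
    tr <- simulate_tree(40, 1)
    model <- rate_model("independent", runif(4, 0.2, 1))
    h <- simulate_characters(tr, model)
    ta <- stats::setNames(h$tip_states$trait_a, h$tip_states$tip)
    tb <- stats::setNames(h$tip_states$trait_b, h$tip_states$tip)
    if (length(unique(ta)) < 2 || length(unique(tb)) < 2) next
    ind <- fit_rate_model(tr, ta, tb, "independent", seed = i)
    dep <- fit_rate_model(tr, ta, tb, "dependent", seed = i)
    expect_gte(dep$loglik, ind$loglik - 1e-4)
  }
})

test_that("fits agree with an independent reference implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(60, 1, seed = 12)
  h <- simulate_characters(tr, rate_model("independent", rep(0.6, 4)),
                           seed = 13)
  a <- stats::setNames(h$tip_states$trait_a, h$tip_states$tip)
  b <- stats::setNames(h$tip_states$trait_b, h$tip_states$tip)
  ind <- fit_rate_model(tr, a, b, "independent", seed = 1)
  fa <- phytools::fitMk(tr, stats::setNames(factor(a), names(a)),
                        model = "ARD", pi = "equal")
  fb <- phytools::fitMk(tr, stats::setNames(factor(b), names(b)),
                        model = "ARD", pi = "equal")
  expect_equal(ind$loglik, as.numeric(stats::logLik(fa)) +
                 as.numeric(stats::logLik(fb)), tolerance = 1e-3)
  dep <- fit_rate_model(tr, a, b, "dependent", seed = 1)
  fp <- phytools::fitPagel(tr, stats::setNames(factor(a), names(a)),
                           stats::setNames(factor(b), names(b)), pi = "equal")
  expect_equal(dep$loglik, as.numeric(fp$dependent.logL), tolerance = 1e-3)
})

test_that("refitting with the same seed reproduces identical rates", {
  tr <- simulate_tree(30, 1, seed = 14)
  h <- simulate_characters(tr, rate_model("independent", rep(0.5, 4)),
                           seed = 15)
  a <- stats::setNames(h$tip_states$trait_a, h$tip_states$tip)
  b <- stats::setNames(h$tip_states$trait_b, h$tip_states$tip)
  f1 <- fit_rate_model(tr, a, b, "dependent", seed = 7)
  f2 <- fit_rate_model(tr, a, b, "dependent", seed = 7)
  expect_identical(f1$model$rates, f2$model$rates)
  p1 <- pagel_test(tr, a, b, n_sim = 19, seed = 5)
  p2 <- pagel_test(tr, a, b, n_sim = 19, seed = 5)
  expect_identical(glance(p1), glance(p2))
})

test_that("degenerate inputs are rejected with informative errors", {
  tr <- simulate_tree(10, 1, seed = 16)
  ones <- stats::setNames(rep(1L, 10), tr$tip.label)
  mixed <- stats::setNames(rep(c(0L, 1L), 5), tr$tip.label)
  expect_error(fit_rate_model(tr, ones, mixed, "independent"),
               class = "pgtrait_validation_error")
  expect_error(pagel_test(tr, mixed, mixed, n_sim = 10),
               class = "pgtrait_config_error")
  expect_error(rate_model("independent", c(1, 2, 3)),
               class = "pgtrait_config_error")
  expect_error(rate_model("dependent", c(rep(1, 7), -1)),
               class = "pgtrait_validation_error")
})

test_that("perfectly coupled characters earn a small error percentage", {
  tr <- simulate_tree(100, 1, seed = 17)
  h <- simulate_characters(tr, rate_model("independent", rep(0.5, 4)),
                           seed = 18)
  a <- stats::setNames(h$tip_states$trait_a, h$tip_states$tip)
  fit <- pagel_test(tr, a, a, n_sim = 19, seed = 19, n_starts = 2)
  expect_lte(fit$error_percentage, 5)
  expect_gt(fit$score, 5)
})
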