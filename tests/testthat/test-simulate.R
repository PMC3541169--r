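test_that("Yule trees have the right shape and are seed-deterministic", {
  tr <- simulate_tree(3, 1, seed = 1)
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  t1 <- ape::write.tree(simulate_tree(25, 0.8, seed = 42))
  t2 <- ape::write.tree(simulate_tree(25, 0.8, seed = 42))
  expect_identical(t1, t2)
  expect_error(simulate_tree(2, 1), class = "pgtrait_config_error")
})

test_that("mean root-to-tip depth matches the Yule expectation", {
  birth <- 1.3
  n <- 8
  expected <- sum(1 / (birth * (2:n)))
  set.seed(123)
  depths <- replicate(1000, {
    tr <- simulate_tree(n, birth)
    max(ape::node.depth.edgelength(tr))
  })
  se <- stats::sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 4 * se)
})

test_that("frozen chains inherit the root state everywhere", {
  tr <- simulate_tree(12, 1, seed = 5)
  h <- simulate_characters(tr, rate_model("dependent", rep(0, 8)),
                           root_state = "10", seed = 6)
  expect_true(all(h$node_states$joint_state == "10"))
  expect_equal(nrow(h$true_events), 0)
  expect_true(all(h$tip_states$trait_a == 1L))
  expect_true(all(h$tip_states$trait_b == 0L))
})

test_that("long symmetric branches reach the uniform joint distribution", {
  tr <- simulate_tree(4, 1, seed = 7)
  tr$edge.length <- rep(30, nrow(tr$edge))  # >> 1/q: memory of the root gone
  set.seed(8)
  states <- replicate(600, {
    h <- simulate_characters(tr, rate_model("independent", rep(1, 4)))
    paste0(h$tip_states$trait_a[1], h$tip_states$trait_b[1])
  })
  freq <- table(factor(states, levels = c("00", "01", "10", "11")))
  expect_true(all(abs(freq / 600 - 0.25) < 4 * sqrt(0.25 * 0.75 / 600)))
})

test_that("a forbidden transition never occurs in the recorded events", {
  # character B cannot gain while A = 0 (rate r00_01 = 0)
  model <- rate_model("dependent", c(0.5, 0, 0.8, 0.3, 0.5, 0.8, 0.3, 0.3))
  set.seed(9)
  for (i in 1:20) {
    tr <- simulate_tree(20, 1)
    h <- simulate_characters(tr, model, root_state = "00")
    ev <- h$true_events
    b_gains <- ev[ev$character == "trait_b" & ev$type == "gain", ]
    if (nrow(b_gains) == 0) next
    # at the moment of each B gain, A must have been 1: walk each branch
    for (k in seq_len(nrow(b_gains))) {
      branch_ev <- ev[ev$parent == b_gains$parent[k] &
                        ev$child == b_gains$child[k], ]
      branch_ev <- branch_ev[order(branch_ev$time), ]
      a_state <- as.integer(substr(
        h$node_states$joint_state[b_gains$parent[k]], 1, 1))
      for (j in seq_len(nrow(branch_ev))) {
        if (branch_ev$time[j] == b_gains$time[k] &&
            branch_ev$character[j] == "trait_b") {
          expect_equal(a_state, 1L)
        }
        if (branch_ev$character[j] == "trait_a") {
          a_state <- if (branch_ev$type[j] == "gain") 1L else 0L
        }
      }
    }
  }
})

test_that("replaying recorded events reproduces the simulated tips exactly", {
  set.seed(10)
  for (i in 1:15) {
    tr <- simulate_tree(sample(5:40, 1), 1)
    kind <- sample(c("independent", "dependent"), 1)
    model <- rate_model(kind, runif(ifelse(kind == "independent", 4, 8), 0, 2))
    h <- simulate_characters(tr, model)
    expect_identical(replay_history(h), h$tip_states)
  }
})

test_that("generated cohorts match their confusion design at scale", {
  spec_prev <- 0.901
  p_absent <- 84 / 108
  unk <- 30 / 138
  cohort <- generate_cohort(n_bacteria = 1e5, set_prevalence = spec_prev,
                            p_absent_given_noset = p_absent,
                            unknown_frac_noset = unk, seed = 11)
  cls <- classify_cohort(cohort)
  n <- nrow(cohort)
  prev_hat <- mean(cls$set_positive)
  expect_lt(abs(prev_hat - spec_prev), 3 * sqrt(spec_prev * (1 - spec_prev) / n))
  neg <- cohort[!cls$set_positive, ]
  unk_hat <- mean(neg$pg_status == "unknown")
  expect_lt(abs(unk_hat - unk), 3 * sqrt(unk * (1 - unk) / nrow(neg)))
  known_neg <- neg[neg$pg_status != "unknown", ]
  abs_hat <- mean(known_neg$pg_status == "absent")
  expect_lt(abs(abs_hat - p_absent),
            3 * sqrt(p_absent * (1 - p_absent) / nrow(known_neg)))
  # set-positive rows always satisfy the rule, set-negative never do
  profile <- binarize(cohort)
  expect_identical(unname(has_minimal_set(profile)), cls$set_positive)
})

test_that("cohort generation is deterministic and validates its spec", {
  path1 <- withr::local_tempfile(fileext = ".tsv")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(generate_cohort(n_bacteria = 200, seed = 12), path1)
  write_cohort(generate_cohort(n_bacteria = 200, seed = 12), path2)
  expect_identical(readLines(path1), readLines(path2))
  expect_error(generate_cohort(set_prevalence = 1.2),
               class = "pgtrait_validation_error")
  # all-unknown negatives leave the negative-side metrics undefined
  cohort <- generate_cohort(n_bacteria = 300, unknown_frac_noset = 1,
                            seed = 13)
  m <- diagnostic_metrics(confusion(classify_cohort(cohort), cohort))
  expect_true(is.na(m$npv))
  expect_true(is.na(m$specificity))
})
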