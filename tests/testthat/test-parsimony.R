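test_that("Newick reading preserves topology, labels and lengths", {
  tr <- read_phylogeny(text = "((A,B),(C,D));")
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  expect_equal(tr$Nnode, 3)
  tr2 <- read_phylogeny(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
  expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
  expect_equal(sum(tr2$edge.length), 6)
  # round-trip through write.tree
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr2, path)
  back <- read_phylogeny(path)
  expect_true(ape::all.equal.phylo(back, tr2, use.edge.length = TRUE))
  expect_error(read_phylogeny(text = "((A,B,(C;"),
               class = "pgtrait_parse_error")
  expect_error(read_phylogeny(text = "((A,A),(C,D));"),
               class = "pgtrait_parse_error")
})

test_that("the four-tip split reconstructs a single loss at the stem", {
  tr <- read_phylogeny(text = "((A,B),(C,D));")
  fit <- ancestral_parsimony(tr, c(A = 1, B = 1, C = 0, D = 0),
                             gain_cost = 2, loss_cost = 1)
  oracle <- brute_force_parsimony_cost(tr, c(A = 1, B = 1, C = 0, D = 0), 2, 1)
  expect_equal(fit$total_cost, oracle)
  expect_equal(fit$total_cost, 1)
  root <- length(tr$tip.label) + 1L
  expect_equal(fit$node_states$state[root], 1L)
  ev <- extract_events(fit)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "loss")
  # the loss branch leads to the ancestor of C and D
  anc_cd <- ape::getMRCA(tr, c("C", "D"))
  expect_equal(ev$child, anc_cd)
})

test_that("a nested regain beats repeated losses under gain-penalizing costs", {
  # clade of five 0-tips hiding one 1-tip, arranged so that without a gain
  # four separate losses are needed; the outgroup is all 1.  With gain 2 /
  # loss 1, one stem loss plus one regain on the 1-tip (cost 3) wins.
  txt <- "(((i1,i2),(g1,i3),i4,i5),(o1,o2));"
  tr <- read_phylogeny(text = txt)
  states <- c(i1 = 0, i2 = 0, i3 = 0, i4 = 0, i5 = 0, g1 = 1,
              o1 = 1, o2 = 1)
  fit <- ancestral_parsimony(tr, states, gain_cost = 2, loss_cost = 1)
  expect_equal(fit$total_cost,
               brute_force_parsimony_cost(tr, states, 2, 1))
  expect_equal(fit$total_cost, 3)
  ev <- extract_events(fit)
  expect_equal(sort(ev$type), c("gain", "loss"))
  expect_equal(ev$child_label[ev$type == "gain"], "g1")
})

test_that("constant tip states yield zero cost and no events", {
  tr <- read_phylogeny(text = "((A,B),(C,D));")
  fit <- ancestral_parsimony(tr, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(fit$total_cost, 0)
  expect_equal(nrow(extract_events(fit)), 0)
  expect_true(all(fit$node_states$state == 1L))
})

test_that("Sankoff cost matches exhaustive enumeration on random instances", {
  set.seed(20)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    tr <- simulate_tree(n, 1)
    states <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    if (length(unique(states)) == 1 && runif(1) < 0.7) {
      states[1] <- 1L - states[1]
    }
    gain <- sample(c(1, 1.5, 2, 3), 1)
    loss <- sample(c(0.5, 1, 2), 1)
    fit <- ancestral_parsimony(tr, states, gain, loss)
    expect_equal(fit$total_cost,
                 brute_force_parsimony_cost(tr, states, gain, loss))
  }
})

test_that("polytomies are handled natively", {
  tr <- read_phylogeny(text = "((A,B,C),(D,E));")
  states <- c(A = 1, B = 1, C = 0, D = 0, E = 0)
  fit <- ancestral_parsimony(tr, states, 2, 1)
  expect_equal(fit$total_cost,
               brute_force_parsimony_cost(tr, states, 2, 1))
})

test_that("raising the gain cost never yields more gains", {
  set.seed(33)
  for (i in 1:10) {
    tr <- simulate_tree(30, 1)
    states <- stats::setNames(sample(0:1, 30, replace = TRUE,
                                     prob = c(0.4, 0.6)), tr$tip.label)
    gains <- sapply(c(1, 1.5, 2, 3, 5), function(gc) {
      ev <- extract_events(ancestral_parsimony(tr, states, gc, 1))
      sum(ev$type == "gain")
    })
    expect_true(all(diff(gains) <= 0))
  }
})

test_that("equal costs recover classical Sankoff/Fitch parsimony", {
  set.seed(44)
  for (i in 1:10) {
    n <- sample(5:16, 1)
    tr <- ape::rtree(n)
    states <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    fit <- ancestral_parsimony(tr, states, gain_cost = 1, loss_cost = 1)
    phang_data <- phangorn::phyDat(matrix(as.character(states),
                                          ncol = 1,
                                          dimnames = list(names(states), NULL)),
                                   type = "USER", levels = c("0", "1"))
    expect_equal(fit$total_cost,
                 as.numeric(phangorn::parsimony(tr, phang_data)))
  }
})

test_that("replaying the event list from the root reproduces every tip state", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(6:25, 1)
    tr <- simulate_tree(n, 1)
    states <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    fit <- ancestral_parsimony(tr, states, 2, 1)
    ev <- extract_events(fit)
    # walk root-to-tip applying events
    st <- fit$node_states$state
    root <- n + 1L
    replayed <- integer(length(st))
    replayed[root] <- st[root]
    post <- ape::reorder.phylo(tr, "postorder")
    for (e in rev(seq_len(nrow(post$edge)))) {
      p <- post$edge[e, 1]; ch <- post$edge[e, 2]
      s <- replayed[p]
      hit <- ev[ev$parent == p & ev$child == ch, ]
      if (nrow(hit) == 1) s <- if (hit$type == "gain") 1L else 0L
      replayed[ch] <- s
    }
    expect_equal(replayed[seq_len(n)], unname(states[tr$tip.label]))
  }
})

test_that("tip states join from a cohort and unknown PG prunes tips", {
  cohort <- toy_cohort()
  tr <- read_phylogeny(text = "((gA,gB),gC);")
  gt51 <- tip_states_from_cohort(cohort, tr, "GT51")
  expect_equal(gt51$states, c(gA = 1L, gB = 0L, gC = 1L))
  set <- tip_states_from_cohort(cohort, tr, "set")
  expect_equal(set$states, c(gA = 1L, gB = 0L, gC = 1L))
  pg <- tip_states_from_cohort(cohort, tr, "pg")
  expect_equal(pg$dropped, "gC")
  expect_equal(sort(names(pg$states)), c("gA", "gB"))
  tr2 <- read_phylogeny(text = "((gA,gX),gC);")
  expect_error(tip_states_from_cohort(cohort, tr2, "GT51"),
               regexp = "gX", class = "pgtrait_validation_error")
  expect_error(ancestral_parsimony(tr, c(gA = 1)),
               regexp = "gB", class = "pgtrait_validation_error")
})
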