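#' Simulate a pure-birth (Yule) tree
#'
#' Lineages split at rate `birth_rate` each; starting from two lineages,
#' epochs with k active lineages last Exp(k * birth_rate), a uniformly
#' chosen lineage splits, and after the n-th tip appears the tree grows one
#' final epoch so tips are not flush with the last split.  The tree is
#' ultrametric with expected root-to-tip depth
#' sum_\{k=2..n\} 1 / (k * birth_rate).
#'
#' @param n_tips Number of tips (at least 3).
#' @param birth_rate Per-lineage splitting rate.
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched.
#' @return A rooted, ultrametric [ape::phylo] with tips `t1 ... tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 3) abort("n_tips must be at least 3", class = "pgtrait_config_error")
  if (birth_rate <= 0) abort("birth_rate must be positive", class = "pgtrait_config_error")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }

  n <- as.integer(n_tips)
  root <- n + 1L
  next_internal <- n + 2L
  # active lineages: the edge's parent node and the time it opened
  act_parent <- c(root, root)
  act_start <- c(0, 0)
  edges <- matrix(0L, 2L * n - 2L, 2L)
  lengths <- numeric(2L * n - 2L)
  n_edge <- 0L
  now <- 0

  for (k in 2:(n - 1L)) {
    now <- now + stats::rexp(1, rate = k * birth_rate)
    i <- sample.int(k, 1)
    node <- next_internal; next_internal <- next_internal + 1L
    n_edge <- n_edge + 1L
    edges[n_edge, ] <- c(act_parent[i], node)
    lengths[n_edge] <- now - act_start[i]
    act_parent <- c(act_parent[-i], node, node)
    act_start <- c(act_start[-i], now, now)
  }
  now <- now + stats::rexp(1, rate = n * birth_rate)
  for (i in seq_len(n)) {
    n_edge <- n_edge + 1L
    edges[n_edge, ] <- c(act_parent[i], i)
    lengths[n_edge] <- now - act_start[i]
  }

  tree <- structure(list(edge = edges, edge.length = lengths,
                         tip.label = paste0("t", seq_len(n)),
                         Nnode = n - 1L),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate a joint two-character history along a tree
#'
#' Evolves the pair of binary characters root-to-tip under a
#' [rate_model()] by exact waiting-time simulation of the continuous-time
#' Markov chain on the four joint states, recording every node state and
#' every change event -- including multiple hits on one branch, which a
#' parsimony reconstruction will legitimately undercount.
#'
#' @param tree A rooted [ape::phylo]; missing branch lengths become 1.
#' @param model A [rate_model()].
#' @param root_state Joint root state `"00"`, `"01"`, `"10"`, `"11"`, or
#'   `NULL` to draw it uniformly.
#' @param seed Optional integer seed (caller's RNG preserved when given).
#' @return A `simulated_history`: the tree, per-tip `tip_states`, per-node
#'   joint `node_states`, and the `true_events` table (character, type,
#'   branch endpoints, time within branch).
#' @export
simulate_characters <- function(tree, model, root_state = NULL, seed = NULL) {
  stopifnot(inherits(model, "rate_model"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  ctx <- pruning_context(tree)
  tree <- ctx$tree
  Q <- build_generator(model)
  n_tip <- ctx$n_tip
  n_node <- n_tip + tree$Nnode
  root <- ctx$root

  if (is.null(root_state)) {
    root_idx <- sample.int(4, 1)
  } else {
    root_idx <- match(root_state, joint_states())
    if (is.na(root_idx)) abort("root_state must be one of 00/01/10/11",
                               class = "pgtrait_config_error")
  }

  state <- integer(n_node)
  state[root] <- root_idx
  ev_from <- integer(0); ev_to <- integer(0)
  ev_parent <- integer(0); ev_child <- integer(0); ev_time <- numeric(0)

  post <- ape::reorder.phylo(tree, "postorder")
  edge <- post$edge
  elen <- post$edge.length
  for (e in rev(seq_len(nrow(edge)))) {  # parents before children
    parent <- edge[e, 1]; child <- edge[e, 2]; t_total <- elen[e]
    s <- state[parent]
    elapsed <- 0
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      dt <- stats::rexp(1, rate = rate)
      if (elapsed + dt > t_total) break
      elapsed <- elapsed + dt
      probs <- Q[s, ]; probs[s] <- 0
      s_new <- sample.int(4, 1, prob = probs)
      ev_from <- c(ev_from, s); ev_to <- c(ev_to, s_new)
      ev_parent <- c(ev_parent, parent); ev_child <- c(ev_child, child)
      ev_time <- c(ev_time, elapsed)
      s <- s_new
    }
    state[child] <- s
  }

  labels <- joint_states()[state]
  tip_states <- tibble::tibble(
    tip = tree$tip.label,
    trait_a = as.integer(substr(labels[seq_len(n_tip)], 1, 1)),
    trait_b = as.integer(substr(labels[seq_len(n_tip)], 2, 2))
  )
  node_states <- tibble::tibble(node = seq_len(n_node), joint_state = labels)
  from_lab <- joint_states()[ev_from]
  to_lab <- joint_states()[ev_to]
  a_changed <- substr(from_lab, 1, 1) != substr(to_lab, 1, 1)
  pos <- ifelse(a_changed, 1L, 2L)
  true_events <- tibble::tibble(
    character = ifelse(a_changed, "trait_a", "trait_b"),
    type = ifelse(substr(to_lab, pos, pos) == "1", "gain", "loss"),
    parent = ev_parent, child = ev_child, time = ev_time
  )
  structure(list(tree = tree, tip_states = tip_states,
                 node_states = node_states, true_events = true_events,
                 model = model),
            class = "simulated_history")
}

#' @export
print.simulated_history <- function(x, ...) {
  cat("<simulated_history>", length(x$tree$tip.label), "tips;",
      nrow(x$true_events), "true change event(s)\n")
  invisible(x)
}

#' Replay the recorded events of a simulated history
#'
#' Walks the tree from the recorded root state, applying the recorded
#' change events branch by branch in time order, and returns the implied
#' tip states.  Replaying must reproduce `tip_states` exactly; this is the
#' generator's internal-consistency contract and is what tests assert.
#'
#' @param history A `simulated_history`.
#' @return A tibble like `tip_states`.
#' @export
replay_history <- function(history) {
  stopifnot(inherits(history, "simulated_history"))
  tree <- history$tree
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  state <- character(n_tip + tree$Nnode)
  state[root] <- history$node_states$joint_state[root]

  flip <- function(s, ev_character, ev_type) {
    a <- substr(s, 1, 1); b <- substr(s, 2, 2)
    bit <- if (ev_type == "gain") "1" else "0"
    if (ev_character == "trait_a") paste0(bit, b) else paste0(a, bit)
  }

  post <- ape::reorder.phylo(tree, "postorder")
  edge <- post$edge
  ev <- history$true_events
  for (e in rev(seq_len(nrow(edge)))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    s <- state[parent]
    here <- ev[ev$parent == parent & ev$child == child, ]
    if (nrow(here) > 0) {
      here <- here[order(here$time), ]
      for (i in seq_len(nrow(here))) s <- flip(s, here$character[i], here$type[i])
    }
    state[child] <- s
  }
  tibble::tibble(
    tip = tree$tip.label,
    trait_a = as.integer(substr(state[seq_len(n_tip)], 1, 1)),
    trait_b = as.integer(substr(state[seq_len(n_tip)], 2, 2))
  )
}

#' Generate an annotation cohort with a configurable confusion structure
#'
#' Builds a bacterial cohort whose classifier-versus-truth behaviour
#' follows a specified confusion design: each genome carries the complete
#' minimal 3-gene set with probability `set_prevalence`; set-positive
#' genomes have PG with probability `p_present_given_set` (1 by default,
#' making the positive predictive value exactly 1); set-negative genomes
#' have unknown PG status with probability `unknown_frac_noset`, and the
#' known-status remainder lack PG with probability `p_absent_given_noset`.
#' Family counts are drawn consistently with the set label, and most
#' set-negative genomes are made GT51-negative (`p_noset_lacks_gt51`), so
#' the single-marker analysis has signal too.  Defaults reproduce the
#' published screen's structure: 90.1% prevalence over 1,398 genomes, 84/108
#' PG-absent among known-status set-negatives, 30/138 unknowns.
#'
#' @param n_bacteria Number of genomes.
#' @param set_prevalence Probability a genome carries the complete set.
#' @param p_present_given_set P(PG present | set present).
#' @param p_absent_given_noset P(PG absent | set absent, status known).
#' @param unknown_frac_noset P(status unknown | set absent).
#' @param p_noset_lacks_gt51 P(GT51 absent | set absent).
#' @param seed Optional integer seed (caller's RNG preserved when given).
#' @return A cohort tibble ([as_cohort()]).
#' @export
generate_cohort <- function(n_bacteria = 1398,
                            set_prevalence = 1260 / 1398,
                            p_present_given_set = 1.0,
                            p_absent_given_noset = 84 / 108,
                            unknown_frac_noset = 30 / 138,
                            p_noset_lacks_gt51 = 114 / 138,
                            seed = NULL) {
  probs <- c(set_prevalence, p_present_given_set, p_absent_given_noset,
             unknown_frac_noset, p_noset_lacks_gt51)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1]",
          class = "pgtrait_validation_error")
  }
  if (n_bacteria < 1) abort("n_bacteria must be positive",
                            class = "pgtrait_validation_error")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }

  n <- as.integer(n_bacteria)
  set_pos <- stats::runif(n) < set_prevalence

  t1 <- fixture_table1()
  phyla <- t1[t1$level == "phylum", ]
  phylum <- sample(phyla$name, n, replace = TRUE, prob = phyla$n)

  counts <- matrix(0L, n, length(pg_families()),
                   dimnames = list(NULL, pg_families()))
  focal <- pg_focal_gh()
  for (i in seq_len(n)) {
    gt28 <- 1L + stats::rpois(1, 1)
    gt51 <- 1L + stats::rpois(1, 1)
    gh <- stats::rbinom(length(focal), 1, 0.5) *
      (1L + stats::rpois(length(focal), 0.7))
    if (set_pos[i]) {
      if (all(gh == 0L)) gh[sample.int(length(focal), 1)] <- 1L
    } else {
      if (stats::runif(1) < p_noset_lacks_gt51) {
        gt51 <- 0L
      } else if (stats::runif(1) < 0.5) {
        gt28 <- 0L
      } else {
        gh[] <- 0L
      }
    }
    counts[i, "GT28"] <- gt28
    counts[i, "GT51"] <- gt51
    counts[i, focal] <- gh
    counts[i, "GH25"] <- stats::rbinom(1, 1, 0.3) * (1L + stats::rpois(1, 0.5))
  }

  pg_status <- character(n)
  for (i in seq_len(n)) {
    if (set_pos[i]) {
      pg_status[i] <- if (stats::runif(1) < p_present_given_set) "present" else "absent"
    } else if (stats::runif(1) < unknown_frac_noset) {
      pg_status[i] <- "unknown"
    } else {
      pg_status[i] <- if (stats::runif(1) < p_absent_given_noset) "absent" else "present"
    }
  }

  as_cohort(dplyr::bind_cols(
    tibble::tibble(genome_id = sprintf("g%04d", seq_len(n)),
                   domain = "Bacteria", phylum = phylum),
    tibble::as_tibble(counts),
    tibble::tibble(pg_status = pg_status)
  ), provenance = "generate_cohort")
}

#' Generate a cohort with covariates under a known logistic model
#'
#' Companion generator for the regression machinery: binary latent
#' predictors (low GC, small genome, obligate intracellular lifestyle) are
#' drawn independently, PG absence follows a logistic model with the
#' supplied odds ratios, and continuous covariates are drawn on the
#' matching side of the regression cut-offs (GC 50%, size 1.5 Mb).  Used
#' for parameter-recovery checks where the true odds ratios are known.
#'
#' @param n Number of genomes.
#' @param odds_ratios Length-3 vector: low GC, small genome, obligate
#'   intracellular.
#' @param intercept Logistic intercept (baseline log-odds of PG absence).
#' @param p_predictor Probability each latent predictor is on.
#' @param seed Optional integer seed.
#' @return A cohort tibble with covariate columns filled in.
#' @export
simulate_covariate_cohort <- function(n = 2000,
                                      odds_ratios = c(5, 5, 5),
                                      intercept = -2.5,
                                      p_predictor = 0.3,
                                      seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  stopifnot(length(odds_ratios) == 3, all(odds_ratios > 0))
  n <- as.integer(n)
  x <- matrix(stats::runif(3 * n) < p_predictor, n, 3)
  eta <- intercept + x %*% log(odds_ratios)
  pg_absent <- stats::runif(n) < stats::plogis(eta)

  counts <- matrix(1L, n, length(pg_families()),
                   dimnames = list(NULL, pg_families()))
  as_cohort(dplyr::bind_cols(
    tibble::tibble(genome_id = sprintf("g%05d", seq_len(n)),
                   domain = "Bacteria", phylum = "SimPhylum"),
    tibble::as_tibble(counts),
    tibble::tibble(
      pg_status = ifelse(pg_absent, "absent", "present"),
      lifestyle = ifelse(x[, 3], "obligate_intracellular",
                         sample(c("free_living", "other"), n, replace = TRUE)),
      gc_percent = ifelse(x[, 1], stats::runif(n, 30, 49.9),
                          stats::runif(n, 50, 70)),
      genome_size_mb = ifelse(x[, 2], stats::runif(n, 0.5, 1.45),
                              stats::runif(n, 1.55, 8))
    )
  ), provenance = "simulate_covariate_cohort")
}
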