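# Independent oracles used to freeze expected values: exhaustive
# enumeration for parsimony, explicit matrix-exponential summation for the
# pruning likelihood.  Both deliberately avoid the code paths they check.

# Minimum total cost over all assignments of internal node states,
# enumerated exhaustively (2^Nnode assignments).
brute_force_parsimony_cost <- function(tree, tip_states, gain_cost, loss_cost) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  edge <- tree$edge
  states <- as.integer(tip_states[tree$tip.label])
  internals <- (n_tip + 1L):n_node
  trans_cost <- function(p, c) {
    if (p == c) 0 else if (c == 1L) gain_cost else loss_cost
  }
  best <- Inf
  grid <- expand.grid(rep(list(0:1), length(internals)))
  for (g in seq_len(nrow(grid))) {
    st <- integer(n_node)
    st[seq_len(n_tip)] <- states
    st[internals] <- as.integer(grid[g, ])
    total <- 0
    for (e in seq_len(nrow(edge))) {
      total <- total + trans_cost(st[edge[e, 1]], st[edge[e, 2]])
    }
    best <- min(best, total)
  }
  best
}

# Joint two-character likelihood by summing over all internal joint states
# with per-branch transition matrices from Matrix::expm.
brute_force_loglik <- function(tree, trait_a, trait_b, model) {
  Q <- build_generator(model)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length
  if (is.null(elen)) elen <- rep(1, nrow(edge))
  P <- lapply(seq_len(nrow(edge)),
              function(e) as.matrix(Matrix::expm(Q * elen[e])))
  tip_idx <- 2L * as.integer(trait_a[tree$tip.label]) +
    as.integer(trait_b[tree$tip.label]) + 1L
  internals <- (n_tip + 1L):n_node
  total <- 0
  grid <- expand.grid(rep(list(1:4), length(internals)))
  for (g in seq_len(nrow(grid))) {
    st <- integer(n_node)
    st[seq_len(n_tip)] <- tip_idx
    st[internals] <- as.integer(grid[g, ])
    p <- 0.25
    for (e in seq_len(nrow(edge))) {
      p <- p * P[[e]][st[edge[e, 1]], st[edge[e, 2]]]
    }
    total <- total + p
  }
  log(total)
}

# Small fully-specified cohort used across IO and classifier tests.
toy_cohort <- function() {
  as_cohort(tibble::tibble(
    genome_id = c("gA", "gB", "gC"),
    domain = c("Bacteria", "Bacteria", "Eukaryota"),
    phylum = c("Proteobacteria", "Tenericutes", "Unclassified"),
    GT28 = c(2L, 0L, 1L), GT51 = c(1L, 0L, 1L), GH23 = c(3L, 0L, 0L),
    GH25 = c(0L, 0L, 0L), GH73 = c(1L, 0L, 0L), GH102 = c(0L, 0L, 0L),
    GH103 = c(0L, 0L, 1L), GH104 = c(0L, 0L, 0L),
    pg_status = c("present", "absent", "unknown"),
    lifestyle = c("free_living", "obligate_intracellular", NA),
    gc_percent = c(55, 30, NA),
    genome_size_mb = c(4.2, 0.8, NA)
  ))
}
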