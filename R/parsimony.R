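#' Read and validate a rooted phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the assumptions the
#' event analysis relies on: a single rooted tree, unique tip labels, and
#' no unary (singleton) internal nodes (these are collapsed).  Polytomies
#' are allowed.  Branch lengths are optional; the parsimony reconstruction
#' ignores them, the correlated-evolution test substitutes unit lengths
#' when they are missing.
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param text Newick string, used instead of `path` when given.
#' @return An [ape::phylo] object.
#' @export
read_phylogeny <- function(path = NULL, text = NULL) {
  tree <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) {
      abort(paste0("Newick parse error: ", conditionMessage(e)),
            class = "pgtrait_parse_error")
    }
  )
  if (is.null(tree)) {
    abort("Newick parse error: no tree found", class = "pgtrait_parse_error")
  }
  if (inherits(tree, "multiPhylo")) {
    abort("Expected a single tree, found several", class = "pgtrait_parse_error")
  }
  validate_phylogeny(tree)
}

#' @rdname read_phylogeny
#' @param tree An [ape::phylo] object.
#' @export
validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::collapse.singles(tree)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate tip label(s): ", paste(unique(dup), collapse = ", ")),
          class = "pgtrait_parse_error")
  }
  if (!ape::is.rooted(tree)) {
    abort("Tree must be rooted", class = "pgtrait_validation_error")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort("Negative branch lengths are not allowed",
          class = "pgtrait_validation_error")
  }
  tree
}

#' Gain-penalizing parsimony reconstruction of a binary character
#'
#' Sankoff dynamic programming over a rooted tree (polytomies handled
#' natively) with asymmetric transition costs, used to annotate ancestral
#' gene content while penalizing gains: with the default `gain_cost = 2`,
#' `loss_cost = 1`, a single ancestral loss is preferred over repeated
#' independent losses, and gains are inferred only when they save at least
#' two losses.  Setting the two costs equal recovers classical Fitch/Sankoff
#' parsimony for a binary character.
#'
#' Branch lengths are ignored: this is a topology-only parsimony method.
#' Ties are resolved deterministically: at the root, toward state 1
#' (presence, the ancestral-gene-content reading); below the root, toward
#' the parent's state, which pushes unavoidable changes toward the tips.
#' Nodes where a tie occurred carry an `ambiguous` flag.
#'
#' @param tree A rooted [ape::phylo].
#' @param tip_states Named vector (names = tip labels) of states in
#'   \{0, 1\} (logical accepted).
#' @param gain_cost,loss_cost Positive transition costs for 0 to 1 and 1
#'   to 0 changes.
#' @param character_name Label carried into the event table.
#' @return A `parsimony_fit`: node states, total cost, and the inputs
#'   needed to extract per-branch events with [extract_events()].
#' @export
ancestral_parsimony <- function(tree, tip_states, gain_cost = 2,
                                loss_cost = 1, character_name = "trait") {
  tree <- validate_phylogeny(tree)
  if (gain_cost <= 0 || loss_cost <= 0) {
    abort("Costs must be positive", class = "pgtrait_config_error")
  }
  states <- prepare_tip_states(tree, tip_states)

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  edge <- post$edge

  # cost[v, s+1]: minimum subtree cost with node v in state s
  cost <- matrix(0, n_node, 2)
  cost[seq_len(n_tip), 1] <- ifelse(states == 0L, 0, Inf)
  cost[seq_len(n_tip), 2] <- ifelse(states == 1L, 0, Inf)
  trans <- matrix(c(0, gain_cost, loss_cost, 0), 2, 2, byrow = TRUE)

  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2]; parent <- edge[e, 1]
    for (s in 1:2) {
      cost[parent, s] <- cost[parent, s] +
        min(cost[child, 1] + trans[s, 1], cost[child, 2] + trans[s, 2])
    }
  }

  root <- n_tip + 1L
  state <- integer(n_node)
  ambiguous <- logical(n_node)
  state[seq_len(n_tip)] <- states
  # root: minimum cost, tie toward presence
  root_tie <- cost[root, 1] == cost[root, 2]
  state[root] <- if (cost[root, 2] <= cost[root, 1]) 1L else 0L
  ambiguous[root] <- root_tie
  total_cost <- min(cost[root, ])

  # preorder sweep: reverse postorder visits each parent before its children
  for (e in rev(seq_len(nrow(edge)))) {
    child <- edge[e, 2]; parent <- edge[e, 1]
    if (child <= n_tip) next
    sp <- state[parent] + 1L
    c0 <- cost[child, 1] + trans[sp, 1]
    c1 <- cost[child, 2] + trans[sp, 2]
    if (c0 == c1) {
      state[child] <- state[parent]  # tie: delay the change toward the tips
      ambiguous[child] <- TRUE
    } else {
      state[child] <- if (c1 < c0) 1L else 0L
    }
  }

  node_states <- tibble::tibble(
    node = seq_len(n_node),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    is_tip = seq_len(n_node) <= n_tip,
    state = state,
    ambiguous = ambiguous
  )
  structure(list(tree = tree, node_states = node_states,
                 total_cost = total_cost,
                 gain_cost = gain_cost, loss_cost = loss_cost,
                 character_name = character_name),
            class = "parsimony_fit")
}

#' @export
print.parsimony_fit <- function(x, ...) {
  ev <- extract_events(x)
  cat("<parsimony_fit>", x$character_name, "on",
      length(x$tree$tip.label), "tips; cost", x$total_cost,
      sprintf("(gain %s / loss %s);", x$gain_cost, x$loss_cost),
      sum(ev$type == "gain"), "gain(s),", sum(ev$type == "loss"), "loss(es)\n")
  invisible(x)
}

#' @export
tidy.parsimony_fit <- function(x, ...) x$node_states

#' @export
glance.parsimony_fit <- function(x, ...) {
  ev <- extract_events(x)
  tibble::tibble(character = x$character_name,
                 n_tips = length(x$tree$tip.label),
                 total_cost = x$total_cost,
                 n_gains = sum(ev$type == "gain"),
                 n_losses = sum(ev$type == "loss"))
}

#' Per-branch gain/loss events of a reconstruction
#'
#' One event per branch whose endpoint states differ: a gain where the
#' parent is 0 and the child 1, a loss where the parent is 1 and the child
#' 0.  A branch (the "date" in the clustering step) is identified by its
#' child node id; the root has no incoming branch and hosts no event.
#'
#' @param fit A `parsimony_fit` from [ancestral_parsimony()].
#' @return A tibble: `character`, `type` (gain/loss), `parent`, `child`
#'   (node ids), `child_label` (tip label where the child is a tip).
#' @export
extract_events <- function(fit) {
  stopifnot(inherits(fit, "parsimony_fit"))
  edge <- fit$tree$edge
  st <- fit$node_states$state
  ps <- st[edge[, 1]]
  cs <- st[edge[, 2]]
  changed <- ps != cs
  tibble::tibble(
    character = fit$character_name,
    type = ifelse(cs[changed] == 1L, "gain", "loss"),
    parent = edge[changed, 1],
    child = edge[changed, 2],
    child_label = fit$node_states$label[edge[changed, 2]]
  )
}

#' Tip states for a tree from a cohort
#'
#' Joins an annotation cohort to the tips of a tree and returns the binary
#' character requested: presence of one family, presence of the complete
#' minimal set, or presence of PG.  For the PG character, unknown-status
#' genomes cannot provide a state: their tips are pruned from the returned
#' tree and listed in `dropped`.
#'
#' @param cohort A cohort tibble.
#' @param tree A rooted [ape::phylo] whose tip labels are `genome_id`s.
#' @param what One of [pg_families()], `"set"`, or `"pg"`.
#' @param rule Rule used when `what = "set"`.
#' @return A list: `states` (named 0/1 vector over the returned tree's
#'   tips), `tree` (possibly pruned), `dropped` (tips removed for unknown
#'   PG status).
#' @export
tip_states_from_cohort <- function(cohort, tree, what, rule = geneset_rule()) {
  cohort <- as_cohort(cohort)
  tree <- validate_phylogeny(tree)
  choices <- c(pg_families(), "set", "pg")
  if (!what %in% choices) {
    abort(paste0("Unknown character: ", what), class = "pgtrait_config_error")
  }
  missing_tips <- setdiff(tree$tip.label, cohort$genome_id)
  if (length(missing_tips) > 0) {
    abort(paste0("Tree tip(s) absent from cohort: ",
                 paste(missing_tips, collapse = ", ")),
          class = "pgtrait_validation_error")
  }
  idx <- match(tree$tip.label, cohort$genome_id)
  dropped <- character(0)
  if (what == "pg") {
    status <- cohort$pg_status[idx]
    dropped <- tree$tip.label[status == "unknown"]
    if (length(dropped) > 0) {
      if (length(tree$tip.label) - length(dropped) < 2) {
        abort("Fewer than 2 tips with known PG status remain",
              class = "pgtrait_validation_error")
      }
      tree <- ape::drop.tip(tree, dropped)
      idx <- match(tree$tip.label, cohort$genome_id)
      status <- cohort$pg_status[idx]
    }
    states <- as.integer(status == "present")
  } else if (what == "set") {
    profile <- binarize(cohort)[idx, ]
    states <- as.integer(has_minimal_set(profile, rule))
  } else {
    states <- as.integer(cohort[[what]][idx] >= 1L)
  }
  list(states = stats::setNames(states, tree$tip.label), tree = tree,
       dropped = dropped)
}

# Validate + align a named tip-state vector with a tree (0/1 integer out).
prepare_tip_states <- function(tree, tip_states) {
  if (is.logical(tip_states)) tip_states <- as.integer(tip_states)
  if (is.null(names(tip_states))) {
    abort("tip_states must be named by tip label",
          class = "pgtrait_validation_error")
  }
  missing_tips <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing_tips) > 0) {
    abort(paste0("No state for tip(s): ", paste(missing_tips, collapse = ", ")),
          class = "pgtrait_validation_error")
  }
  states <- as.integer(tip_states[tree$tip.label])
  if (anyNA(states) || !all(states %in% c(0L, 1L))) {
    abort("tip_states must be 0/1", class = "pgtrait_validation_error")
  }
  states
}
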