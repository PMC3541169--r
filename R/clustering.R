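#' Cluster gain/loss events that co-occur on shared branches
#'
#' `cluster_by_date()` groups (character, event-type) pairs that recur
#' together on the same branches ("dates", branches framed by two
#' speciation events).  Co-occurrence is read at branch granularity: two
#' events co-occur when they sit on the branch with the same child node.
#' The clusters reported are the closed co-occurring sets: a set of events
#' is a cluster when it appears jointly on at least `min_dates` branches
#' and no strictly larger set appears on exactly the same branches.
#' `n_dates` counts the branches where every member co-occurs.
#'
#' `cluster_by_feature()` instead groups characters whose events fall on
#' similar branch sets (profile similarity): characters whose event-branch
#' profiles have Jaccard similarity at or above `jaccard_threshold`
#' (default 1, identical profiles) are merged by single linkage.  Feature
#' clusters may mix gains and losses and singletons are kept.
#'
#' @param events An event tibble ([extract_events()] output, several
#'   characters row-bound; columns `character`, `type`, `parent`,
#'   `child`).
#' @param min_dates Minimum number of shared branches for a date cluster.
#' @return An `event_clusters` object: a `clusters` tibble (cluster id,
#'   member events, dates, `n_dates`) plus the unclustered remainder, so
#'   no event is silently dropped.
#' @export
cluster_by_date <- function(events, min_dates = 2) {
  events <- check_events(events)
  empty <- event_clusters(tibble::tibble(
    cluster = integer(), members = list(), n_events = integer(),
    dates = list(), n_dates = integer()
  ), events, "date")
  if (nrow(events) == 0) return(empty)

  events$item <- paste(events$type, events$character)
  branch_sets <- lapply(split(events$item, events$child), unique)
  branches <- names(branch_sets)

  # candidate closed sets: branch itemsets closed under pairwise intersection
  cand <- unique(lapply(branch_sets, sort))
  repeat {
    extra <- list()
    for (i in seq_along(cand)) {
      for (j in seq_along(cand)) {
        if (i < j) {
          s <- intersect(cand[[i]], cand[[j]])
          if (length(s) >= 2 && !any(vapply(c(cand, extra), identical, TRUE, y = s)))
            extra[[length(extra) + 1L]] <- s
        }
      }
    }
    if (length(extra) == 0) break
    cand <- c(cand, extra)
  }
  cand <- Filter(function(s) length(s) >= 2, cand)

  support_of <- function(s) {
    branches[vapply(branch_sets, function(bs) all(s %in% bs), TRUE)]
  }
  rows <- list()
  for (s in cand) {
    supp <- support_of(s)
    if (length(supp) < min_dates) next
    closure <- sort(Reduce(intersect, branch_sets[supp]))
    if (!identical(sort(s), closure)) next  # not closed: a superset shares its dates
    rows[[length(rows) + 1L]] <- tibble::tibble(
      members = list(parse_items(s)), n_events = length(s),
      dates = list(as.integer(supp)), n_dates = length(supp)
    )
  }
  if (length(rows) == 0) return(empty)
  clusters <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$n_dates), dplyr::desc(.data$n_events)) |>
    dplyr::mutate(cluster = dplyr::row_number(), .before = 1)
  event_clusters(clusters, events, "date")
}

#' @rdname cluster_by_date
#' @param jaccard_threshold Minimum Jaccard similarity of two characters'
#'   event-branch profiles for them to be merged.
#' @export
cluster_by_feature <- function(events, jaccard_threshold = 1) {
  events <- check_events(events)
  if (jaccard_threshold <= 0 || jaccard_threshold > 1) {
    abort("jaccard_threshold must lie in (0, 1]", class = "pgtrait_config_error")
  }
  if (nrow(events) == 0) {
    return(event_clusters(tibble::tibble(
      cluster = integer(), members = list(), n_events = integer(),
      dates = list(), n_dates = integer()
    ), events, "feature"))
  }
  chars <- sort(unique(events$character))
  profiles <- lapply(chars, function(ch) unique(events$child[events$character == ch]))
  names(profiles) <- chars

  # single-linkage merge via union-find
  parent <- seq_along(chars)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(chars)) {
    for (j in seq_along(chars)) {
      if (i < j) {
        jac <- length(intersect(profiles[[i]], profiles[[j]])) /
          length(union(profiles[[i]], profiles[[j]]))
        if (jac >= jaccard_threshold) parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_along(chars), find, 1L)
  rows <- lapply(unique(comp), function(cid) {
    members_chr <- chars[comp == cid]
    ev <- events[events$character %in% members_chr, ]
    items <- unique(ev[, c("character", "type")])
    shared <- Reduce(intersect, profiles[members_chr])
    tibble::tibble(members = list(items), n_events = nrow(items),
                   dates = list(as.integer(sort(shared))),
                   n_dates = length(shared))
  })
  clusters <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$n_dates)) |>
    dplyr::mutate(cluster = dplyr::row_number(), .before = 1)
  event_clusters(clusters, events, "feature")
}

check_events <- function(events) {
  needed <- c("character", "type", "parent", "child")
  if (!all(needed %in% names(events))) {
    abort(paste0("Event table needs columns: ", paste(needed, collapse = ", ")),
          class = "pgtrait_validation_error")
  }
  if (nrow(events) > 0 && !all(events$type %in% c("gain", "loss"))) {
    abort("Event type must be gain or loss", class = "pgtrait_validation_error")
  }
  tibble::as_tibble(events)
}

parse_items <- function(items) {
  parts <- strsplit(items, " ", fixed = TRUE)
  tibble::tibble(character = vapply(parts, `[`, "", 2),
                 type = vapply(parts, `[`, "", 1))
}

event_clusters <- function(clusters, events, method) {
  covered <- rep(FALSE, nrow(events))
  if (nrow(clusters) > 0 && nrow(events) > 0) {
    for (i in seq_len(nrow(clusters))) {
      m <- clusters$members[[i]]
      key <- paste(m$type, m$character)
      covered <- covered |
        (paste(events$type, events$character) %in% key &
           events$child %in% clusters$dates[[i]])
    }
  }
  structure(list(clusters = clusters,
                 unclustered = events[!covered,
                                      c("character", "type", "parent", "child")],
                 method = method),
            class = "event_clusters")
}

#' @export
print.event_clusters <- function(x, ...) {
  cat("<event_clusters>", x$method, "clustering:", nrow(x$clusters),
      "cluster(s),", nrow(x$unclustered), "unclustered event(s)\n")
  if (nrow(x$clusters) > 0) print(tidy(x))
  invisible(x)
}

#' @export
tidy.event_clusters <- function(x, ...) {
  if (nrow(x$clusters) == 0) {
    return(tibble::tibble(cluster = integer(), character = character(),
                          type = character(), n_dates = integer()))
  }
  purrr::pmap(list(x$clusters$cluster, x$clusters$members,
                   x$clusters$n_dates), function(id, m, nd) {
    dplyr::mutate(m, cluster = id, n_dates = nd, .before = 1)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("cluster", "n_dates", "character", "type")
}

#' Verify event clusters with the correlated-evolution test
#'
#' For every pair of distinct characters inside a cluster, runs
#' [pagel_test()] on their tip states and attaches the scores; a cluster is
#' flagged `supported` when every pairwise error percentage is at most
#' `max_error` (default 5, i.e. a Monte-Carlo p-value of 0.05).  Clusters
#' involving a single character cannot be verified this way and carry an
#' `NA` flag with a note.
#'
#' @param x An `event_clusters` object.
#' @param tree The tree the events were reconstructed on.
#' @param traits Named list of named 0/1 tip-state vectors, one per
#'   character name appearing in the clusters.
#' @param n_sim,seed,n_starts Passed to [pagel_test()].
#' @param max_error Support cut-off on the error percentage.
#' @return The `event_clusters` object with `verification` and
#'   `supported` columns added to its `clusters` tibble.
#' @export
verify_clusters <- function(x, tree, traits, n_sim = 99, seed = 1L,
                            n_starts = 5, max_error = 5) {
  stopifnot(inherits(x, "event_clusters"))
  if (nrow(x$clusters) == 0) return(x)
  verifications <- vector("list", nrow(x$clusters))
  supported <- rep(NA, nrow(x$clusters))
  for (i in seq_len(nrow(x$clusters))) {
    chars <- unique(x$clusters$members[[i]]$character)
    missing_traits <- setdiff(chars, names(traits))
    if (length(missing_traits) > 0) {
      abort(paste0("No tip states supplied for character(s): ",
                   paste(missing_traits, collapse = ", ")),
            class = "pgtrait_validation_error")
    }
    if (length(chars) < 2) {
      verifications[[i]] <- tibble::tibble(
        character_a = NA_character_, character_b = NA_character_,
        score = NA_real_, error_percentage = NA_real_,
        note = "single-character cluster: verification skipped")
      next
    }
    pairs <- utils::combn(chars, 2)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      ta <- traits[[pairs[1, k]]]; tb <- traits[[pairs[2, k]]]
      shared <- intersect(intersect(names(ta), names(tb)), tree$tip.label)
      tr <- if (length(shared) < length(tree$tip.label)) {
        ape::keep.tip(tree, shared)
      } else tree
      fit <- pagel_test(tr, ta[shared], tb[shared],
                        n_sim = n_sim, seed = seed + k, n_starts = n_starts)
      tibble::tibble(character_a = pairs[1, k], character_b = pairs[2, k],
                     score = fit$score,
                     error_percentage = fit$error_percentage,
                     note = NA_character_)
    })
    verifications[[i]] <- dplyr::bind_rows(rows)
    supported[i] <- all(verifications[[i]]$error_percentage <= max_error)
  }
  x$clusters$verification <- verifications
  x$clusters$supported <- supported
  x
}
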