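#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end on one cohort (and optionally one
#' tree): gene-set classification with diagnostic metrics, the statistical
#' battery (per-family associations, phi correlations, PCA, covariate
#' regression when covariates are present), parsimony gain/loss events per
#' character, the correlated-evolution test for configured trait pairs,
#' and event clustering with optional verification.  Each stage writes its
#' report (JSON with sorted keys, TSV mirrors for tables) into `out_dir`,
#' plus a manifest recording the configuration and seed; a rerun with the
#' same inputs and seed is byte-identical.  A stage failure aborts with
#' the stage name; reports already written are preserved.
#'
#' @param cohort A cohort tibble or a path to an annotation TSV.
#' @param tree A rooted [ape::phylo], a Newick path, or `NULL` (the
#'   phylogenetic stages are then skipped).
#' @param out_dir Output directory (created if needed).
#' @param rule Gene-set rule for classification.
#' @param characters Characters to reconstruct events for (families,
#'   `"set"`, `"pg"`).
#' @param pagel_pairs List of length-2 character vectors to test for
#'   correlated evolution.
#' @param gain_cost,loss_cost Parsimony costs.
#' @param n_sim Bootstrap simulations for [pagel_test()].
#' @param seed Integer seed for every stochastic step.
#' @param stages Subset of `c("classify", "stats", "events", "pagel",
#'   "clusters")`.
#' @param verify Run pairwise verification on date clusters.
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with per-stage results and output paths.
#' @export
run_pipeline <- function(cohort, tree = NULL, out_dir,
                         rule = geneset_rule(),
                         characters = c("GT51", "set", "pg"),
                         pagel_pairs = list(c("GT51", "pg")),
                         gain_cost = 2, loss_cost = 1,
                         n_sim = 99, seed = 1L,
                         stages = c("classify", "stats", "events",
                                    "pagel", "clusters"),
                         verify = TRUE, quiet = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  cohort <- as_cohort(cohort)
  if (is.character(tree)) tree <- read_phylogeny(tree)
  if (is.null(tree)) stages <- setdiff(stages, c("events", "pagel", "clusters"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say <- function(...) if (!quiet) message("[pgtrait] ", ...)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "pgtrait_pipeline_error")
    })
  }
  results <- list()

  if ("classify" %in% stages) {
    say("classify")
    results$classify <- run_stage("classify", {
      predictions <- classify_cohort(cohort, rule)
      survey <- classification_summary(cohort, rule)
      set_conf <- confusion(predictions, cohort, positive_means = "pg_present")
      gt51_pred <- cohort$GT51 == 0L
      gt51_conf <- confusion(gt51_pred, cohort, positive_means = "pg_absent")
      metrics <- list(
        set = as.list(diagnostic_metrics(set_conf)),
        gt51_absence = as.list(diagnostic_metrics(gt51_conf))
      )
      readr::write_tsv(predictions, file.path(out_dir, "predictions.tsv"),
                       progress = FALSE)
      readr::write_tsv(survey, file.path(out_dir, "survey.tsv"),
                       progress = FALSE)
      write_report(metrics, file.path(out_dir, "metrics.json"))
      list(predictions = predictions, survey = survey, metrics = metrics)
    })
  }

  if ("stats" %in% stages) {
    say("stats")
    results$stats <- run_stage("stats", {
      out <- list()
      if (length(unique(cohort$domain)) > 1) {
        out$domain_association <- purrr::map(pg_families(), function(f) {
          res <- chisq_association(family_domain_table(cohort, f))
          c(list(family = f), as.list(res))
        })
      }
      known <- cohort$pg_status != "unknown"
      if (any(cohort$pg_status[known] == "absent") &&
          any(cohort$pg_status[known] == "present")) {
        out$absence_correlation <- purrr::map(pg_families(), function(f) {
          list(family = f, phi = phi_correlation(absence_pg_table(cohort, f)))
        })
        pca <- tryCatch(suppressWarnings(absence_pca(cohort)),
                        error = function(e) NULL)
        if (!is.null(pca)) {
          out$pca_loadings <- purrr::transpose(as.list(tidy(pca)))
        }
      }
      if (all(c("lifestyle", "gc_percent", "genome_size_mb") %in% names(cohort))) {
        reg <- tryCatch(pg_absence_regression(cohort), error = function(e) NULL)
        if (!is.null(reg)) {
          out$regression <- list(terms = purrr::transpose(as.list(tidy(reg))),
                                 fit = purrr::transpose(as.list(glance(reg))))
        }
      }
      write_report(out, file.path(out_dir, "stats.json"))
      out
    })
  }

  events_all <- NULL
  traits <- list()
  if (any(c("events", "pagel", "clusters") %in% stages)) {
    for (ch in union(characters, unlist(pagel_pairs))) {
      ts <- tip_states_from_cohort(cohort, tree, ch, rule)
      traits[[ch]] <- ts
    }
  }

  if ("events" %in% stages) {
    say("events")
    results$events <- run_stage("events", {
      fits <- purrr::map(characters, function(ch) {
        ts <- traits[[ch]]
        ancestral_parsimony(ts$tree, ts$states, gain_cost, loss_cost,
                            character_name = ch)
      })
      events <- dplyr::bind_rows(purrr::map(fits, extract_events))
      summary <- dplyr::bind_rows(purrr::map(fits, glance))
      readr::write_tsv(events, file.path(out_dir, "events.tsv"),
                       progress = FALSE)
      write_report(list(summary = purrr::transpose(as.list(summary)),
                        events = purrr::transpose(as.list(events))),
                   file.path(out_dir, "events.json"))
      list(fits = stats::setNames(fits, characters), events = events,
           summary = summary)
    })
    events_all <- results$events$events
  }

  if ("pagel" %in% stages) {
    say("pagel")
    results$pagel <- run_stage("pagel", {
      fits <- purrr::imap(pagel_pairs, function(pair, i) {
        ta <- traits[[pair[1]]]; tb <- traits[[pair[2]]]
        shared <- intersect(ta$tree$tip.label, tb$tree$tip.label)
        tr <- if (length(shared) < length(tree$tip.label)) {
          ape::keep.tip(tree, shared)
        } else tree
        pagel_test(tr, ta$states[shared], tb$states[shared],
                   n_sim = n_sim, seed = seed + i)
      })
      report <- purrr::map2(pagel_pairs, fits, function(pair, fit) {
        c(list(trait_a = pair[1], trait_b = pair[2]),
          as.list(glance(fit)))
      })
      write_report(report, file.path(out_dir, "pagel.json"))
      list(fits = fits, report = report)
    })
  }

  if ("clusters" %in% stages) {
    say("clusters")
    results$clusters <- run_stage("clusters", {
      if (is.null(events_all)) {
        fits <- purrr::map(characters, function(ch) {
          ts <- traits[[ch]]
          ancestral_parsimony(ts$tree, ts$states, gain_cost, loss_cost,
                              character_name = ch)
        })
        events_all <- dplyr::bind_rows(purrr::map(fits, extract_events))
      }
      by_date <- cluster_by_date(events_all)
      by_feature <- cluster_by_feature(events_all)
      if (verify && nrow(by_date$clusters) > 0) {
        trait_states <- purrr::map(traits, "states")
        by_date <- verify_clusters(by_date, tree, trait_states,
                                   n_sim = n_sim, seed = seed)
      }
      write_report(list(by_date = clusters_report(by_date),
                        by_feature = clusters_report(by_feature)),
                   file.path(out_dir, "clusters.json"))
      list(by_date = by_date, by_feature = by_feature)
    })
  }

  manifest <- list(
    package = "pgtrait",
    version = as.character(utils::packageVersion("pgtrait")),
    seed = as.integer(seed),
    n_sim = as.integer(n_sim),
    gain_cost = gain_cost, loss_cost = loss_cost,
    rule = list(required_all = rule$required_all,
                required_any = rule$required_any, min_any = rule$min_any),
    characters = characters,
    stages = stages,
    n_genomes = nrow(cohort),
    n_tips = if (is.null(tree)) 0L else length(tree$tip.label)
  )
  write_report(manifest, file.path(out_dir, "manifest.json"))
  results$manifest <- manifest
  invisible(results)
}

# Table 2-shaped flat report of a cluster set.
clusters_report <- function(x) {
  cl <- x$clusters
  verif <- if ("verification" %in% names(cl)) cl$verification
           else vector("list", nrow(cl))
  supp <- if ("supported" %in% names(cl)) cl$supported else rep(NA, nrow(cl))
  rows <- purrr::pmap(
    list(cl$cluster, cl$members, cl$dates, cl$n_dates, verif, as.list(supp)),
    function(id, members, dates, n_dates, verification, supported) {
      out <- list(cluster = id,
                  n_dates = n_dates,
                  dates = as.integer(dates),
                  events = paste(members$type, members$character))
      if (!is.null(verification) && nrow(verification) > 0) {
        out$verification <- purrr::transpose(as.list(
          verification[, c("character_a", "character_b", "score",
                           "error_percentage")]))
      }
      if (!is.na(supported)) out$supported <- supported
      out
    })
  list(method = x$method, clusters = rows,
       unclustered = purrr::transpose(as.list(x$unclustered)))
}

# Canonical JSON: keys sorted recursively, full precision, unboxed scalars.
write_report <- function(x, path) {
  jsonlite::write_json(sort_keys(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

sort_keys <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    lapply(x, sort_keys)
  } else x
}
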