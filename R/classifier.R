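#' Minimal gene-set rules for peptidoglycan metabolic capacity
#'
#' The default rule is the minimal 3-gene set: a genome is predicted capable
#' of PG metabolism when it carries GT28 (dimer synthesis) AND GT51 (glycan
#' polymerization) AND at least one of the five focal hydrolase families
#' GH23/GH73/GH102/GH103/GH104 (lysis).  Both the family lists and the
#' minimum number of hydrolase families are configurable, so the six-family
#' variant that also admits GH25 is one argument away.
#'
#' @param required_all Families that must all be present.
#' @param required_any Families of which at least `min_any` must be present.
#' @param min_any Minimum number of `required_any` families present.
#' @return A `geneset_rule` object.
#' @export
geneset_rule <- function(required_all = c("GT28", "GT51"),
                         required_any = pg_focal_gh(),
                         min_any = 1L) {
  unknown <- setdiff(c(required_all, required_any), pg_families())
  if (length(unknown) > 0) {
    abort(paste0("Rule references unknown family: ",
                 paste(unknown, collapse = ", ")),
          class = "pgtrait_config_error")
  }
  if (length(intersect(required_all, required_any)) > 0) {
    abort("required_all and required_any must be disjoint",
          class = "pgtrait_config_error")
  }
  min_any <- as.integer(min_any)
  if (min_any < 1L) {
    abort("min_any must be at least 1", class = "pgtrait_config_error")
  }
  structure(list(required_all = required_all, required_any = required_any,
                 min_any = min_any),
            class = "geneset_rule")
}

#' @export
print.geneset_rule <- function(x, ...) {
  cat("<geneset_rule> all of {", paste(x$required_all, collapse = ", "),
      "} and >= ", x$min_any, " of {", paste(x$required_any, collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' Apply a gene-set rule to presence profiles
#'
#' @param profile A presence-profile tibble from [binarize()] (logical
#'   columns per family), or a single named logical vector.
#' @param rule A [geneset_rule()].
#' @return A logical vector, one prediction per profile row.
#' @export
has_minimal_set <- function(profile, rule = geneset_rule()) {
  stopifnot(inherits(rule, "geneset_rule"))
  if (is.logical(profile) && !is.null(names(profile))) {
    profile <- tibble::as_tibble(as.list(profile))
  }
  needed <- c(rule$required_all, rule$required_any)
  missing_fam <- setdiff(needed, names(profile))
  if (length(missing_fam) > 0) {
    abort(paste0("Profile lacks family column(s): ",
                 paste(missing_fam, collapse = ", ")),
          class = "pgtrait_config_error")
  }
  all_ok <- rep(TRUE, nrow(profile))
  for (fam in rule$required_all) all_ok <- all_ok & profile[[fam]]
  n_any <- rowSums(as.matrix(profile[, rule$required_any, drop = FALSE]))
  all_ok & (n_any >= rule$min_any)
}

#' Classify a cohort with a gene-set rule
#'
#' @param cohort A cohort tibble ([as_cohort()]).
#' @param rule A [geneset_rule()].
#' @return The cohort's identifying columns plus a logical `set_positive`
#'   prediction per genome, in input order.
#' @export
classify_cohort <- function(cohort, rule = geneset_rule()) {
  cohort <- as_cohort(cohort)
  profile <- binarize(cohort)
  tibble::tibble(
    genome_id = cohort$genome_id,
    domain = cohort$domain,
    phylum = cohort$phylum,
    pg_status = cohort$pg_status,
    set_positive = has_minimal_set(profile, rule)
  )
}

#' Per-group survey of family presence and complete-set counts
#'
#' Summarizes a cohort the way the published per-phylum table is laid out:
#' one row per domain (plus one per bacterial phylum), with the number of
#' genomes carrying each family and the number carrying the complete set.
#'
#' @inheritParams classify_cohort
#' @return A tibble with `level`, `name`, `n`, per-family positive counts
#'   and `complete_set`.
#' @export
classification_summary <- function(cohort, rule = geneset_rule()) {
  cohort <- as_cohort(cohort)
  profile <- binarize(cohort)
  pos <- has_minimal_set(profile, rule)
  base <- dplyr::bind_cols(
    cohort[, c("domain", "phylum")],
    profile[, pg_families()],
    tibble::tibble(complete_set = pos)
  )
  summarize_group <- function(df, level, name) {
    counts <- lapply(df[, c(pg_families(), "complete_set")], function(v) sum(v))
    dplyr::bind_cols(tibble::tibble(level = level, name = name, n = nrow(df)),
                     tibble::as_tibble(counts))
  }
  domains <- base |>
    dplyr::group_by(.data$domain) |>
    dplyr::group_map(~ summarize_group(.x, "domain", .y$domain)) |>
    dplyr::bind_rows()
  phyla <- base |>
    dplyr::filter(.data$domain == "Bacteria") |>
    dplyr::group_by(.data$phylum) |>
    dplyr::group_map(~ summarize_group(.x, "phylum", .y$phylum)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(domains, phyla)
}

#' Confusion counts against three-valued PG truth
#'
#' Cross-tabulates binary predictions against literature PG status.
#' Genomes with unknown status are excluded from the table and counted in
#' `excluded_unknown`; they are never imputed.  The `positive_means`
#' argument states what a positive prediction asserts, because both
#' orientations are in use: the 3-gene set predicts PG presence, while GT51
#' absence predicts PG absence.
#'
#' @param predictions Logical vector, or a tibble from [classify_cohort()]
#'   (its `set_positive` column is used).
#' @param cohort The cohort the predictions align with.
#' @param positive_means `"pg_present"` or `"pg_absent"`.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `excluded_unknown`.
#' @export
confusion <- function(predictions, cohort,
                      positive_means = c("pg_present", "pg_absent")) {
  positive_means <- match.arg(positive_means)
  if (is.data.frame(predictions)) predictions <- predictions$set_positive
  cohort <- as_cohort(cohort)
  if (length(predictions) != nrow(cohort)) {
    abort("predictions and cohort have different lengths",
          class = "pgtrait_validation_error")
  }
  status <- cohort$pg_status
  known <- status != "unknown"
  truth_pos <- if (positive_means == "pg_present") {
    status[known] == "present"
  } else {
    status[known] == "absent"
  }
  pred <- predictions[known]
  confusion_counts(
    tp = sum(pred & truth_pos),
    fp = sum(pred & !truth_pos),
    tn = sum(!pred & !truth_pos),
    fn = sum(!pred & truth_pos),
    excluded_unknown = sum(!known)
  )
}

#' @rdname confusion
#' @param tp,fp,tn,fn,excluded_unknown Non-negative integer counts, for
#'   building a confusion table directly (e.g. from published counts).
#' @export
confusion_counts <- function(tp, fp, tn, fn, excluded_unknown = 0L) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn,
              excluded_unknown = excluded_unknown)
  if (any(counts < 0)) {
    abort("Confusion counts must be non-negative",
          class = "pgtrait_validation_error")
  }
  tibble::tibble(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn),
                 excluded_unknown = as.integer(excluded_unknown))
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive
#' value tp/(tp+fp) and negative predictive value tn/(tn+fn).  A metric
#' whose denominator is zero is reported as `NA` (undefined), never as 0 or
#' 1, so "no data" stays distinguishable from a perfect score.
#'
#' @param counts A confusion tibble from [confusion()] or
#'   [confusion_counts()].
#' @return A one-row tibble with the four metrics as fractions in \[0, 1\]
#'   (or `NA`), plus the counts carried through.
#' @export
diagnostic_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, tibble::tibble(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    tp = tp, fp = fp, tn = tn, fn = fn,
    excluded_unknown = counts$excluded_unknown %||% 0L
  ))
}
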