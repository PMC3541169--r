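#' Genome annotation cohorts
#'
#' A cohort is a tibble with one row per genome: an identifier, taxonomy
#' (domain, phylum), gene counts for the eight CAZy families involved in
#' peptidoglycan (PG) metabolism ([pg_families()]), the literature PG status,
#' and optional covariates (lifestyle, GC percentage, genome size in Mb).
#' `as_cohort()` validates and normalizes a data frame into this shape;
#' `read_cohort()` and `write_cohort()` move cohorts through tab-separated
#' files with that schema.
#'
#' PG status is three-valued: `"present"`, `"absent"`, `"unknown"`.  On
#' input, common aliases are normalized (`+`/`yes`/`1` to present,
#' `-`/`no`/`0` to absent, `ND`/`NA`/empty/`?` to unknown, case-insensitive).
#' An unknown status is never imputed; downstream metrics exclude those rows
#' explicitly and report how many were excluded.
#'
#' @param x A data frame with the required columns (see Details).
#' @param provenance Optional free-text note stored as the `"provenance"`
#'   attribute of the returned tibble.
#'
#' @details Required columns: `genome_id`, `domain` (one of Bacteria,
#'   Archaea, Eukaryota, Viruses), `phylum`, the eight family-count columns
#'   named by [pg_families()], and `pg_status`.  Optional columns:
#'   `lifestyle` (free_living / obligate_intracellular / other), `gc_percent`
#'   (0-100), `genome_size_mb` (positive).  Column order is free; extra
#'   columns are preserved.
#'
#' @return A tibble with validated columns, counts as integers, and
#'   `pg_status` normalized to the three canonical values.
#' @export
as_cohort <- function(x, provenance = NULL) {
  x <- tibble::as_tibble(x)
  required <- c("genome_id", "domain", "phylum", pg_families(), "pg_status")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pgtrait_schema_error")
  }

  x$genome_id <- as.character(x$genome_id)
  dup <- x$genome_id[duplicated(x$genome_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate genome_id: ", paste(unique(dup), collapse = ", ")),
          class = "pgtrait_validation_error")
  }

  bad_domain <- setdiff(unique(x$domain), pg_domains())
  if (length(bad_domain) > 0) {
    abort(paste0("Unknown domain value(s): ", paste(bad_domain, collapse = ", "),
                 " (expected ", paste(pg_domains(), collapse = "/"), ")"),
          class = "pgtrait_validation_error")
  }

  for (fam in pg_families()) {
    counts <- x[[fam]]
    if (is.character(counts)) counts <- suppressWarnings(as.numeric(counts))
    if (anyNA(counts)) {
      abort(paste0("Column ", fam, " contains missing or malformed counts"),
            class = "pgtrait_validation_error")
    }
    if (any(counts < 0) || any(counts != trunc(counts))) {
      abort(paste0("Column ", fam, " must hold non-negative integer counts"),
            class = "pgtrait_validation_error")
    }
    x[[fam]] <- as.integer(counts)
  }

  x$pg_status <- normalize_pg_status(x$pg_status)

  if (!is.null(x[["lifestyle"]])) {
    ls_known <- c("free_living", "obligate_intracellular", "other")
    bad <- setdiff(unique(stats::na.omit(x$lifestyle)), ls_known)
    if (length(bad) > 0) {
      abort(paste0("Unknown lifestyle value(s): ", paste(bad, collapse = ", ")),
            class = "pgtrait_validation_error")
    }
  }
  if (!is.null(x[["gc_percent"]])) {
    gc <- x$gc_percent
    if (any(!is.na(gc) & (gc < 0 | gc > 100))) {
      abort("gc_percent must lie in [0, 100]", class = "pgtrait_validation_error")
    }
  }
  if (!is.null(x[["genome_size_mb"]])) {
    sz <- x$genome_size_mb
    if (any(!is.na(sz) & sz <= 0)) {
      abort("genome_size_mb must be positive", class = "pgtrait_validation_error")
    }
  }

  if (!is.null(provenance)) attr(x, "provenance") <- provenance
  x
}

#' @rdname as_cohort
#' @param path Path to a UTF-8, tab-separated annotation table.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Annotation file not found: ", path),
          class = "pgtrait_schema_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  for (col in c("gc_percent", "genome_size_mb")) {
    if (col %in% names(raw)) {
      v <- raw[[col]]
      v[v %in% c("", "NA", "ND")] <- NA_character_
      raw[[col]] <- suppressWarnings(as.numeric(v))
    }
  }
  if ("lifestyle" %in% names(raw)) {
    v <- raw$lifestyle
    v[v %in% c("", "NA", "ND")] <- NA_character_
    raw$lifestyle <- v
  }
  as_cohort(raw, provenance = paste0("read_cohort: ", path))
}

#' @rdname as_cohort
#' @param cohort A validated cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  canonical <- c("genome_id", "domain", "phylum", pg_families(), "pg_status",
                 intersect(c("lifestyle", "gc_percent", "genome_size_mb"),
                           names(cohort)))
  extra <- setdiff(names(cohort), canonical)
  readr::write_tsv(cohort[, c(canonical, extra)], path, progress = FALSE)
  invisible(path)
}

#' @export
#' @rdname as_cohort
pg_domains <- function() c("Bacteria", "Archaea", "Eukaryota", "Viruses")

# Alias table for three-valued PG status; unknown is explicit, never imputed.
normalize_pg_status <- function(status) {
  s <- tolower(trimws(as.character(status)))
  s[is.na(s)] <- "unknown"
  out <- dplyr::case_match(
    s,
    c("present", "+", "1", "yes", "p") ~ "present",
    c("absent", "-", "0", "no", "a") ~ "absent",
    c("unknown", "nd", "na", "", "?") ~ "unknown",
    .default = NA_character_
  )
  if (anyNA(out)) {
    bad <- unique(status[is.na(out)])
    abort(paste0("Unrecognized pg_status value(s): ",
                 paste(bad, collapse = ", ")),
          class = "pgtrait_validation_error")
  }
  out
}

#' Binarize family counts into presence/absence profiles
#'
#' A family is present in a genome when its gene count is at least one; CAZy
#' reports counts and any positive count is treated as presence.
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @return A tibble with `genome_id` and one logical column per family.
#' @export
binarize <- function(cohort) {
  cohort <- as_cohort(cohort)
  out <- tibble::tibble(genome_id = cohort$genome_id)
  for (fam in pg_families()) out[[fam]] <- cohort[[fam]] >= 1L
  out
}
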