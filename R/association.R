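#' Two-by-two association statistics
#'
#' `chisq_association()` runs the Pearson chi-squared test (1 df, no
#' continuity correction by default) on a 2x2 contingency table;
#' `phi_correlation()` computes the phi coefficient, which equals the
#' Pearson correlation of the two expanded 0/1 indicator vectors and is
#' computed in closed form as (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)).
#'
#' A table with a zero margin carries no information about association;
#' both functions then return `NA` markers rather than raising.
#'
#' @param tab A 2x2 matrix of counts, or a length-4 vector `c(a, b, c, d)`
#'   filled row-wise (rows = indicator 1/0, columns = outcome 1/0).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return For `chisq_association()`, a one-row tibble with `statistic`,
#'   `p_value`, `df`; for `phi_correlation()`, a number in \[-1, 1\] or `NA`.
#' @export
chisq_association <- function(tab, correct = FALSE) {
  m <- as_two_by_two(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_, df = NA_integer_))
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = unname(res$p.value),
                 df = as.integer(res$parameter))
}

#' @rdname chisq_association
#' @export
phi_correlation <- function(tab) {
  m <- as_two_by_two(tab)
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(NA_real_)
  (a * d - b * c) / sqrt(denom)
}

as_two_by_two <- function(tab) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == c(2, 2)))
    m <- tab
    storage.mode(m) <- "double"  # products of counts overflow integers
  } else {
    stopifnot(length(tab) == 4)
    m <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  }
  if (any(m < 0) || sum(m) == 0) {
    abort("2x2 table needs non-negative counts and a positive total",
          class = "pgtrait_validation_error")
  }
  m
}

#' Contingency tables from a cohort
#'
#' `family_domain_table()` cross-tabulates presence of one family against
#' membership in one domain (the per-family domain-association screen).
#' `absence_pg_table()` cross-tabulates absence of one family against
#' absence of PG over known-status records (the marker-association screen);
#' unknown-status genomes are excluded.
#'
#' @param cohort A cohort tibble.
#' @param family One of [pg_families()].
#' @param domain Domain whose membership is the outcome.
#' @return A 2x2 integer matrix (rows: indicator yes/no; columns: outcome
#'   yes/no).
#' @export
family_domain_table <- function(cohort, family, domain = "Bacteria") {
  cohort <- as_cohort(cohort)
  stopifnot(family %in% pg_families(), domain %in% pg_domains())
  pres <- cohort[[family]] >= 1L
  in_dom <- cohort$domain == domain
  matrix(c(sum(pres & in_dom), sum(pres & !in_dom),
           sum(!pres & in_dom), sum(!pres & !in_dom)),
         2, 2, byrow = TRUE,
         dimnames = list(presence = c("yes", "no"), domain = c("yes", "no")))
}

#' @rdname family_domain_table
#' @export
absence_pg_table <- function(cohort, family) {
  cohort <- as_cohort(cohort)
  stopifnot(family %in% pg_families())
  known <- cohort$pg_status != "unknown"
  fam_absent <- cohort[[family]][known] == 0L
  pg_absent <- cohort$pg_status[known] == "absent"
  matrix(c(sum(fam_absent & pg_absent), sum(fam_absent & !pg_absent),
           sum(!fam_absent & pg_absent), sum(!fam_absent & !pg_absent)),
         2, 2, byrow = TRUE,
         dimnames = list(family_absent = c("yes", "no"),
                         pg_absent = c("yes", "no")))
}

#' PCA of absence indicators
#'
#' Principal component analysis of the 0/1 absence indicators of the eight
#' families plus PG, over known-status genomes, to display collinearity
#' between gene absence and PG absence as a factor-loading plot.  The
#' indicator matrix is centered; scaling to unit variance is optional
#' (absence indicators share a scale already, so the default leaves
#' variances intact).  Constant columns are dropped with a warning.
#'
#' @param cohort A cohort tibble.
#' @param scale. Scale indicators to unit variance before PCA.
#' @return A `pg_pca` object; `tidy()` returns long-format loadings and
#'   `autoplot()` draws the loading plot.
#' @export
absence_pca <- function(cohort, scale. = FALSE) {
  cohort <- as_cohort(cohort)
  known <- cohort$pg_status != "unknown"
  if (sum(known) < 3) {
    abort("absence_pca needs at least 3 known-status records",
          class = "pgtrait_validation_error")
  }
  sub <- cohort[known, ]
  ind <- sapply(pg_families(), function(f) as.numeric(sub[[f]] == 0L))
  ind <- cbind(ind, PG = as.numeric(sub$pg_status == "absent"))
  keep <- apply(ind, 2, function(v) stats::var(v) > 0)
  if (any(!keep)) {
    warn(paste0("Dropping constant absence column(s): ",
                paste(colnames(ind)[!keep], collapse = ", ")))
  }
  ind <- ind[, keep, drop = FALSE]
  if (ncol(ind) < 2) {
    abort("Fewer than 2 varying absence columns; PCA is undefined",
          class = "pgtrait_validation_error")
  }
  fit <- stats::prcomp(ind, center = TRUE, scale. = scale.)
  structure(list(prcomp = fit, variables = colnames(ind), n = nrow(ind)),
            class = "pg_pca")
}

#' @export
print.pg_pca <- function(x, ...) {
  cat("<pg_pca> absence-indicator PCA over", x$n, "known-status genomes;",
      length(x$variables), "variables\n")
  print(utils::head(tidy(x), 4))
  invisible(x)
}

#' @export
tidy.pg_pca <- function(x, ...) {
  rot <- x$prcomp$rotation
  tibble::tibble(
    variable = rep(rownames(rot), ncol(rot)),
    component = rep(colnames(rot), each = nrow(rot)),
    loading = as.vector(rot)
  )
}

#' @export
glance.pg_pca <- function(x, ...) {
  v <- x$prcomp$sdev^2
  tibble::tibble(n = x$n, n_components = length(v),
                 prop_var_pc1 = v[1] / sum(v),
                 prop_var_pc2 = if (length(v) > 1) v[2] / sum(v) else NA_real_)
}

#' @export
autoplot.pg_pca <- function(object, ...) {
  rot <- object$prcomp$rotation
  df <- tibble::tibble(variable = rownames(rot),
                       PC1 = rot[, 1],
                       PC2 = if (ncol(rot) > 1) rot[, 2] else 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   label = .data$variable)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = 0), linewidth = 0.2) +
    ggplot2::geom_text(size = 3, vjust = -0.6) +
    ggplot2::geom_point() +
    ggplot2::labs(title = "Absence-indicator factor loadings",
                  x = "Component 1", y = "Component 2") +
    ggplot2::theme_minimal()
}

#' Logistic regression of PG absence on genome covariates
#'
#' Binary logistic regression with PG absence as the outcome and three
#' binarized predictors: low GC content (below `gc_cutoff` percent), small
#' genome (below `size_cutoff` Mb) and an obligate intracellular lifestyle.
#' Fits either the joint (multivariable) model or one model per predictor.
#' Goodness of fit uses a Hosmer-Lemeshow test on deciles of fitted risk.
#' Complete separation is reported (infinite odds-ratio marker and a
#' `separation` flag), never raised as an error.
#'
#' @param cohort A cohort tibble with `pg_status`, `gc_percent`,
#'   `genome_size_mb` and `lifestyle` filled in for the analysed rows.
#' @param mode `"multivariable"` (all predictors jointly) or
#'   `"univariate"` (one model per predictor).
#' @param gc_cutoff,size_cutoff Binarization cut-offs for GC percent and
#'   genome size in Mb.
#' @return A `pg_logistic` object; `tidy()` gives per-predictor odds
#'   ratios with Wald 95% CIs and p-values, `glance()` gives fit-level
#'   summaries including the Hosmer-Lemeshow p-value.
#' @export
pg_absence_regression <- function(cohort,
                                  mode = c("multivariable", "univariate"),
                                  gc_cutoff = 50, size_cutoff = 1.5) {
  mode <- match.arg(mode)
  cohort <- as_cohort(cohort)
  needed <- c("lifestyle", "gc_percent", "genome_size_mb")
  missing_cov <- setdiff(needed, names(cohort))
  if (length(missing_cov) > 0) {
    abort(paste0("Regression needs covariate column(s): ",
                 paste(missing_cov, collapse = ", ")),
          class = "pgtrait_schema_error")
  }
  dat <- cohort |>
    dplyr::filter(.data$pg_status != "unknown",
                  !is.na(.data$gc_percent), !is.na(.data$genome_size_mb),
                  !is.na(.data$lifestyle)) |>
    dplyr::transmute(
      pg_absent = as.numeric(.data$pg_status == "absent"),
      low_gc = as.numeric(.data$gc_percent < gc_cutoff),
      small_genome = as.numeric(.data$genome_size_mb < size_cutoff),
      obligate_intracellular =
        as.numeric(.data$lifestyle == "obligate_intracellular")
    )
  if (nrow(dat) < 10) {
    abort("Too few complete known-status records for regression",
          class = "pgtrait_validation_error")
  }
  predictors <- c("low_gc", "small_genome", "obligate_intracellular")
  fit_one <- function(terms) {
    f <- stats::as.formula(paste("pg_absent ~", paste(terms, collapse = " + ")))
    suppressWarnings(stats::glm(f, data = dat, family = stats::binomial()))
  }
  fits <- if (mode == "multivariable") {
    list(joint = fit_one(predictors))
  } else {
    stats::setNames(lapply(predictors, fit_one), predictors)
  }
  structure(list(fits = fits, data = dat, mode = mode,
                 cutoffs = c(gc = gc_cutoff, size = size_cutoff)),
            class = "pg_logistic")
}

# Wald summaries with an explicit infinite-OR marker under separation.
logistic_terms <- function(fit) {
  s <- summary(fit)$coefficients
  terms <- rownames(s)[-1]
  est <- s[-1, "Estimate"]
  se <- s[-1, "Std. Error"]
  p <- s[-1, "Pr(>|z|)"]
  separated <- abs(est) > 15 | se > 100
  tibble::tibble(
    term = terms,
    odds_ratio = ifelse(separated, sign(est) * Inf, exp(est)),
    conf_low = ifelse(separated, NA_real_, exp(est - 1.96 * se)),
    conf_high = ifelse(separated, NA_real_, exp(est + 1.96 * se)),
    p_value = ifelse(separated, NA_real_, p),
    separation = separated
  )
}

#' @export
tidy.pg_logistic <- function(x, ...) {
  purrr::imap(x$fits, function(fit, nm) {
    dplyr::mutate(logistic_terms(fit), model = nm, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' @export
glance.pg_logistic <- function(x, ...) {
  purrr::imap(x$fits, function(fit, nm) {
    hl <- hosmer_lemeshow(fit)
    tibble::tibble(model = nm, n = stats::nobs(fit),
                   loglik = as.numeric(stats::logLik(fit)),
                   aic = stats::AIC(fit),
                   hosmer_lemeshow_stat = hl$statistic,
                   hosmer_lemeshow_p = hl$p_value)
  }) |>
    dplyr::bind_rows()
}

#' @export
print.pg_logistic <- function(x, ...) {
  cat("<pg_logistic>", x$mode, "logistic regression of PG absence,",
      nrow(x$data), "genomes\n")
  print(tidy(x))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into `g` bins of fitted risk and compares observed
#' and expected event counts; the statistic is referred to a chi-squared
#' distribution with g - 2 degrees of freedom.  With heavily tied fitted
#' values (binary predictors) fewer than `g` distinct bins may form; the
#' degrees of freedom follow the realized number of bins.
#'
#' @param fit A binomial `glm`.
#' @param g Target number of risk groups (default 10).
#' @return A list with `statistic`, `df`, `p_value`, `n_groups`.
#' @export
hosmer_lemeshow <- function(fit, g = 10) {
  y <- fit$y
  p <- stats::fitted(fit)
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1)))
  if (length(breaks) < 3) {
    # fewer than two distinct risk groups: the test is degenerate
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                n_groups = length(breaks) - 1L))
  }
  grp <- cut(p, breaks = breaks, include.lowest = TRUE)
  obs <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  exp_g <- tapply(p, grp, sum)
  keep <- !is.na(n_g) & n_g > 0
  obs <- obs[keep]; n_g <- n_g[keep]; exp_g <- exp_g[keep]
  pbar <- exp_g / n_g
  denom <- n_g * pbar * (1 - pbar)
  ok <- denom > 0
  stat <- sum((obs[ok] - exp_g[ok])^2 / denom[ok])
  df <- max(1L, sum(ok) - 2L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       n_groups = sum(keep))
}
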