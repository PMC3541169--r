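test_that("chi-squared association reproduces published bounds and edge cases", {
  # GH23 presence vs domain membership, from the per-phylum survey counts
  res <- chisq_association(c(1224, 174, 5, 241))
  expect_lt(res$p_value, 1e-7)
  # perfectly independent table
  flat <- chisq_association(c(10, 10, 10, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # photosynthetic vs non-photosynthetic eukaryotes carrying set genes
  euk <- chisq_association(c(5, 2, 3, 32))
  expect_lte(euk$p_value, 0.001)
  # zero margin: undefined marker, no error
  degenerate <- chisq_association(c(0, 0, 3, 5))
  expect_true(is.na(degenerate$statistic))
})

test_that("chi-squared is symmetric under transposition and swaps", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(rpois(4, 20) + 1, 2, 2)
    base <- chisq_association(m)$statistic
    expect_equal(chisq_association(t(m))$statistic, base)
    expect_equal(chisq_association(m[2:1, ])$statistic, base)
    expect_equal(chisq_association(m[, 2:1])$statistic, base)
  }
})

test_that("phi equals brute-force Pearson on expanded indicator vectors", {
  expand_pearson <- function(a, b, c, d) {
    x <- c(rep(1, a + b), rep(0, c + d))
    y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
    stats::cor(x, y)
  }
  set.seed(7)
  for (i in 1:50) {
    counts <- rmultinom(1, size = sample(20:400, 1), prob = runif(4, 0.05, 1))
    a <- counts[1]; b <- counts[2]; c <- counts[3]; d <- counts[4]
    phi <- phi_correlation(c(a, b, c, d))
    if ((a + b) * (c + d) * (a + c) * (b + d) == 0) {
      expect_true(is.na(phi))
    } else {
      expect_equal(phi, expand_pearson(a, b, c, d), tolerance = 1e-12)
    }
  }
  # published GT51/PG absence table
  expect_equal(phi_correlation(c(84, 5, 0, 1279)),
               expand_pearson(84, 5, 0, 1279), tolerance = 1e-12)
  expect_equal(round(phi_correlation(c(84, 5, 0, 1279)), 4), 0.9696)
  # identical indicators
  expect_equal(phi_correlation(c(6, 0, 0, 9)), 1.0)
})

test_that("absence PCA returns orthonormal loadings and flags collinearity", {
  # cohort where GT51 absence coincides exactly with PG absence and every
  # other family's absence is independent noise of comparable variance:
  # the coupled pair should dominate the first component
  set.seed(3)
  n <- 300
  absent <- runif(n) < 0.4
  df <- tibble::tibble(
    genome_id = sprintf("g%03d", seq_len(n)),
    domain = "Bacteria", phylum = "Mixed",
    GT28 = rbinom(n, 1, 0.5), GT51 = as.integer(!absent),
    GH23 = rbinom(n, 1, 0.5), GH25 = rbinom(n, 1, 0.5),
    GH73 = rbinom(n, 1, 0.5), GH102 = rbinom(n, 1, 0.5),
    GH103 = rbinom(n, 1, 0.5), GH104 = rbinom(n, 1, 0.5),
    pg_status = ifelse(absent, "absent", "present")
  )
  pca <- absence_pca(as_cohort(df))
  rot <- pca$prcomp$rotation
  expect_equal(t(rot) %*% rot, diag(ncol(rot)), tolerance = 1e-10,
               ignore_attr = TRUE)
  ld <- tidy(pca)
  pc1 <- ld[ld$component == "PC1", ]
  coupled <- abs(pc1$loading[pc1$variable %in% c("GT51", "PG")])
  others <- abs(pc1$loading[!pc1$variable %in% c("GT51", "PG")])
  expect_gt(min(coupled), max(others))
  # perfectly correlated columns load identically up to sign
  expect_equal(coupled[1], coupled[2], tolerance = 1e-8)
})

test_that("constant absence columns are dropped with a warning", {
  cohort <- generate_cohort(n_bacteria = 200, seed = 5)
  cohort$GH104 <- 1L  # never absent
  expect_warning(pca <- absence_pca(cohort), "GH104")
  expect_false("GH104" %in% pca$variables)
})

test_that("logistic regression recovers known odds ratios", {
  hits <- 0
  n_rep <- 40
  for (seed in seq_len(n_rep)) {
    cohort <- simulate_covariate_cohort(n = 2000, odds_ratios = c(5, 5, 5),
                                        seed = 1000 + seed)
    fit <- pg_absence_regression(cohort)
    td <- tidy(fit)
    row <- td[td$term == "low_gc", ]
    if (!row$separation && row$conf_low <= 5 && 5 <= row$conf_high) {
      hits <- hits + 1
    }
  }
  # Wald 95% interval should cover the truth in about 95% of replicates
  expect_gte(hits / n_rep, 0.85)
})

test_that("a predictor unrelated to the outcome gets an odds ratio near one", {
  cohort <- simulate_covariate_cohort(n = 4000, odds_ratios = c(1, 8, 8),
                                      seed = 77)
  td <- tidy(pg_absence_regression(cohort))
  row <- td[td$term == "low_gc", ]
  expect_true(row$conf_low <= 1 && 1 <= row$conf_high)
  expect_lt(abs(log(row$odds_ratio)), 0.5)
})

test_that("permuting the outcome calibrates regression type-I error", {
  cohort <- simulate_covariate_cohort(n = 400, odds_ratios = c(4, 4, 4),
                                      seed = 9)
  base <- cohort
  n_perm <- 200
  pvals <- numeric(0)
  set.seed(123)
  for (i in seq_len(n_perm)) {
    perm <- base
    perm$pg_status <- sample(perm$pg_status)
    td <- tryCatch(tidy(pg_absence_regression(perm)), error = function(e) NULL)
    if (!is.null(td)) pvals <- c(pvals, td$p_value[!td$separation])
  }
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("univariate mode fits one model per predictor", {
  cohort <- simulate_covariate_cohort(n = 1500, seed = 21)
  fit <- pg_absence_regression(cohort, mode = "univariate")
  expect_equal(nrow(tidy(fit)), 3)
  expect_setequal(unique(tidy(fit)$model),
                  c("low_gc", "small_genome", "obligate_intracellular"))
  g <- glance(fit)
  expect_equal(nrow(g), 3)
  expect_true(all(is.finite(g$hosmer_lemeshow_stat) |
                    is.na(g$hosmer_lemeshow_stat)))
})

test_that("complete separation is flagged, not raised", {
  cohort <- simulate_covariate_cohort(n = 300, seed = 31)
  cohort$pg_status <- ifelse(cohort$gc_percent < 50, "absent", "present")
  td <- tidy(pg_absence_regression(cohort))
  row <- td[td$term == "low_gc", ]
  expect_true(row$separation)
  expect_true(is.infinite(row$odds_ratio))
})
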