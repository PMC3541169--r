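#' Two-state Markov rate models for correlated evolution
#'
#' The correlated-evolution test compares two continuous-time Markov models
#' of a pair of binary characters evolving along a tree.  Under the
#' independent model each character has its own gain rate (0 to 1) and loss
#' rate (1 to 0), four parameters in all; under the dependent model the
#' rate of change of each character may depend on the current state of the
#' other, giving eight parameters over the joint states \{00, 01, 10, 11\}.
#' Simultaneous changes of both characters have rate zero in both models.
#'
#' Joint states are ordered `00, 01, 10, 11` with the first digit for
#' character A, the second for character B.
#'
#' @param kind `"independent"` or `"dependent"`.
#' @param rates Non-negative rates.  Independent: named or positional
#'   `c(a01, a10, b01, b10)`.  Dependent: `c(r00_10, r00_01, r01_11,
#'   r01_00, r10_00, r10_11, r11_01, r11_10)`, each `rXY_ZW` the rate of
#'   the joint transition XY to ZW.
#' @return A `rate_model` object.
#' @export
rate_model <- function(kind = c("independent", "dependent"), rates) {
  kind <- match.arg(kind)
  n_expected <- if (kind == "independent") 4L else 8L
  rates <- as.numeric(rates)
  if (length(rates) != n_expected) {
    abort(paste0(kind, " model needs ", n_expected, " rates"),
          class = "pgtrait_config_error")
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort("Rates must be finite and non-negative",
          class = "pgtrait_validation_error")
  }
  names(rates) <- rate_names(kind)
  structure(list(kind = kind, rates = rates), class = "rate_model")
}

rate_names <- function(kind) {
  if (kind == "independent") c("a01", "a10", "b01", "b10")
  else c("r00_10", "r00_01", "r01_11", "r01_00",
         "r10_00", "r10_11", "r11_01", "r11_10")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model>", x$kind, "\n")
  print(round(x$rates, 6))
  invisible(x)
}

#' Generator matrix of a rate model over the joint states
#'
#' @param model A [rate_model()].
#' @return A 4x4 matrix with rows summing to zero, states ordered
#'   `00, 01, 10, 11`.
#' @export
build_generator <- function(model) {
  stopifnot(inherits(model, "rate_model"))
  r <- model$rates
  if (model$kind == "independent") {
    r <- c(r00_10 = unname(r["a01"]), r00_01 = unname(r["b01"]),
           r01_11 = unname(r["a01"]), r01_00 = unname(r["b10"]),
           r10_00 = unname(r["a10"]), r10_11 = unname(r["b01"]),
           r11_01 = unname(r["a10"]), r11_10 = unname(r["b10"]))
  }
  Q <- matrix(0, 4, 4, dimnames = list(joint_states(), joint_states()))
  Q["00", "10"] <- r[["r00_10"]]; Q["00", "01"] <- r[["r00_01"]]
  Q["01", "11"] <- r[["r01_11"]]; Q["01", "00"] <- r[["r01_00"]]
  Q["10", "00"] <- r[["r10_00"]]; Q["10", "11"] <- r[["r10_11"]]
  Q["11", "01"] <- r[["r11_01"]]; Q["11", "10"] <- r[["r11_10"]]
  diag(Q) <- -rowSums(Q)
  Q
}

joint_states <- function() c("00", "01", "10", "11")

# Precompute the per-tree quantities a likelihood evaluation needs.
pruning_context <- function(tree, unit_length_fallback = TRUE) {
  tree <- validate_phylogeny(tree)
  if (is.null(tree$edge.length)) {
    if (!unit_length_fallback) {
      abort("Tree has no branch lengths", class = "pgtrait_validation_error")
    }
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  post <- ape::reorder.phylo(tree, "postorder")
  list(tree = tree, edge = post$edge, edge_length = post$edge.length,
       n_tip = length(tree$tip.label), root = length(tree$tip.label) + 1L)
}

# Tip partial likelihoods over the four joint states; NA components are
# summed over (ambiguity), matching standard pruning practice.
joint_tip_likelihoods <- function(ctx, trait_a, trait_b) {
  tips <- ctx$tree$tip.label
  for (nm in c("trait_a", "trait_b")) {
    v <- get(nm)
    if (is.null(names(v))) {
      abort(paste0(nm, " must be named by tip label"),
            class = "pgtrait_validation_error")
    }
    miss <- setdiff(tips, names(v))
    if (length(miss) > 0) {
      abort(paste0("No ", nm, " state for tip(s): ",
                   paste(miss, collapse = ", ")),
            class = "pgtrait_validation_error")
    }
  }
  a <- as.integer(trait_a[tips])
  b <- as.integer(trait_b[tips])
  if (any(!(a %in% c(0L, 1L, NA)), !(b %in% c(0L, 1L, NA)))) {
    abort("Trait states must be 0/1 (NA allowed for a missing component)",
          class = "pgtrait_validation_error")
  }
  L <- matrix(0, length(tips), 4, dimnames = list(tips, joint_states()))
  for (i in seq_along(tips)) {
    ok_a <- if (is.na(a[i])) c(TRUE, TRUE) else c(a[i] == 0L, a[i] == 1L)
    ok_b <- if (is.na(b[i])) c(TRUE, TRUE) else c(b[i] == 0L, b[i] == 1L)
    # columns 00,01,10,11: A is the first digit, B the second
    L[i, ] <- as.numeric(c(ok_a[1] & ok_b[1], ok_a[1] & ok_b[2],
                           ok_a[2] & ok_b[1], ok_a[2] & ok_b[2]))
  }
  L
}

#' Pruning log-likelihood of two binary characters under a rate model
#'
#' Felsenstein pruning over the rooted tree with per-branch transition
#' probabilities `expm(Q t)` and a uniform root prior over the four joint
#' states.  Trees without branch lengths are given unit lengths (the
#' comparative analysis consumes cladogram-like trees).
#'
#' @param tree A rooted [ape::phylo].
#' @param trait_a,trait_b Named 0/1 vectors over the tips (NA = missing
#'   component, summed over).
#' @param model A [rate_model()].
#' @return The log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, trait_a, trait_b, model) {
  ctx <- pruning_context(tree)
  L <- joint_tip_likelihoods(ctx, trait_a, trait_b)
  Q <- build_generator(model)
  mk_loglik_cpp(ctx$edge, ctx$edge_length, L, Q, rep(0.25, 4),
                ctx$n_tip, ctx$root)
}

# Single-character 2-state pruning likelihood (used by the factorized
# independent-model fit: under independence the joint likelihood is the
# product of the two marginal likelihoods with uniform root priors).
binary_loglik <- function(ctx, states01, q01, q10) {
  binary_loglik2_cpp(ctx$edge, ctx$edge_length, as.integer(states01),
                     q01, q10, ctx$n_tip, ctx$root)
}

# Dependent-model generator without the construction overhead of
# rate_model()/build_generator(); rate order as in rate_names("dependent").
dep_generator <- function(r) {
  Q <- matrix(0, 4, 4)
  Q[1, 3] <- r[1]; Q[1, 2] <- r[2]
  Q[2, 4] <- r[3]; Q[2, 1] <- r[4]
  Q[3, 1] <- r[5]; Q[3, 4] <- r[6]
  Q[4, 2] <- r[7]; Q[4, 3] <- r[8]
  diag(Q) <- -rowSums(Q)
  Q
}

# Multi-start Nelder-Mead over log-rates with soft box bounds.  `starts`
# is a list of log-rate vectors; the caller supplies a data-informed first
# start plus seeded perturbations.
optimize_rates <- function(neg_loglik, starts) {
  lb <- log(1e-6); ub <- log(1e3)
  penalized <- function(lr) {
    if (any(lr < lb) || any(lr > ub)) {
      return(1e8 + sum(pmax(lb - lr, 0) + pmax(lr - ub, 0)))
    }
    neg_loglik(exp(lr))
  }
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, penalized, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-7))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish: Nelder-Mead restarted from its own optimum regains a full-size
  # simplex and escapes premature contraction
  for (round in 1:4) {
    polish <- stats::optim(best$par, penalized, method = "Nelder-Mead",
                           control = list(maxit = 500, reltol = 1e-8))
    improved <- best$value - polish$value
    if (polish$value < best$value) best <- polish
    if (improved < 1e-5) break
  }
  list(rates = exp(best$par), loglik = -best$value)
}

seeded_starts <- function(center, n_starts, sd = 1.0) {
  lapply(seq_len(n_starts), function(i) {
    if (i == 1) center else stats::rnorm(length(center), mean = center, sd = sd)
  })
}

# Crude per-character rate scale: parsimony-style change count over total
# tree length, floored away from zero.
initial_rate <- function(ctx, states01) {
  changes <- max(1, sum(abs(diff(states01[order(states01)])) > 0))
  total_len <- sum(ctx$edge_length)
  max(0.05, min(10, changes / max(total_len, 1e-6)))
}

#' Maximum-likelihood fit of the independent or dependent model
#'
#' Rates are fitted by multi-start Nelder-Mead over log-rates bounded in
#' \[1e-6, 1e3\]; the first start uses a data-driven rate scale, the rest
#' are seeded perturbations, so refitting under the same seed reproduces
#' the same rates.  The independent model factorizes into two 2-state fits,
#' which is both faster and more robust than a joint 4-parameter search.
#'
#' @inheritParams mk_loglik
#' @param kind `"independent"` or `"dependent"`.
#' @param n_starts Number of optimizer starts (at least 1; default 5).
#' @param seed Integer seed for the start perturbations.
#' @return A list: `model` (fitted [rate_model()]), `loglik`.
#' @export
fit_rate_model <- function(tree, trait_a, trait_b,
                           kind = c("independent", "dependent"),
                           n_starts = 5, seed = 1L) {
  kind <- match.arg(kind)
  ctx <- pruning_context(tree)
  a <- as.integer(trait_a[ctx$tree$tip.label])
  b <- as.integer(trait_b[ctx$tree$tip.label])
  if (anyNA(a) || anyNA(b)) {
    # fall back to the joint machinery which understands ambiguity
    return(fit_joint(ctx, trait_a, trait_b, kind, n_starts, seed))
  }
  for (v in list(a = a, b = b)) {
    if (length(unique(v)) < 2) {
      abort("Both characters must vary across the tips; the test is undefined otherwise",
            class = "pgtrait_validation_error")
    }
  }
  if (ctx$n_tip < 4) {
    abort("Need at least 4 tips", class = "pgtrait_validation_error")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  fit_marginal <- function(v) {
    optimize_rates(function(r) -binary_loglik(ctx, v, r[1], r[2]),
                   seeded_starts(rep(log(initial_rate(ctx, v)), 2), n_starts))
  }
  fit_a <- fit_marginal(a)
  fit_b <- fit_marginal(b)
  if (kind == "independent") {
    model <- rate_model("independent",
                        c(fit_a$rates[1], fit_a$rates[2],
                          fit_b$rates[1], fit_b$rates[2]))
    list(model = model, loglik = fit_a$loglik + fit_b$loglik)
  } else {
    L <- joint_tip_likelihoods(ctx, trait_a, trait_b)
    nll <- function(r) {
      -mk_loglik4_cpp(ctx$edge, ctx$edge_length, L, dep_generator(r),
                      ctx$n_tip, ctx$root)
    }
    # start at the independent optimum mapped into the dependent space:
    # for null-like data the search then begins near its optimum
    center <- log(pmax(c(fit_a$rates[1], fit_b$rates[1], fit_a$rates[1],
                         fit_b$rates[2], fit_a$rates[2], fit_b$rates[1],
                         fit_a$rates[2], fit_b$rates[2]), 1e-5))
    fit <- optimize_rates(nll, seeded_starts(center, n_starts))
    list(model = rate_model("dependent", fit$rates), loglik = fit$loglik)
  }
}

# Joint-likelihood fit used when a character has missing components.
fit_joint <- function(ctx, trait_a, trait_b, kind, n_starts, seed) {
  L <- joint_tip_likelihoods(ctx, trait_a, trait_b)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  n_par <- if (kind == "independent") 4L else 8L
  nll <- function(r) {
    Q <- build_generator(rate_model(kind, r))
    -mk_loglik_cpp(ctx$edge, ctx$edge_length, L, Q, rep(0.25, 4),
                   ctx$n_tip, ctx$root)
  }
  fit <- optimize_rates(nll, seeded_starts(rep(log(0.5), n_par), n_starts))
  list(model = rate_model(kind, fit$rates), loglik = fit$loglik)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Correlated-evolution test for two binary characters
#'
#' Likelihood-ratio comparison of the dependent (8-rate) against the
#' independent (4-rate) model.  The score is the likelihood-ratio
#' statistic `2 (lnL_dep - lnL_indep)`, clamped at zero (the models are
#' nested, so a negative difference can only be optimizer noise).  The
#' error percentage is a Monte-Carlo p-value times 100: characters are
#' re-simulated `n_sim` times under the fitted independent model on the
#' same tree (parametric bootstrap), each replicate is refitted under both
#' models, and `error = 100 (1 + #\{sim score >= observed\}) / (n_sim + 1)`
#' -- never exactly zero, with resolution `100 / (n_sim + 1)`.
#'
#' @inheritParams fit_rate_model
#' @param n_sim Number of bootstrap simulations (at least 19).
#' @param seed Integer seed governing optimizer starts and simulations.
#' @return A `pagel_fit` with both fitted models, log-likelihoods, score,
#'   error percentage and bootstrap scores.
#' @export
pagel_test <- function(tree, trait_a, trait_b, n_sim = 99, seed = 1L,
                       n_starts = 5) {
  if (n_sim < 19) {
    abort("n_sim must be at least 19 (error-percentage resolution)",
          class = "pgtrait_config_error")
  }
  ctx <- pruning_context(tree)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  score_of <- function(ta, tb) {
    ind <- fit_rate_model(ctx$tree, ta, tb, "independent",
                          n_starts = n_starts,
                          seed = stats::runif(1, 1, 2^30))
    dep <- fit_rate_model(ctx$tree, ta, tb, "dependent",
                          n_starts = n_starts,
                          seed = stats::runif(1, 1, 2^30))
    list(ind = ind, dep = dep,
         score = max(0, 2 * (dep$loglik - ind$loglik)))
  }

  obs <- score_of(trait_a, trait_b)

  sim_scores <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    repeat {
      sim <- simulate_characters(ctx$tree, obs$ind$model)
      sa <- sim$tip_states$trait_a
      sb <- sim$tip_states$trait_b
      if (length(unique(sa)) > 1 && length(unique(sb)) > 1) break
    }
    names(sa) <- names(sb) <- sim$tip_states$tip
    sim_scores[i] <- score_of(sa, sb)$score
  }
  error_percentage <- 100 * (1 + sum(sim_scores >= obs$score)) / (n_sim + 1)

  structure(list(
    loglik_independent = obs$ind$loglik,
    loglik_dependent = obs$dep$loglik,
    model_independent = obs$ind$model,
    model_dependent = obs$dep$model,
    score = obs$score,
    error_percentage = error_percentage,
    sim_scores = sim_scores,
    n_sim = n_sim, seed = as.integer(seed),
    n_tips = ctx$n_tip
  ), class = "pagel_fit")
}

#' @export
print.pagel_fit <- function(x, ...) {
  cat("<pagel_fit>", x$n_tips, "tips; score",
      sprintf("%.3f", x$score), "; error",
      sprintf("%.1f%%", x$error_percentage),
      sprintf("(%d simulations)\n", x$n_sim))
  invisible(x)
}

#' @export
tidy.pagel_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(model = "independent",
                   rate = names(x$model_independent$rates),
                   estimate = unname(x$model_independent$rates)),
    tibble::tibble(model = "dependent",
                   rate = names(x$model_dependent$rates),
                   estimate = unname(x$model_dependent$rates))
  )
}

#' @export
glance.pagel_fit <- function(x, ...) {
  tibble::tibble(
    n_tips = x$n_tips,
    loglik_independent = x$loglik_independent,
    loglik_dependent = x$loglik_dependent,
    score = x$score,
    error_percentage = x$error_percentage,
    n_sim = x$n_sim,
    seed = x$seed
  )
}

#' @export
autoplot.pagel_fit <- function(object, ...) {
  df <- tibble::tibble(score = object$sim_scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = object$score, color = "red",
                        linewidth = 0.8) +
    ggplot2::labs(
      title = "Bootstrap null distribution of the correlation score",
      subtitle = sprintf("observed score %.2f, error %.1f%%",
                         object$score, object$error_percentage),
      x = "score (2 Δ lnL)", y = "simulations") +
    ggplot2::theme_minimal()
}
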