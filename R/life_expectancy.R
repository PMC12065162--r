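#' Integration grid for life-expectancy estimation
#'
#' @param age0 starting age in years.
#' @param h integration step in years (at most 1; default 0.5).
#' @param age_max integration horizon in years (default 115, beyond
#'   plausible survival, so truncated person-years are negligible).
#' @return object of class `le_grid`.
#' @export
le_grid <- function(age0 = 50, h = 0.5, age_max = 115) {
  if (!(age0 < age_max)) stop("age0 must be below age_max")
  if (h <= 0 || h > 1) stop("step h must be in (0, 1]")
  structure(list(age0 = age0, h = h, age_max = age_max), class = "le_grid")
}

#' State-specific life expectancies from a fitted model
#'
#' Computes `e[r, s]`, the expected future years spent in living state `s`
#' for a person in state `r` at `age0`, by deterministic product
#' integration of the transition-probability flow: the occupancy matrix
#' `P(age0, u)` is advanced as an ordered product of per-step matrix
#' exponentials with the age covariate refreshed at each step midpoint (the
#' other covariates held at `profile`), and occupancies are accumulated by
#' the trapezoidal rule up to `age_max`.
#'
#' @param object an `msm_fit` or `msm_params`.
#' @param profile a [covariate_profile()] fixing non-age covariates.
#' @param grid an [le_grid()].
#' @return 3x3 matrix of expected years, rows = starting state, columns =
#'   occupied state, with a `"survival"` attribute giving the residual
#'   survival probabilities at `age_max`. Warns when any residual survival
#'   exceeds 1e-3 (horizon too short).
#' @export
state_specific_les <- function(object, profile = covariate_profile(),
                               grid = le_grid()) {
  spec <- params_spec(object)
  theta <- params_theta(object)
  stopifnot(inherits(grid, "le_grid"))
  B <- coef_matrix(spec, theta)
  z0 <- profile_row(spec, profile, age = grid$age0)
  age_col <- if ("age" %in% spec$columns) match("age", spec$columns) - 1L else -1L
  res <- le_integrate_cpp(B, z0, age_col, grid$age0, grid$h, grid$age_max,
                          spec$age_offset, spec$transitions)
  e <- res$e
  dimnames(e) <- list(STATE_LABELS[1:3], STATE_LABELS[1:3])
  # only starting states that exist in the transition structure are
  # diagnosable: structurally absent states never exit and stay at
  # survival 1 by construction
  active <- sort(unique(spec$transitions[, 1]))
  if (any(res$surv[active] > 1e-3)) {
    warning(sprintf(
      "residual survival %.2e at age %.0f: horizon too short, expectancies truncated",
      max(res$surv[active]), grid$age_max))
  }
  attr(e, "survival") <- as.numeric(res$surv)
  e
}

#' Distribution over living states at a starting age
#'
#' Models the baseline (first-observation) state of each subject with a
#' multinomial logistic regression on age and evaluates it at `age0`; this
#' supplies the initial weights for marginal life expectancies. When the
#' regression is degenerate (fewer than two baseline states observed, or a
#' fitting failure), the overall empirical baseline proportions are used.
#'
#' @param panel a validated panel data frame.
#' @param age0 age (years) at which to evaluate the distribution.
#' @param method `"auto"` (multinomial logit with empirical fallback),
#'   `"multinom"` or `"empirical"`.
#' @return named probability vector over robust / prefrail / frail.
#' @export
initial_state_distribution <- function(panel, age0,
                                       method = c("auto", "multinom",
                                                  "empirical")) {
  method <- match.arg(method)
  panel <- panel[order(panel$subject_id, panel$age), , drop = FALSE]
  base <- panel[!duplicated(panel$subject_id), , drop = FALSE]
  base <- base[base$state %in% LIVING_STATES, , drop = FALSE]
  if (nrow(base) == 0) stop("no living baseline records in panel")
  emp <- tabulate(base$state, nbins = 3) / nrow(base)
  probs <- NULL
  if (method != "empirical" && length(unique(base$state)) >= 2) {
    fitm <- tryCatch({
      m <- nnet::multinom(factor(state, levels = LIVING_STATES) ~ age,
                          data = base, trace = FALSE)
      p <- predict(m, newdata = data.frame(age = age0), type = "probs")
      full <- setNames(numeric(3), as.character(LIVING_STATES))
      if (is.null(dim(p))) full[names(p)] <- p else full[colnames(p)] <- p[1, ]
      # multinom drops unobserved levels; re-insert as zero
      if (length(unique(base$state)) == 2) {
        lv <- as.character(sort(unique(base$state)))
        pr <- predict(m, newdata = data.frame(age = age0), type = "probs")
        full[] <- 0; full[lv[2]] <- pr; full[lv[1]] <- 1 - pr
      }
      full
    }, error = function(e) NULL)
    probs <- fitm
  }
  if (is.null(probs)) {
    if (method == "multinom") stop("multinomial baseline model is degenerate")
    probs <- emp
  }
  probs <- pmax(as.numeric(probs), 0)
  probs <- probs / sum(probs)
  setNames(probs, STATE_LABELS[1:3])
}

#' Marginal frailty-free, frail and total life expectancies
#'
#' Weights the state-specific expectancies by the initial state
#' distribution: marginal years in state `s` are `sum_r pi_r e[r, s]`.
#' Frailty-free life expectancy is the time in robust plus pre-frail;
#' frail life expectancy is the time in the frail state; these need not be
#' contiguous spells. Percentages are of total remaining life.
#'
#' @param e_rs 3x3 state-specific expectancy matrix from
#'   [state_specific_les()].
#' @param init_dist probability vector over the three living states.
#' @return object of class `le_result` with elements `e_rs`, `init_dist`,
#'   `by_state`, `frailty_free`, `frail`, `total`, `pct_frailty_free`,
#'   `pct_frail`.
#' @export
marginal_les <- function(e_rs, init_dist) {
  stopifnot(is.matrix(e_rs), all(dim(e_rs) == c(3, 3)))
  if (length(init_dist) != 3 || any(init_dist < 0)) {
    stop("init_dist must be 3 non-negative probabilities")
  }
  init_dist <- init_dist / sum(init_dist)
  by_state <- as.numeric(init_dist %*% e_rs)
  names(by_state) <- STATE_LABELS[1:3]
  ff <- by_state[["robust"]] + by_state[["prefrail"]]
  fr <- by_state[["frail"]]
  tot <- ff + fr
  out <- list(
    e_rs = e_rs, init_dist = init_dist, by_state = by_state,
    frailty_free = ff, frail = fr, total = tot,
    pct_frailty_free = 100 * ff / tot, pct_frail = 100 * fr / tot
  )
  class(out) <- "le_result"
  out
}

le_quantities <- c("frailty_free", "frail", "total",
                   "pct_frailty_free", "pct_frail")

#' @export
print.le_result <- function(x, ...) {
  fmt <- function(q) {
    v <- sprintf("%.1f", x[[q]])
    if (!is.null(x$ci) && q %in% names(x$ci)) {
      v <- sprintf("%s (%.1f-%.1f)", v, x$ci[[q]][1], x$ci[[q]][2])
    }
    v
  }
  cat("Life expectancies:\n")
  cat("  frailty-free:", fmt("frailty_free"), "years,",
      fmt("pct_frailty_free"), "%\n")
  cat("  frail:       ", fmt("frail"), "years,", fmt("pct_frail"), "%\n")
  cat("  total:       ", fmt("total"), "years\n")
  invisible(x)
}

# draw parameter vectors from the estimator's asymptotic normal law
draw_parameters <- function(fit, n_draws, seed = NULL) {
  if (is.null(fit$vcov)) stop("fit covariance unavailable; cannot bootstrap")
  Sigma <- (fit$vcov + t(fit$vcov)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    warning("covariance not positive semi-definite; using nearest PSD repair")
    Sigma <- as.matrix(Matrix::nearPD(Sigma)$mat)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  draws <- MASS::mvrnorm(n_draws, mu = fit$estimate, Sigma = Sigma,
                         tol = 1e-6)
  if (n_draws == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- names(fit$estimate)
  draws
}

#' Parametric-bootstrap life expectancies with percentile intervals
#'
#' Implements the standard uncertainty propagation for model-based life
#' expectancies: `n_draws` parameter vectors are drawn from the
#' multivariate normal centred at the maximum-likelihood estimate with the
#' estimated covariance, every life-expectancy quantity is recomputed for
#' each draw, and 2.5/97.5 percentile limits form the 95% intervals.
#' Results are deterministic given `seed`. The initial state distribution
#' is held fixed across draws (its sampling uncertainty is negligible next
#' to the intensity parameters in cohorts of this size).
#'
#' To contrast two covariate profiles with paired draws, call this function
#' for each profile with the same `fit` and `seed`: the parameter draws are
#' then identical and per-draw differences cancel shared parameter noise.
#'
#' @inheritParams state_specific_les
#' @param fit an `msm_fit` with available covariance.
#' @param init_dist probability vector over living states at `grid$age0`
#'   (see [initial_state_distribution()]).
#' @param n_draws number of parameter draws (default 1000).
#' @param seed integer seed for the draws.
#' @param level confidence level for the percentile intervals.
#' @param keep_draws keep the per-draw quantity matrix (needed for group
#'   contrasts).
#' @return an `le_result` (point estimates at the MLE) augmented with
#'   `ci` (named list of `c(lower, upper)`), `draws` (matrix n_draws x
#'   quantities), `n_draws`, `seed` and `boot_id` identifying the draw
#'   stream.
#' @export
bootstrap_les <- function(fit, profile = covariate_profile(),
                          grid = le_grid(), init_dist, n_draws = 1000,
                          seed = NULL, level = 0.95, keep_draws = TRUE) {
  stopifnot(inherits(fit, "msm_fit"))
  point <- marginal_les(state_specific_les(fit, profile, grid), init_dist)
  draws <- draw_parameters(fit, n_draws, seed)
  spec <- fit$spec
  z0 <- profile_row(spec, profile, age = grid$age0)
  age_col <- if ("age" %in% spec$columns) match("age", spec$columns) - 1L else -1L
  qn <- c(le_quantities, "years_robust", "years_prefrail", "years_frail")
  qmat <- matrix(NA_real_, nrow = n_draws, ncol = length(qn),
                 dimnames = list(NULL, qn))
  for (d in seq_len(n_draws)) {
    B <- coef_matrix(spec, setNames(draws[d, ], colnames(draws)))
    res <- le_integrate_cpp(B, z0, age_col, grid$age0, grid$h, grid$age_max,
                            spec$age_offset, spec$transitions)
    m <- marginal_les(structure(res$e, dimnames = dimnames(point$e_rs)),
                      init_dist)
    qmat[d, ] <- c(m$frailty_free, m$frail, m$total, m$pct_frailty_free,
                   m$pct_frail, m$by_state)
  }
  a <- (1 - level) / 2
  ci <- lapply(qn, function(q) unname(quantile(qmat[, q], c(a, 1 - a))))
  names(ci) <- qn
  point$ci <- ci
  point$level <- level
  point$n_draws <- n_draws
  point$seed <- seed
  point$boot_id <- paste(format(sum(fit$estimate), digits = 15),
                         fit$n_intervals, n_draws,
                         if (is.null(seed)) "noseed" else seed, sep = "/")
  if (keep_draws) point$draws <- qmat
  point
}

#' Microsimulation cross-check of model-based life expectancies
#'
#' Simulates individual trajectories under the fitted intensities
#' (piecewise-homogeneous over 1-year age bands with competing exponential
#' clocks) and averages the exact years spent in each living state. This is
#' a Monte-Carlo estimate of the same quantities that
#' [state_specific_les()] computes by deterministic integration; it exists
#' to cross-validate the integrator, not for production use.
#'
#' @inheritParams state_specific_les
#' @param start_state state occupied at `grid$age0`.
#' @param n number of simulated trajectories.
#' @param seed integer seed.
#' @return named vector of mean years in robust / prefrail / frail with a
#'   `"se"` attribute of Monte-Carlo standard errors.
#' @export
microsim_les <- function(object, profile = covariate_profile(),
                         grid = le_grid(), start_state = 1, n = 5000,
                         seed = NULL) {
  spec <- params_spec(object)
  theta <- params_theta(object)
  B <- coef_matrix(spec, theta)
  if (!is.null(seed)) set.seed(as.integer(seed))
  occ <- matrix(0, nrow = n, ncol = 3)
  for (i in seq_len(n)) {
    path <- sim_path(B, spec, profile_row(spec, profile, age = grid$age0),
                     grid$age0, grid$age_max, start_state)
    occ[i, ] <- path_occupancy(path, grid$age_max)
  }
  est <- colMeans(occ)
  names(est) <- STATE_LABELS[1:3]
  attr(est, "se") <- apply(occ, 2, function(x) sd(x) / sqrt(n))
  est
}

# simulate one latent path under coefficient matrix B from age0 to horizon;
# intensities fixed within 1-year bands at the band midpoint age.
# Returns data.frame(age, state) of jump records starting at (age0, state).
sim_path <- function(B, spec, z0, age0, horizon, state) {
  age_col <- if ("age" %in% spec$columns) match("age", spec$columns) else 0L
  trans <- spec$transitions
  x <- z0
  a <- age0
  ages <- a; states <- state
  while (a < horizon && state != STATE_DEAD) {
    band_end <- min(floor(a - age0) + 1 + age0, horizon)
    if (age_col > 0) x[age_col] <- (a + band_end) / 2 - spec$age_offset
    rows <- which(trans[, 1] == state)
    rates <- vapply(rows, function(i) exp(B[i, 1] + sum(B[i, -1] * x)),
                    numeric(1))
    tot <- sum(rates)
    if (tot <= 0) { a <- band_end; next }
    wait <- rexp(1, tot)
    if (a + wait >= band_end) { a <- band_end; next }
    a <- a + wait
    pick <- rows[sample.int(length(rows), 1, prob = rates / tot)]
    state <- trans[pick, 2]
    ages <- c(ages, a); states <- c(states, state)
  }
  data.frame(age = ages, state = states)
}

# exact occupancy years per living state of a jump path up to horizon
path_occupancy <- function(path, horizon) {
  occ <- numeric(3)
  k <- nrow(path)
  ends <- c(path$age[-1], max(horizon, path$age[k]))
  for (j in seq_len(k)) {
    s <- path$state[j]
    if (s %in% LIVING_STATES) occ[s] <- occ[s] + (ends[j] - path$age[j])
  }
  occ
}
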