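#' Log-likelihood of a multi-state model on panel data
#'
#' The likelihood is a product over consecutive observation pairs within
#' subjects (the Markov property makes intervals conditionally
#' independent). A living-to-living pair over `dt` years contributes
#' `P_rs(dt)`; a pair ending in an exactly observed death contributes
#' `sum_k P_rk(dt) q_k,dead`, marginalising the living state occupied
#' immediately before death; a dead record without an exact death time
#' contributes `1 - sum_k P_rk(dt)`. Intensities over an interval are held
#' at the interval's covariate values (piecewise-homogeneous
#' approximation).
#'
#' @param object an `msm_params` or `msm_fit`.
#' @param panel a validated panel data frame (see [validate_panel()]).
#' @param by `"total"`, `"subject"` or `"interval"` aggregation of the
#'   log-likelihood contributions.
#' @return a number, or a named vector of per-subject / per-interval
#'   contributions. A zero-probability observed pair yields `-Inf` with a
#'   warning identifying the pair.
#' @export
msm_loglik <- function(object, panel, by = c("total", "subject", "interval")) {
  by <- match.arg(by)
  spec <- params_spec(object)
  theta <- params_theta(object)
  iv <- panel_intervals(panel, spec)
  ll <- interval_loglik_cpp(coef_matrix(spec, theta), iv$X, iv$from, iv$to,
                            iv$dt, iv$is_death, spec$transitions,
                            iv$age_col, iv$death_shift)
  bad <- ll <= log(1e-299)
  if (any(bad)) {
    i <- which(bad)[1]
    warning(sprintf(
      "zero-probability observed pair (subject %s, %d -> %d over %.2f years)",
      iv$subject[i], iv$from[i], iv$to[i], iv$dt[i]))
    ll[bad] <- -Inf
  }
  switch(by,
    total = sum(ll),
    subject = vapply(split(ll, iv$subject), sum, numeric(1)),
    interval = ll
  )
}

# crude initial values: log((events + 0.5) / person-years at risk) per
# transition, covariate effects zero
crude_init <- function(spec, iv) {
  theta <- setNames(rep(0, length(param_names(spec))), param_names(spec))
  py <- vapply(LIVING_STATES, function(r) sum(iv$dt[iv$from == r]), numeric(1))
  for (i in seq_len(nrow(spec$transitions))) {
    r <- spec$transitions[i, 1]; s <- spec$transitions[i, 2]
    ev <- if (s == STATE_DEAD) sum(iv$from == r & iv$to == STATE_DEAD) else
      sum(iv$from == r & iv$to == s & iv$is_death == 0)
    theta[paste0("q", r, s)] <- log((ev + 0.5) / max(py[r], 1e-8))
  }
  theta
}

#' Fit the multi-state model by maximum likelihood
#'
#' Maximises the interval-censored panel likelihood by quasi-Newton (BFGS)
#' ascent on the unconstrained parameterisation (log baseline intensities
#' plus covariate log hazard ratios). The covariance of the estimator is
#' the inverse of the numerically differentiated observed information.
#'
#' @param panel a panel data frame; it is validated with [validate_panel()]
#'   first and exclusions are messaged.
#' @param spec an [msm_spec()].
#' @param init optional named starting values (defaults to log crude
#'   transition rates from observed counts and person-years, zero betas).
#' @param control passed to [stats::optim()]; defaults to
#'   `list(maxit = 500, reltol = 1e-8)`.
#' @param bic_n `"subjects"` (default) or `"observations"`: the sample size
#'   used in the BIC penalty.
#' @return an object of class `msm_fit`: `estimate` (named vector), `vcov`
#'   (or `NULL` if the information was singular), `loglik`, `bic`,
#'   `n_subjects`, `n_observations`, `n_intervals`, `converged`, `spec`.
#'   Non-convergence is flagged, not raised.
#' @export
fit_msm <- function(panel, spec, init = NULL, control = list(),
                    bic_n = c("subjects", "observations")) {
  bic_n <- match.arg(bic_n)
  val <- validate_panel(panel)
  if (nrow(val$excluded) > 0) {
    message("fit_msm: excluded ", nrow(val$excluded),
            " subject(s) lacking longitudinal data")
  }
  panel <- val$panel
  iv <- panel_intervals(panel, spec)

  # warn about allowed transitions never observed as interval endpoints
  for (i in seq_len(nrow(spec$transitions))) {
    r <- spec$transitions[i, 1]; s <- spec$transitions[i, 2]
    seen <- if (s == STATE_DEAD) any(iv$from == r & iv$to == STATE_DEAD) else
      any(iv$from == r & iv$to == s)
    if (!seen) warning("transition ", r, "->", s,
                       " never observed; its baseline is weakly identified")
  }

  nm <- param_names(spec)
  theta0 <- if (is.null(init)) crude_init(spec, iv) else {
    if (!all(nm %in% names(init))) stop("init must name all parameters")
    init[nm]
  }
  negll <- function(theta) {
    names(theta) <- nm
    -sum(interval_loglik_cpp(coef_matrix(spec, theta), iv$X, iv$from, iv$to,
                             iv$dt, iv$is_death, spec$transitions,
                             iv$age_col, iv$death_shift))
  }
  ctrl <- modifyList(list(maxit = 500, reltol = 1e-8), control)
  opt <- optim(theta0, negll, method = "BFGS", control = ctrl)
  est <- setNames(opt$par, nm)

  H <- tryCatch(optimHess(est, negll), error = function(e) NULL)
  vcov <- NULL
  if (!is.null(H) && all(is.finite(H))) {
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov) && any(diag(vcov) <= 0)) vcov <- NULL
  }
  if (is.null(vcov)) {
    message("fit_msm: observed information singular or indefinite; ",
            "covariance unavailable")
  } else {
    dimnames(vcov) <- list(nm, nm)
  }

  n_subj <- length(unique(panel$subject_id))
  n_obs <- nrow(panel)
  n_for_bic <- if (bic_n == "subjects") n_subj else n_obs
  loglik <- -opt$value
  out <- list(
    spec = spec, estimate = est, vcov = vcov, loglik = loglik,
    n_subjects = n_subj, n_observations = n_obs,
    n_intervals = length(iv$dt), n_params = length(nm),
    bic = -2 * loglik + length(nm) * log(n_for_bic),
    converged = opt$convergence == 0, optim = opt[c("counts", "convergence")],
    data_signature = c(n_subj, n_obs, round(sum(iv$dt), 6),
                       sum(iv$from * 7 + iv$to))
  )
  class(out) <- "msm_fit"
  out
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Four-state frailty multi-state model",
      if (!is.null(x$spec$stratum)) paste0("(", x$spec$stratum, ")"), "\n")
  cat(sprintf("  %d subjects, %d observations, %d intervals\n",
              x$n_subjects, x$n_observations, x$n_intervals))
  cat(sprintf("  log-likelihood %.2f, BIC %.2f, %d parameters, converged: %s\n",
              x$loglik, x$bic, x$n_params, x$converged))
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, x$n_params)
  print(round(data.frame(estimate = x$estimate, se = se), 4))
  invisible(x)
}

#' Hazard ratios with Wald confidence intervals
#'
#' Each covariate effect on a transition intensity exponentiates to a
#' hazard ratio; confidence limits are `exp(beta +/- z * SE)`.
#'
#' @param fit a converged [fit_msm()] result with available covariance.
#' @param level confidence level (default 0.95).
#' @return data frame: `transition`, `term`, `beta`, `se`, `hr`, `lower`,
#'   `upper`.
#' @export
hazard_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "msm_fit"))
  if (is.null(fit$vcov)) stop("covariance unavailable; cannot form intervals")
  nm <- names(fit$estimate)
  is_beta <- grepl(":", nm, fixed = TRUE)
  if (!any(is_beta)) {
    return(data.frame(transition = character(), term = character(),
                      beta = numeric(), se = numeric(), hr = numeric(),
                      lower = numeric(), upper = numeric()))
  }
  z <- qnorm(1 - (1 - level) / 2)
  beta <- fit$estimate[is_beta]
  se <- sqrt(diag(fit$vcov))[is_beta]
  parts <- strsplit(nm[is_beta], ":", fixed = TRUE)
  data.frame(
    transition = vapply(parts, `[`, "", 1),
    term = vapply(parts, `[`, "", 2),
    beta = unname(beta), se = unname(se),
    hr = unname(exp(beta)),
    lower = unname(exp(beta - z * se)),
    upper = unname(exp(beta + z * se))
  )
}

#' Rank fitted models by BIC
#'
#' All fits must be to the same panel (checked on subject/observation
#' counts and interval fingerprints). Lower BIC is a better trade-off of
#' fit against parameter count.
#'
#' @param ... two or more `msm_fit` objects (optionally named).
#' @return data frame ranked by ascending BIC with `delta_bic` relative to
#'   the best model.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "msm_fit")) fits <- fits[[1]]
  stopifnot(all(vapply(fits, inherits, TRUE, "msm_fit")))
  if (length(fits) < 2) stop("supply at least two fits")
  sigs <- vapply(fits, function(f) paste(f$data_signature, collapse = "/"), "")
  if (length(unique(sigs)) != 1) {
    stop("fits are not on the same panel; BIC comparison is meaningless")
  }
  nms <- names(fits)
  if (is.null(nms) || any(nms == "")) nms <- paste0("model", seq_along(fits))
  out <- data.frame(
    model = nms,
    n_params = vapply(fits, `[[`, 0, "n_params"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    bic = vapply(fits, `[[`, 0, "bic")
  )
  out <- out[order(out$bic), , drop = FALSE]
  out$delta_bic <- out$bic - out$bic[1]
  rownames(out) <- NULL
  out
}

#' Serialise a fitted model to JSON
#'
#' Writes estimates, standard errors, the covariance matrix,
#' log-likelihood, BIC and convergence diagnostics.
#'
#' @param fit an `msm_fit`.
#' @param file output path.
#' @export
write_fit_json <- function(fit, file) {
  stopifnot(inherits(fit, "msm_fit"))
  obj <- list(
    stratum = fit$spec$stratum,
    transitions = trans_label(fit$spec$transitions),
    design = fit$spec$design,
    estimate = as.list(fit$estimate),
    se = if (!is.null(fit$vcov)) as.list(setNames(sqrt(diag(fit$vcov)),
                                                  names(fit$estimate))) else NULL,
    vcov = fit$vcov,
    loglik = fit$loglik, bic = fit$bic,
    n_subjects = fit$n_subjects, n_observations = fit$n_observations,
    converged = fit$converged, counts = as.list(fit$optim$counts)
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
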