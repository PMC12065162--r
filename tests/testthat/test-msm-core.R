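test_that("intensity matrix follows the proportional-intensities form", {
  spec <- msm_spec(covariates = c("age", "wealth"))
  nm <- param_names(spec)
  theta <- setNames(rep(0, length(nm)), nm)
  theta[!grepl(":", nm)] <- log(c(0.3, 0.15, 0.1, 0.07, 0.01, 0.02, 0.06))
  pars <- msm_params(spec, theta)

  # all betas zero: intensities equal baselines at any covariate pattern
  Q <- intensity_matrix(pars, covariate_profile(wealth_q = 4), age = 81.3)
  expect_equal(Q[1, 2], 0.3)
  expect_equal(Q[3, 4], 0.06)
  expect_equal(Q[1, 3], 0)  # robust -> frail forbidden
  expect_equal(Q[3, 1], 0)
  expect_equal(unname(Q[4, ]), rep(0, 4))
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)

  # an age effect of 0.1 multiplies the intensity by e per +10 years
  theta["q12:age"] <- 0.1
  pars <- msm_params(spec, theta)
  Q70 <- intensity_matrix(pars, covariate_profile(), age = 70)
  Q80 <- intensity_matrix(pars, covariate_profile(), age = 80)
  expect_equal(Q80[1, 2] / Q70[1, 2], exp(1), tolerance = 1e-12)
  expect_equal(Q80[2, 1], Q70[2, 1])  # untouched transition
})

test_that("transition probabilities: identity at t=0, closed form, stochasticity", {
  set.seed(101)
  Q <- random_generator(absorbing = TRUE)
  expect_equal(transition_probability(Q, 0), diag(4), ignore_attr = TRUE)
  expect_error(transition_probability(Q, -1), ">= 0")

  # two-state alive/dead closed form
  lam <- 0.23
  Q2 <- matrix(c(-lam, lam, 0, 0), 2, 2, byrow = TRUE)
  for (t in c(0.1, 1, 5)) {
    expect_equal(transition_probability(Q2, t)[1, 1], exp(-lam * t),
                 tolerance = 1e-12)
  }

  for (r in 1:10) {
    Qr <- random_generator()
    P <- transition_probability(Qr, 0.7)
    expect_lt(max(abs(P - expm_series(Qr, 0.7))), 1e-9)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-10)
    expect_true(all(P >= 0))
  }
})

test_that("interval likelihood matches a hand-built series oracle", {
  set.seed(202)
  spec <- msm_spec(covariates = c("age", "wealth"))
  nm <- param_names(spec)
  theta <- setNames(runif(length(nm), -0.1, 0.1), nm)
  theta[!grepl(":", nm)] <- log(c(0.3, 0.15, 0.12, 0.07, 0.02, 0.03, 0.08))
  pars <- msm_params(spec, theta)
  prof <- covariate_profile(wealth_q = 2)

  # three living observations then an exact death
  sub <- data.frame(subject_id = "s", age = c(70, 72, 74.2, 75.1),
                    state = c(1L, 2L, 3L, 4L),
                    exact_death = c(0L, 0L, 0L, 1L),
                    wealth_q = 2L, imd_q = 1L, education = "lt_hs",
                    married = 0L)
  got <- msm_loglik(pars, sub)
  want <- oracle_subject_loglik(pars, sub, prof)
  expect_equal(got, want, tolerance = 1e-9)

  # an observed robust -> frail interval is finite via the pre-frail path
  rf <- data.frame(subject_id = "s", age = c(70, 72), state = c(1L, 3L),
                   exact_death = c(0L, 0L), wealth_q = 2L, imd_q = 1L,
                   education = "lt_hs", married = 0L)
  ll <- msm_loglik(pars, rf)
  expect_true(is.finite(ll))
  expect_equal(ll, oracle_subject_loglik(pars, rf, prof), tolerance = 1e-9)

  # interval-censored death (no exact time)
  cens <- data.frame(subject_id = "s", age = c(70, 72), state = c(2L, 4L),
                     exact_death = c(0L, 0L), wealth_q = 2L, imd_q = 1L,
                     education = "lt_hs", married = 0L)
  expect_equal(msm_loglik(pars, cens),
               oracle_subject_loglik(pars, cens, prof), tolerance = 1e-9)
})

test_that("small-interval limit: log-likelihood of staying is -exit intensity * dt", {
  pars <- homogeneous_params(log(c(0.3, 0.15, 0.1, 0.07, 0.01, 0.02, 0.06)))
  sub <- data.frame(subject_id = "s", age = c(70, 70 + 1e-5),
                    state = c(2L, 2L), exact_death = c(0L, 0L))
  Q <- intensity_matrix(pars)
  expect_equal(msm_loglik(pars, sub), Q[2, 2] * 1e-5, tolerance = 1e-5)
})

test_that("likelihood is consistent under interval splitting (Chapman-Kolmogorov)", {
  pars <- homogeneous_params(log(c(0.3, 0.15, 0.1, 0.07, 0.01, 0.02, 0.06)))
  Q <- intensity_matrix(pars)
  P4 <- transition_probability(Q, 4)
  P2 <- transition_probability(Q, 2)
  # marginalising an unobserved state at the midpoint reproduces the longer
  # interval exactly
  expect_equal(P4[1, 3], sum(P2[1, ] * P2[, 3]), tolerance = 1e-10)
  expect_lt(max(abs(P4 - P2 %*% P2)), 1e-10)
})

test_that("constant-hazard fit recovers the rate and is a likelihood fixed point", {
  lambda <- 0.1
  panel <- two_state_panel(2000, lambda, dt = 2, seed = 33)
  fit <- fit_msm(panel, two_state_spec())
  expect_true(fit$converged)
  lam_hat <- exp(fit$estimate[["q14"]])
  se_log <- sqrt(diag(fit$vcov))[["q14"]]
  expect_lt(abs(fit$estimate[["q14"]] - log(lambda)), 3 * se_log)

  # refitting from the solution stays put
  refit <- fit_msm(panel, two_state_spec(), init = fit$estimate)
  expect_equal(refit$estimate, fit$estimate, tolerance = 1e-6)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-8)

  # analytic check: with exact death times and right censoring the MLE is
  # total deaths / total person-years
  iv <- frailspan:::panel_intervals(panel, two_state_spec())
  expect_equal(lam_hat, sum(iv$is_death) / sum(iv$dt), tolerance = 1e-4)
})

test_that("a panel with no observed deaths flags the death transitions", {
  panel <- data.frame(
    subject_id = rep(sprintf("s%03d", 1:80), each = 3),
    age = rep(c(60, 62, 64), 80),
    state = 1L, exact_death = 0L
  )
  set.seed(9)
  panel$state[seq(2, nrow(panel), 3)] <- sample(1:2, 80, replace = TRUE)
  panel$state[seq(3, nrow(panel), 3)] <- sample(1:2, 80, replace = TRUE)
  spec <- msm_spec(covariates = character(0))
  w <- capture_warnings(fit_msm(panel, spec, control = list(maxit = 50)))
  # every death transition is unidentified here and each is flagged
  expect_true(all(grepl("never observed", w)))
  expect_true(any(grepl("1->4", w)) && any(grepl("2->4", w)) &&
                any(grepl("3->4", w)))
})

test_that("hazard ratios exponentiate effects with Wald limits", {
  spec <- msm_spec(covariates = "wealth", per_transition =
                     list("2-4" = "wealth"),
                   transitions = matrix(c(2L, 4L), 1, 2))
  theta <- c("q24" = log(0.05), "q24:wealth" = -0.1625)
  V <- diag(c(0.01, 0.0567^2))
  dimnames(V) <- list(names(theta), names(theta))
  fit <- fake_fit(spec, theta, vcov = V)
  hr <- hazard_ratios(fit)
  expect_equal(hr$transition, "q24")
  expect_equal(hr$term, "wealth")
  expect_equal(round(hr$hr, 2), 0.85)
  expect_equal(round(hr$lower, 2), 0.76)
  expect_equal(round(hr$upper, 2), 0.95)
  expect_true(hr$lower < hr$hr & hr$hr < hr$upper)

  # zero effect maps to HR 1
  fit0 <- fake_fit(spec, c("q24" = log(0.05), "q24:wealth" = 0), vcov = V)
  expect_equal(hazard_ratios(fit0)$hr, 1)
})

test_that("BIC comparison ranks models and penalises free parameters", {
  spec1 <- msm_spec(covariates = character(0))
  spec2 <- msm_spec(covariates = "wealth")
  n <- 150
  th1 <- setNames(rep(log(0.1), length(param_names(spec1))),
                  param_names(spec1))
  th2 <- setNames(rep(0, length(param_names(spec2))), param_names(spec2))
  th2[!grepl(":", names(th2))] <- log(0.1)
  f1 <- fake_fit(spec1, th1, n_subjects = n, loglik = -800)
  f2 <- fake_fit(spec2, th2, n_subjects = n, loglik = -800)

  tie <- compare_models(a = f1, b = f1)
  expect_equal(tie$delta_bic, c(0, 0))

  cmp <- compare_models(small = f1, large = f2)
  expect_equal(cmp$model[1], "small")
  # identical log-likelihood: BIC grows by ln(n) per extra parameter
  expect_equal(cmp$delta_bic[2],
               (f2$n_params - f1$n_params) * log(n), tolerance = 1e-10)

  f3 <- fake_fit(spec1, th1, n_subjects = n + 1, loglik = -800)
  expect_error(compare_models(f1, f3), "same panel")
})

test_that("fit results serialise to JSON with estimates and diagnostics", {
  spec <- msm_spec(covariates = character(0))
  th <- setNames(log(c(0.3, 0.15, 0.1, 0.07, 0.01, 0.02, 0.06)),
                 param_names(spec))
  f <- tempfile(fileext = ".json")
  write_fit_json(fake_fit(spec, th), f)
  got <- jsonlite::read_json(f)
  expect_equal(got$estimate$q12, log(0.3))
  expect_true(got$converged)
  expect_equal(length(got$transitions), 7)
  unlink(f)
})
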