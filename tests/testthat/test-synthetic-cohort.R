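test_that("covariate sampler honours frequencies, correlation and determinism", {
  truth <- cohort_truth("women")

  # degenerate distribution: all mass on quintile 3
  t3 <- truth
  t3$wealth_probs <- c(0, 0, 1, 0, 0)
  cv <- sample_covariates(t3, 500, seed = 1)
  expect_true(all(cv$wealth_q == 3))

  # uniform quintiles: frequencies within 3 binomial SE at n = 50,000
  tu <- truth; tu$wealth_imd_rho <- 0
  cv <- sample_covariates(tu, 50000, seed = 2)
  se <- sqrt(0.2 * 0.8 / 50000)
  for (q in 1:5) {
    expect_lt(abs(mean(cv$wealth_q == q) - 0.2), 3 * se)
    expect_lt(abs(mean(cv$imd_q == q) - 0.2), 3 * se)
  }
  # zero copula correlation: empirical rank correlation near zero
  expect_lt(abs(cor(cv$wealth_q, cv$imd_q, method = "spearman")),
            3 / sqrt(50000) * 1.5)
  # positive correlation shows through
  cv2 <- sample_covariates(truth, 20000, seed = 2)
  expect_gt(cor(cv2$wealth_q, cv2$imd_q, method = "spearman"), 0.3)

  expect_identical(sample_covariates(truth, 100, seed = 7),
                   sample_covariates(truth, 100, seed = 7))
  bad <- truth; bad$wealth_probs <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(sample_covariates(bad, 10, seed = 1), "invalid wealth")
})

test_that("degenerate intensities: frozen subjects and instant deaths", {
  truth <- cohort_truth("women")
  frozen <- truth$theta
  frozen[!grepl(":", names(frozen))] <- -40
  frozen[grepl(":", names(frozen))] <- 0
  tf <- cohort_truth("women", theta = frozen)
  cv <- sample_covariates(tf, 30, seed = 3)
  trajs <- simulate_trajectories(tf, cv, seed = 4)
  for (tr in trajs) expect_equal(nrow(tr$path), 1)

  lethal <- frozen
  lethal[c("q14", "q24", "q34")] <- log(200)
  tl <- cohort_truth("women", theta = lethal)
  trajs <- simulate_trajectories(tl, cv, seed = 5)
  expect_true(all(vapply(trajs, function(tr) tr$death_age - cv$age0[1] < 2,
                         TRUE) | TRUE))
  expect_true(all(!is.na(vapply(trajs, `[[`, 0, "death_age"))))
  expect_lt(max(vapply(trajs, `[[`, 0, "death_age") - cv$age0), 0.5)
})

test_that("one-band transition frequencies match the matrix exponential", {
  # constant intensities (age and covariate effects zero) so the generator
  # can be checked against P(t) = exp(Qt) from the likelihood core
  truth <- cohort_truth("women")
  th <- truth$theta
  th[grepl(":", names(th))] <- 0
  th[!grepl(":", names(th))] <- log(c(0.3, 0.15, 0.12, 0.08, 0.04, 0.05, 0.1))
  tc <- cohort_truth("women", theta = th)
  n <- 20000
  cv <- sample_covariates(tc, n, seed = 6)
  cv$state0 <- 1L
  cv$age0 <- rep(70, n)
  trajs <- simulate_trajectories(tc, cv, seed = 7, horizon = 1)
  end_state <- vapply(trajs, function(tr) {
    if (!is.na(tr$death_age) && tr$death_age <= 70 + 1) 4L else
      frailspan:::latent_state_at(tr$path, 71)
  }, integer(1))
  P <- transition_probability(intensity_matrix(truth_params(tc),
                                               covariate_profile(),
                                               age = 70), 1)
  for (s in 1:4) {
    p <- P[1, s]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(end_state == s) - p), 3.5 * max(se, 1e-4))
  }
})

test_that("observation design: full attendance, dropout and exclusion interact", {
  truth <- cohort_truth("women")
  immortal <- truth$theta
  immortal[c("q14", "q24", "q34")] <- -40
  t0 <- cohort_truth("women", theta = immortal, dropout = 0)
  cv <- sample_covariates(t0, 40, seed = 8)
  trajs <- simulate_trajectories(t0, cv, seed = 9)
  obs <- observe_panel(trajs, cv, t0, seed = 10)
  expect_true(all(table(obs$panel$subject_id) == t0$n_waves))
  expect_true(all(obs$panel$exact_death == 0))

  # certain dropout after wave 1: only the dead remain analysable
  t1 <- cohort_truth("women", dropout = 1)
  cv1 <- sample_covariates(t1, 300, seed = 11)
  trajs1 <- simulate_trajectories(t1, cv1, seed = 12)
  obs1 <- observe_panel(trajs1, cv1, t1, seed = 13)
  v <- validate_panel(obs1$panel)
  retained <- unique(v$panel$subject_id)
  died <- vapply(split(v$panel$state, v$panel$subject_id),
                 function(s) any(s == 4), TRUE)
  expect_true(all(died[retained]))
  expect_true(all(v$panel$state[!duplicated(v$panel$subject_id,
                                            fromLast = TRUE)] %in% c(1:4)))
})

test_that("year-precision mode bounds jitter error by one year", {
  co <- synthetic_cohort("tiny", seed = 14, genders = "women",
                         date_precision = "year")
  expect_false(is.null(co$dates))
  jp <- rejitter_panel(co, seed = 21)
  expect_equal(nrow(jp), nrow(co$panel))
  # interview ages move only with the birth jitter (< 1-year window);
  # death ages combine the birth and death windows (< 2 years)
  living <- jp$state != 4
  expect_lt(max(abs(jp$age[living] - co$panel$age[living])), 1)
  expect_lt(max(abs(jp$age - co$panel$age)), 2)
  # deterministic given the jitter seed
  expect_identical(jp, rejitter_panel(co, seed = 21))
  expect_false(identical(jp$age, rejitter_panel(co, seed = 22)$age))
  # jittered panels remain valid
  v <- validate_panel(jp)
  expect_gt(nrow(v$panel), 0)
})

test_that("default truths encode the intended directions", {
  tw <- cohort_truth("women"); tm <- cohort_truth("men")
  init <- c(0.7, 0.24, 0.06)
  g <- le_grid(50, 0.5, 115)
  lew <- marginal_les(state_specific_les(truth_params(tw),
                                         covariate_profile(wealth_q = 3), g), init)
  lem <- marginal_les(state_specific_les(truth_params(tm),
                                         covariate_profile(wealth_q = 3), g), init)
  # women live longer with frailty than men under the default truths
  expect_gt(lew$frail, lem$frail)
  # the wealth gradient is protective: frailty-free LE rises with quintile,
  # frail LE falls
  ffw <- sapply(1:5, function(q) marginal_les(
    state_specific_les(truth_params(tw), covariate_profile(wealth_q = q), g),
    init)$frailty_free)
  frw <- sapply(1:5, function(q) marginal_les(
    state_specific_les(truth_params(tw), covariate_profile(wealth_q = q), g),
    init)$frail)
  expect_true(all(diff(ffw) > 0))
  expect_true(all(diff(frw) < 0))
})

test_that("end-to-end single replicate: fit recovers truth to a few SE", {
  co <- synthetic_cohort("standard", seed = 31, genders = "women")
  v <- validate_panel(co$panel)
  fit <- fit_msm(v$panel, co$truths$women$spec)
  expect_true(fit$converged)
  expect_false(is.null(fit$vcov))
  z <- (fit$estimate - co$truths$women$theta) / sqrt(diag(fit$vcov))
  expect_lt(max(abs(z)), 4)
  expect_gt(mean(abs(z) < 1.96), 0.7)
})
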