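test_that("homogeneous-model integrator matches the fundamental matrix", {
  set.seed(404)
  pars <- homogeneous_params()  # random baselines, no age effect
  Q <- intensity_matrix(pars)
  closed <- solve(-Q[1:3, 1:3])
  e <- state_specific_les(pars, grid = le_grid(50, h = 0.1, age_max = 450))
  expect_lt(max(abs(e - closed) / closed), 0.005)
})

test_that("overwhelming mortality drives all expectancies to zero", {
  pars <- homogeneous_params(log(c(0.3, 0.15, 0.1, 0.07, 50, 50, 50)))
  e <- state_specific_les(pars, grid = le_grid(50, h = 0.01, age_max = 60))
  expect_lt(max(e), 0.05)
  # and they shrink monotonically as mortality grows
  pars2 <- homogeneous_params(log(c(0.3, 0.15, 0.1, 0.07, 5, 5, 5)))
  e2 <- state_specific_les(pars2, grid = le_grid(50, h = 0.01, age_max = 60))
  expect_true(all(diag(e) < diag(e2)))
})

test_that("halving the step converges toward the closed form", {
  pars <- homogeneous_params(log(c(0.3, 0.15, 0.1, 0.07, 0.05, 0.06, 0.1)))
  Q <- intensity_matrix(pars)
  closed <- solve(-Q[1:3, 1:3])
  e1 <- state_specific_les(pars, grid = le_grid(50, h = 1, age_max = 450))
  e2 <- state_specific_les(pars, grid = le_grid(50, h = 0.5, age_max = 450))
  err1 <- max(abs(e1 - closed))
  err2 <- max(abs(e2 - closed))
  expect_lt(err2, err1)
  expect_lt(max(abs(e2 - e1)), 4 * err1)
})

test_that("a too-short horizon is reported", {
  pars <- homogeneous_params(log(c(0.3, 0.15, 0.1, 0.07, 0.01, 0.01, 0.02)))
  expect_warning(state_specific_les(pars, grid = le_grid(50, 0.5, 70)),
                 "horizon")
})

test_that("initial state distribution: degenerate, age-flat and logit cases", {
  base <- data.frame(subject_id = sprintf("s%03d", 1:50),
                     age = runif(50, 50, 80), state = 1L, exact_death = 0L)
  expect_equal(unname(initial_state_distribution(base, 60)), c(1, 0, 0))

  # states independent of age: multinom recovers the plain proportions
  set.seed(77)
  n <- 3000
  base2 <- data.frame(subject_id = sprintf("s%05d", 1:n),
                      age = runif(n, 50, 90),
                      state = sample(1:3, n, TRUE, prob = c(0.5, 0.3, 0.2)),
                      exact_death = 0L)
  p <- initial_state_distribution(base2, 65)
  emp <- tabulate(base2$state, 3) / n
  expect_equal(unname(p), emp, tolerance = 0.05)

  # known age-dependent logit law recovered within 3 SE at a probe age
  set.seed(78)
  age <- runif(n, 50, 90)
  eta2 <- -1 + 0.05 * (age - 50); eta3 <- -2.5 + 0.08 * (age - 50)
  den <- 1 + exp(eta2) + exp(eta3)
  u <- runif(n)
  st <- ifelse(u < exp(eta2) / den, 2L, ifelse(u < (exp(eta2) + exp(eta3)) / den, 3L, 1L))
  base3 <- data.frame(subject_id = sprintf("s%05d", 1:n), age = age,
                      state = st, exact_death = 0L)
  p70 <- initial_state_distribution(base3, 70)
  eta2t <- -1 + 0.05 * 20; eta3t <- -2.5 + 0.08 * 20
  dent <- 1 + exp(eta2t) + exp(eta3t)
  truth <- c(1, exp(eta2t), exp(eta3t)) / dent
  se <- sqrt(truth * (1 - truth) / n) * 3  # generous: 3 x binomial SE
  expect_true(all(abs(p70 - truth) < 3 * pmax(se, 0.01)))

  expect_error(initial_state_distribution(base[0, ], 60), "no living")
})

test_that("marginal life expectancies conserve and weight correctly", {
  e <- matrix(c(20, 6, 2, 12, 9, 4, 6, 7, 8), 3, 3, byrow = TRUE,
              dimnames = list(frailspan:::STATE_LABELS[1:3],
                              frailspan:::STATE_LABELS[1:3]))
  m1 <- marginal_les(e, c(1, 0, 0))
  expect_equal(unname(m1$by_state), unname(e[1, ]))
  expect_equal(m1$frailty_free, 26)
  expect_equal(m1$frail, 2)
  expect_equal(m1$total, 28)

  mu <- marginal_les(e, c(1, 1, 1) / 3)
  expect_equal(unname(mu$by_state), unname(colMeans(e)), tolerance = 1e-12)
  expect_equal(mu$frailty_free + mu$frail, mu$total, tolerance = 1e-8)
  expect_equal(mu$pct_frailty_free + mu$pct_frail, 100, tolerance = 1e-8)
})

test_that("zero covariance collapses bootstrap intervals onto the point", {
  spec <- msm_spec(covariates = character(0))
  th <- setNames(log(c(0.3, 0.15, 0.1, 0.07, 0.05, 0.06, 0.1)),
                 param_names(spec))
  V0 <- matrix(0, 7, 7, dimnames = list(names(th), names(th)))
  fit <- fake_fit(spec, th, vcov = V0)
  b <- suppressWarnings(bootstrap_les(fit, covariate_profile(),
                                      le_grid(50, 0.5, 300),
                                      init_dist = c(0.6, 0.3, 0.1),
                                      n_draws = 50, seed = 4))
  expect_equal(b$ci$frailty_free[1], b$frailty_free, tolerance = 1e-10)
  expect_equal(b$ci$frailty_free[2], b$frailty_free, tolerance = 1e-10)
  expect_equal(b$ci$total[1], b$ci$total[2], tolerance = 1e-10)
})

test_that("bootstrap draws are reproducible and conserve state time", {
  spec <- msm_spec(covariates = character(0))
  th <- setNames(log(c(0.3, 0.15, 0.1, 0.07, 0.05, 0.06, 0.1)),
                 param_names(spec))
  V <- diag(rep(0.003, 7)); dimnames(V) <- list(names(th), names(th))
  fit <- fake_fit(spec, th, vcov = V)
  g <- le_grid(50, 0.5, 300)
  b1 <- bootstrap_les(fit, covariate_profile(), g, c(0.6, 0.3, 0.1),
                      n_draws = 200, seed = 12)
  b2 <- bootstrap_les(fit, covariate_profile(), g, c(0.6, 0.3, 0.1),
                      n_draws = 200, seed = 12)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$draws, b2$draws)
  # conservation holds draw by draw, not just at the point estimate
  expect_lt(max(abs(b1$draws[, "frailty_free"] + b1$draws[, "frail"] -
                      b1$draws[, "total"])), 1e-8)
  expect_lt(max(abs(b1$draws[, "pct_frailty_free"] +
                      b1$draws[, "pct_frail"] - 100)), 1e-8)
})

test_that("microsimulation agrees with the deterministic integrator", {
  pars <- homogeneous_params(log(c(0.3, 0.15, 0.1, 0.07, 0.05, 0.06, 0.1)))
  g <- le_grid(50, 0.25, 300)
  e <- state_specific_les(pars, grid = g)
  ms <- microsim_les(pars, grid = g, start_state = 1, n = 4000, seed = 5)
  se <- attr(ms, "se")
  for (s in 1:3) {
    expect_lt(abs(ms[s] - e[1, s]), 4 * max(se[s], 0.02))
  }
})

test_that("protective effects and older starting ages order life expectancies", {
  spec <- msm_spec(covariates = c("age", "wealth"))
  nm <- param_names(spec)
  theta <- setNames(rep(0, length(nm)), nm)
  theta[!grepl(":", nm)] <- log(c(0.3, 0.15, 0.1, 0.07, 0.012, 0.02, 0.065))
  theta[grepl(":age", nm)] <- c(0.05, -0.03, 0.05, -0.03, 0.1, 0.095, 0.09)
  theta[grepl(":wealth", nm)] <- -0.15
  pars <- msm_params(spec, theta)
  ff <- sapply(c(1, 3, 5), function(q) {
    marginal_les(state_specific_les(pars, covariate_profile(wealth_q = q),
                                    le_grid(50, 0.5, 115)),
                 c(0.7, 0.24, 0.06))$frailty_free
  })
  expect_true(all(diff(ff) > 0))

  tot <- sapply(c(50, 60, 70, 80), function(a) {
    marginal_les(state_specific_les(pars, covariate_profile(wealth_q = 3),
                                    le_grid(a, 0.5, 115)),
                 c(0.7, 0.24, 0.06))$total
  })
  expect_true(all(diff(tot) < 0))
})
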