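#' Ground truth for a synthetic ageing cohort
#'
#' Bundles everything the generator needs: a transition model (an
#' [msm_spec()] plus a true parameter vector on the same scale the fitter
#' estimates), the baseline population (age distribution, baseline-state
#' logit law, covariate joint distribution) and the observation design
#' (biennial waves, attrition, vital-date precision).
#'
#' The default truths are calibrated qualitatively, not numerically, to an
#' English ageing cohort: intensities rise log-linearly with age
#' (Gompertz-type), recovery declines with age, higher wealth protects
#' against frailty onset and against death (from the pre-frail state for
#' women, from the robust state for men), women have lower mortality but
#' higher frailty onset than men. They are intended for direction and
#' recovery tests, never as reproductions of published estimates.
#'
#' @param stratum `"women"` or `"men"`; picks the default parameter set.
#' @param theta optional named replacement for the true parameter vector.
#' @param n_waves number of interview waves (default 9).
#' @param wave_interval years between waves (default 2).
#' @param dropout per-wave probability of non-death attrition (absorbing
#'   for observation, not survival; default 0.05).
#' @param p_wealth_shift per-wave probability that the wealth quintile
#'   moves one step up or down (default 0.02).
#' @param p_marital_change per-wave probability that marital status
#'   toggles (default 0.02).
#' @param wealth_imd_rho Gaussian-copula correlation between the wealth and
#'   deprivation quintile ranks (default 0.5; deprivation quintile 5 is the
#'   least deprived, so the correlation is positive).
#' @param date_precision `"exact"` (death and birth times known exactly) or
#'   `"year"` (vital dates degraded to calendar-year windows, to exercise
#'   the date-jittering sensitivity analysis).
#' @return object of class `cohort_truth`.
#' @export
cohort_truth <- function(stratum = c("women", "men"), theta = NULL,
                         n_waves = 9, wave_interval = 2, dropout = 0.05,
                         p_wealth_shift = 0.02, p_marital_change = 0.02,
                         wealth_imd_rho = 0.5,
                         date_precision = c("exact", "year")) {
  stratum <- match.arg(stratum)
  date_precision <- match.arg(date_precision)
  spec <- msm_spec(
    covariates = "age",
    per_transition = if (stratum == "women") {
      list("1-2" = c("age", "wealth"), "2-3" = c("age", "wealth"),
           "2-4" = c("age", "wealth"))
    } else {
      list("1-2" = c("age", "wealth"), "2-3" = c("age", "wealth"),
           "1-4" = c("age", "wealth"))
    },
    stratum = stratum, age_offset = 70
  )
  default_theta <- if (stratum == "women") c(
    "q12" = log(0.30), "q12:age" = 0.05, "q12:wealth" = -0.15,
    "q21" = log(0.14), "q21:age" = -0.03,
    "q23" = log(0.10), "q23:age" = 0.05, "q23:wealth" = -0.15,
    "q32" = log(0.07), "q32:age" = -0.03,
    "q14" = log(0.012), "q14:age" = 0.10,
    "q24" = log(0.020), "q24:age" = 0.095, "q24:wealth" = -0.16,
    "q34" = log(0.065), "q34:age" = 0.09
  ) else c(
    "q12" = log(0.26), "q12:age" = 0.05, "q12:wealth" = -0.15,
    "q21" = log(0.15), "q21:age" = -0.03,
    "q23" = log(0.09), "q23:age" = 0.05, "q23:wealth" = -0.15,
    "q32" = log(0.07), "q32:age" = -0.03,
    "q14" = log(0.018), "q14:age" = 0.10, "q14:wealth" = -0.21,
    "q24" = log(0.028), "q24:age" = 0.095,
    "q34" = log(0.085), "q34:age" = 0.09
  )
  params <- msm_params(spec, if (is.null(theta)) default_theta else theta)
  out <- list(
    stratum = stratum, spec = spec,
    theta = setNames(as.numeric(params), names(params)),
    # baseline ages: 50+, right-skewed towards the younger end
    age0_sampler = function(n) 50 + 40 * rbeta(n, 1.2, 3.4),
    # multinomial logit of baseline state on (age - 50):
    # log P(prefrail)/P(robust), log P(frail)/P(robust)
    baseline_logit = list(prefrail = c(intercept = -1.06, age = 0.062),
                          frail = c(intercept = -2.39, age = 0.076)),
    wealth_probs = rep(0.2, 5), imd_probs = rep(0.2, 5),
    wealth_imd_rho = wealth_imd_rho,
    education_probs = c(lt_hs = 0.37, hs = 0.175, gt_hs = 0.455),
    p_married = 0.697,
    n_waves = as.integer(n_waves), wave_interval = wave_interval,
    dropout = dropout, p_wealth_shift = p_wealth_shift,
    p_marital_change = p_marital_change, date_precision = date_precision
  )
  out$education_probs <- out$education_probs / sum(out$education_probs)
  class(out) <- "cohort_truth"
  out
}

#' True parameters of a cohort truth as an `msm_params` object
#'
#' @param truth a [cohort_truth()].
#' @return `msm_params` usable anywhere a fitted parameter vector is.
#' @export
truth_params <- function(truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  msm_params(truth$spec, truth$theta)
}

#' Sample baseline covariates, ages and states for a synthetic cohort
#'
#' Wealth and deprivation quintiles are drawn from their marginal
#' frequencies with a Gaussian-copula rank correlation; education and
#' marital status independently; the baseline age from the truth's age
#' sampler; and the baseline living state from the truth's age-dependent
#' multinomial logit law.
#'
#' @param truth a [cohort_truth()].
#' @param n number of subjects.
#' @param seed integer seed.
#' @return data frame `subject_id`, `age0`, `state0`, `wealth_q`, `imd_q`,
#'   `education`, `married`.
#' @export
sample_covariates <- function(truth, n, seed) {
  stopifnot(inherits(truth, "cohort_truth"), n >= 1)
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("invalid ", what, " frequency vector")
    }
  }
  check_probs(truth$wealth_probs, "wealth")
  check_probs(truth$imd_probs, "deprivation")
  check_probs(truth$education_probs, "education")
  set.seed(as.integer(seed))
  rho <- truth$wealth_imd_rho
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  to_quintile <- function(z, probs) {
    br <- qnorm(cumsum(probs)[-length(probs)])
    findInterval(z, br) + 1L
  }
  wealth_q <- to_quintile(z1, truth$wealth_probs)
  imd_q <- to_quintile(z2, truth$imd_probs)
  education <- sample(EDU_LEVELS, n, replace = TRUE,
                      prob = truth$education_probs)
  married <- runif(n) < truth$p_married
  age0 <- truth$age0_sampler(n)
  bl <- truth$baseline_logit
  eta2 <- bl$prefrail["intercept"] + bl$prefrail["age"] * (age0 - 50)
  eta3 <- bl$frail["intercept"] + bl$frail["age"] * (age0 - 50)
  denom <- 1 + exp(eta2) + exp(eta3)
  u <- runif(n)
  p2 <- exp(eta2) / denom
  p3 <- exp(eta3) / denom
  state0 <- ifelse(u < p2, STATE_PREFRAIL,
                   ifelse(u < p2 + p3, STATE_FRAIL, STATE_ROBUST))
  data.frame(
    subject_id = sprintf("S%05d", seq_len(n)), age0 = age0,
    state0 = as.integer(state0), wealth_q = wealth_q, imd_q = imd_q,
    education = education, married = married, stringsAsFactors = FALSE
  )
}

# wave-by-wave covariate path for one subject (wealth drift, marital
# toggles; deprivation quintile held fixed)
covariate_path <- function(truth, wealth_q, married) {
  W <- truth$n_waves
  wq <- integer(W); mar <- logical(W)
  wq[1] <- wealth_q; mar[1] <- married
  for (w in 2:W) {
    wq[w] <- wq[w - 1]
    if (runif(1) < truth$p_wealth_shift) {
      wq[w] <- max(1L, min(5L, wq[w] + sample(c(-1L, 1L), 1)))
    }
    mar[w] <- if (runif(1) < truth$p_marital_change) !mar[w - 1] else mar[w - 1]
  }
  data.frame(wave = seq_len(W), wealth_q = wq, married = mar)
}

#' Simulate latent frailty trajectories under a known truth
#'
#' Each subject's continuous-time path is simulated exactly under the
#' truth's intensity model, piecewise-homogeneous over 1-year age bands
#' (intensities evaluated at the band midpoint age) with competing
#' exponential clocks choosing the next event. Time-varying covariates
#' (wealth, marital status) update at wave boundaries. Death is absorbing;
#' the latent death time is exact.
#'
#' @param truth a [cohort_truth()].
#' @param covariates data frame from [sample_covariates()].
#' @param seed integer seed.
#' @param horizon years of follow-up after baseline; defaults to the full
#'   wave design `(n_waves - 1) * wave_interval`.
#' @return list of per-subject records: `subject_id`, `path` (jump data
#'   frame `age`, `state`), `death_age` (`NA` if alive at the horizon),
#'   `cov_path` (per-wave covariate values).
#' @export
simulate_trajectories <- function(truth, covariates, seed,
                                  horizon = NULL) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(as.integer(seed))
  if (is.null(horizon)) {
    horizon <- (truth$n_waves - 1) * truth$wave_interval
  }
  spec <- truth$spec
  B <- coef_matrix(spec, truth$theta)
  lapply(seq_len(nrow(covariates)), function(i) {
    cv <- covariates[i, ]
    cov_path <- covariate_path(truth, cv$wealth_q, cv$married)
    age0 <- cv$age0
    state <- cv$state0
    ages <- age0; states <- state
    a <- age0
    for (w in seq_len(truth$n_waves)) {
      if (state == STATE_DEAD) break
      seg_end <- age0 + min(w * truth$wave_interval, horizon)
      if (a >= seg_end) next
      prof <- covariate_profile(
        wealth_q = cov_path$wealth_q[w], imd_q = cv$imd_q,
        education = cv$education, married = cov_path$married[w]
      )
      z <- profile_row(spec, prof, age = a)
      seg <- sim_path_banded(B, spec, z, a, seg_end, state, age0)
      if (nrow(seg) > 1) {
        ages <- c(ages, seg$age[-1]); states <- c(states, seg$state[-1])
      }
      state <- states[length(states)]
      a <- seg_end
    }
    death_age <- if (STATE_DEAD %in% states) ages[states == STATE_DEAD] else
      NA_real_
    list(subject_id = cv$subject_id,
         path = data.frame(age = ages, state = as.integer(states)),
         death_age = death_age, cov_path = cov_path)
  })
}

# like sim_path() but with 1-year bands anchored at band_origin so that
# band boundaries line up across wave segments
sim_path_banded <- function(B, spec, z0, a0, a_end, state, band_origin) {
  age_col <- if ("age" %in% spec$columns) match("age", spec$columns) else 0L
  trans <- spec$transitions
  x <- z0
  a <- a0
  ages <- a; states <- state
  while (a < a_end - 1e-12 && state != STATE_DEAD) {
    band_end <- min(band_origin + floor(a - band_origin + 1e-12) + 1, a_end)
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
  data.frame(age = ages, state = as.integer(states))
}

latent_state_at <- function(path, age) {
  path$state[max(which(path$age <= age + 1e-9))]
}

#' Observe latent trajectories as an interval-censored panel
#'
#' Samples each latent path at the biennial wave ages, applies per-wave
#' attrition (absorbing for observation but not survival: deaths are still
#' recorded through mortality linkage up to the follow-up horizon), and
#' records deaths with their exact age. With `date_precision = "year"` the
#' cohort is anchored to calendar time and vital dates are degraded to
#' calendar-year windows, producing the inputs for [jitter_dates()].
#'
#' @param trajectories output of [simulate_trajectories()].
#' @param covariates the matching [sample_covariates()] frame.
#' @param truth the [cohort_truth()] used to simulate.
#' @param seed integer seed (attrition and calendar anchoring).
#' @return list: `panel` (true-age panel data frame with `wave` for living
#'   rows), plus, in year-precision mode, `dates` (year windows and
#'   interview-date constraints per subject) and `interviews` (long frame
#'   of calendar interview dates).
#' @export
observe_panel <- function(trajectories, covariates, truth, seed) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(as.integer(seed) + 1L)
  W <- truth$n_waves
  horizon_rel <- (W - 1) * truth$wave_interval
  year_mode <- truth$date_precision == "year"
  rows <- vector("list", length(trajectories))
  dates <- vector("list", length(trajectories))
  interviews <- vector("list", length(trajectories))
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    cv <- covariates[i, ]
    wave_ages <- cv$age0 + (seq_len(W) - 1) * truth$wave_interval
    observed <- logical(W)
    observed[1] <- TRUE
    for (w in 2:W) {
      if (!observed[w - 1]) break
      observed[w] <- runif(1) >= truth$dropout
    }
    alive_at <- if (is.na(tr$death_age)) rep(TRUE, W) else
      wave_ages < tr$death_age
    use <- observed & alive_at
    # observation ends at the first missed wave: deaths before that age are
    # seen (the subject was still enrolled), later deaths are not, so
    # attrition censors death and survival symmetrically (non-informative)
    first_missed <- which(!observed)[1]
    window_end <- if (is.na(first_missed)) cv$age0 + horizon_rel else
      wave_ages[first_missed]
    if (!any(use)) next  # died before any chance of follow-up handled below
    ws <- which(use)
    sub_rows <- data.frame(
      subject_id = tr$subject_id, wave = ws, age = wave_ages[ws],
      state = vapply(wave_ages[ws], function(a) latent_state_at(tr$path, a),
                     integer(1)),
      exact_death = 0L,
      wealth_q = tr$cov_path$wealth_q[ws], imd_q = cv$imd_q,
      education = cv$education,
      married = as.integer(tr$cov_path$married[ws]),
      stringsAsFactors = FALSE
    )
    if (!is.na(tr$death_age) && tr$death_age <= window_end) {
      last <- nrow(sub_rows)
      sub_rows <- rbind(sub_rows, data.frame(
        subject_id = tr$subject_id, wave = NA_integer_, age = tr$death_age,
        state = STATE_DEAD, exact_death = 1L,
        wealth_q = sub_rows$wealth_q[last], imd_q = cv$imd_q,
        education = cv$education, married = sub_rows$married[last],
        stringsAsFactors = FALSE
      ))
    }
    rows[[i]] <- sub_rows
    if (year_mode) {
      date0 <- as.Date("2002-03-01") + floor(runif(1) * 365)
      iv_dates <- date0 + round((wave_ages - cv$age0) * 365.25)
      birth_true <- date0 - round(cv$age0 * 365.25)
      death_true <- if (is.na(tr$death_age)) as.Date(NA) else
        birth_true + round(tr$death_age * 365.25)
      year_window <- function(d) {
        y <- as.integer(format(d, "%Y"))
        c(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)))
      }
      bw <- year_window(birth_true)
      has_death <- sub_rows$state[nrow(sub_rows)] == STATE_DEAD
      dw <- if (has_death) year_window(death_true) else as.Date(c(NA, NA))
      living_ws <- ws
      dates[[i]] <- data.frame(
        subject_id = tr$subject_id, birth_min = bw[1], birth_max = bw[2],
        death_min = dw[1], death_max = dw[2],
        first_interview = iv_dates[living_ws[1]],
        last_interview = iv_dates[living_ws[length(living_ws)]],
        birth_true = birth_true, death_true = death_true,
        stringsAsFactors = FALSE
      )
      interviews[[i]] <- data.frame(
        subject_id = tr$subject_id, wave = living_ws,
        date = iv_dates[living_ws], stringsAsFactors = FALSE
      )
    }
  }
  panel <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(panel) <- NULL
  out <- list(panel = panel)
  if (year_mode) {
    out$dates <- do.call(rbind, dates[!vapply(dates, is.null, TRUE)])
    out$interviews <- do.call(rbind,
                              interviews[!vapply(interviews, is.null, TRUE)])
    rownames(out$dates) <- rownames(out$interviews) <- NULL
  }
  out
}

#' Generate a complete synthetic ageing cohort
#'
#' End-to-end generator: samples covariates and baseline states, simulates
#' latent trajectories under the stratum truths, and observes them as a
#' biennial interval-censored panel. Presets scale the cohort: `"tiny"`
#' (200 subjects, for smoke tests), `"standard"` (2,000) and `"large"`
#' (15,003, the full study-like size). Women make up 54.5% of subjects.
#'
#' @param preset `"tiny"`, `"standard"` or `"large"` (ignored when `n` is
#'   given).
#' @param seed integer seed governing every random element.
#' @param genders subset of `c("women", "men")`.
#' @param n optional explicit number of subjects.
#' @param date_precision `"exact"` or `"year"` vital dates.
#' @param truths optional named list of [cohort_truth()] objects per
#'   gender, overriding the defaults.
#' @return object of class `synthetic_cohort`: `panel` (with `gender`
#'   column), `covariates`, `truths`, and in year mode `dates` and
#'   `interviews`.
#' @export
synthetic_cohort <- function(preset = c("standard", "tiny", "large"),
                             seed = 1, genders = c("women", "men"), n = NULL,
                             date_precision = c("exact", "year"),
                             truths = NULL) {
  preset <- match.arg(preset)
  date_precision <- match.arg(date_precision)
  genders <- match.arg(genders, c("women", "men"), several.ok = TRUE)
  if (is.null(n)) {
    n <- switch(preset, tiny = 200L, standard = 2000L, large = 15003L)
  }
  frac <- c(women = 0.545, men = 0.455)[genders]
  frac <- frac / sum(frac)
  n_per <- setNames(round(n * frac), genders)
  panels <- list(); dates <- list(); interviews <- list(); covs <- list()
  out_truths <- list()
  for (k in seq_along(genders)) {
    g <- genders[k]
    truth <- if (!is.null(truths) && g %in% names(truths)) truths[[g]] else
      cohort_truth(g, date_precision = date_precision)
    truth$date_precision <- date_precision
    out_truths[[g]] <- truth
    sub_seed <- as.integer(seed) + 101L * k
    cv <- sample_covariates(truth, n_per[g], sub_seed)
    cv$subject_id <- paste0(toupper(substr(g, 1, 1)), cv$subject_id)
    trajs <- simulate_trajectories(truth, cv, sub_seed + 1L)
    obs <- observe_panel(trajs, cv, truth, sub_seed + 2L)
    obs$panel$gender <- if (g == "women") "woman" else "man"
    panels[[g]] <- obs$panel
    covs[[g]] <- cbind(cv, gender = obs$panel$gender[1])
    if (date_precision == "year") {
      dates[[g]] <- obs$dates
      interviews[[g]] <- obs$interviews
    }
  }
  out <- list(
    panel = do.call(rbind, panels), covariates = do.call(rbind, covs),
    truths = out_truths, preset = preset, seed = seed,
    date_precision = date_precision
  )
  rownames(out$panel) <- rownames(out$covariates) <- NULL
  if (date_precision == "year") {
    out$dates <- do.call(rbind, dates)
    out$interviews <- do.call(rbind, interviews)
    rownames(out$dates) <- rownames(out$interviews) <- NULL
  }
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic ageing cohort (", x$preset, " preset, seed ", x$seed, "):\n",
      sep = "")
  cat(" ", length(unique(x$panel$subject_id)), "subjects,",
      nrow(x$panel), "panel records,", x$date_precision, "vital dates\n")
  invisible(x)
}

#' Re-derive panel ages from jittered vital dates
#'
#' For a year-precision synthetic cohort, draws exact birth and death dates
#' within the calendar-year windows (see [jitter_dates()]) and recomputes
#' every observation age from them, reproducing the sensitivity-analysis
#' protocol of repeating the whole analysis over several jitter seeds.
#'
#' @param cohort a [synthetic_cohort()] built with
#'   `date_precision = "year"`.
#' @param seed jitter seed.
#' @return the cohort's panel with ages recomputed from jittered dates.
#' @export
rejitter_panel <- function(cohort, seed) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (cohort$date_precision != "year") {
    stop("cohort was generated with exact dates; nothing to jitter")
  }
  jit <- jitter_dates(cohort$dates, seed)
  birth <- setNames(jit$birth, jit$subject_id)
  death <- setNames(jit$death, jit$subject_id)
  iv_date <- setNames(cohort$interviews$date,
                      paste(cohort$interviews$subject_id,
                            cohort$interviews$wave))
  panel <- cohort$panel
  living <- panel$state != STATE_DEAD
  key <- paste(panel$subject_id, panel$wave)
  panel$age[living] <- as.numeric(
    iv_date[key[living]] - birth[panel$subject_id[living]]) / 365.25
  dead <- !living
  panel$age[dead] <- as.numeric(
    death[panel$subject_id[dead]] - birth[panel$subject_id[dead]]) / 365.25
  panel
}
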