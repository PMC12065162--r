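# Independent oracles and small fixture builders used across the suite.

# truncated power-series matrix exponential (independent of the package's
# scaling-and-squaring / uniformization routines)
expm_series <- function(A, t = 1, terms = 30) {
  S <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(terms)) {
    term <- term %*% (A * t) / k
    S <- S + term
  }
  S
}

# random valid 4-state generator (non-negative off-diagonal, zero row sums)
random_generator <- function(absorbing = FALSE) {
  Q <- matrix(runif(16, 0.02, 0.5), 4, 4)
  diag(Q) <- 0
  if (absorbing) Q[4, ] <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# a homogeneous (no covariate) model over all seven allowed transitions
# with given or random log baseline intensities
homogeneous_params <- function(log_q = NULL) {
  spec <- msm_spec(covariates = character(0))
  nm <- param_names(spec)
  if (is.null(log_q)) log_q <- log(runif(length(nm), 0.05, 0.5))
  msm_params(spec, setNames(log_q, nm))
}

# brute-force log-likelihood for one subject, built from intensity_matrix()
# and the series exponential only (never touches the compiled core)
oracle_subject_loglik <- function(object, sub, profile,
                                  age_at = c("midpoint", "start")) {
  age_at <- match.arg(age_at)
  spec <- frailspan:::params_spec(object)
  ll <- 0
  for (i in seq_len(nrow(sub) - 1)) {
    a0 <- sub$age[i]; a1 <- sub$age[i + 1]
    dt <- a1 - a0
    amid <- if (age_at == "midpoint") a0 + dt / 2 else a0
    has_age <- "age" %in% spec$columns
    Q <- intensity_matrix(object, profile, age = if (has_age) amid else NULL)
    P <- expm_series(Q, dt, terms = 40)
    r <- sub$state[i]; s <- sub$state[i + 1]
    if (s == 4 && sub$exact_death[i + 1] == 1) {
      Qd <- intensity_matrix(object, profile, age = if (has_age) a1 else NULL)
      ll <- ll + log(sum(P[r, 1:3] * Qd[1:3, 4]))
    } else if (s == 4) {
      ll <- ll + log(P[r, 4])
    } else {
      ll <- ll + log(P[r, s])
    }
  }
  unname(ll)
}

# simulate the simple alive -> dead constant-hazard observation scheme:
# each subject seen at age 50 and followed for one interval of `dt` years;
# death within the interval is recorded at its exact time
two_state_panel <- function(n, lambda, dt = 2, seed = 1) {
  set.seed(seed)
  tt <- rexp(n, lambda)
  died <- tt < dt
  rows <- lapply(seq_len(n), function(i) {
    if (died[i]) {
      data.frame(subject_id = sprintf("T%05d", i), age = c(50, 50 + tt[i]),
                 state = c(1L, 4L), exact_death = c(0L, 1L))
    } else {
      data.frame(subject_id = sprintf("T%05d", i), age = c(50, 50 + dt),
                 state = c(1L, 1L), exact_death = c(0L, 0L))
    }
  })
  do.call(rbind, rows)
}

two_state_spec <- function() {
  msm_spec(covariates = character(0),
           transitions = matrix(c(1L, 4L), 1, 2))
}

# fabricate a minimal msm_fit-shaped object for interface-level tests
fake_fit <- function(spec, theta, vcov = NULL, n_subjects = 100,
                     loglik = -500) {
  nm <- param_names(spec)
  stopifnot(all(nm %in% names(theta)))
  if (is.null(vcov)) {
    vcov <- diag(rep(1e-4, length(nm)))
    dimnames(vcov) <- list(nm, nm)
  }
  structure(list(
    spec = spec, estimate = theta[nm], vcov = vcov, loglik = loglik,
    n_subjects = n_subjects, n_observations = 3 * n_subjects,
    n_intervals = 2 * n_subjects, n_params = length(nm),
    bic = -2 * loglik + length(nm) * log(n_subjects), converged = TRUE,
    optim = list(counts = c(1, 1), convergence = 0),
    data_signature = c(n_subjects, 3 * n_subjects, 1, 1)
  ), class = "msm_fit")
}
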