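#' Default allowed-transition structure of the four-state frailty model
#'
#' Robust and frail are not adjacent: direct robust-to-frail moves (and the
#' reverse) are excluded, so any observed robust-to-frail change over an
#' interval is attributed to an unobserved passage through pre-frailty.
#' Death is reachable from every living state and absorbing.
#'
#' @return integer matrix with columns `from`, `to`, one row per allowed
#'   instantaneous transition.
#' @export
default_transitions <- function() {
  m <- rbind(
    c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L),
    c(1L, 4L), c(2L, 4L), c(3L, 4L)
  )
  colnames(m) <- c("from", "to")
  m
}

# canonical covariate term order and how each term maps panel columns to a
# numeric design value
COVARIATE_TERMS <- c("age", "wealth", "imd", "educ_hs", "educ_gths", "married")

trans_label <- function(trans) paste0(trans[, 1], "-", trans[, 2])

expand_terms <- function(terms) {
  terms <- unlist(lapply(terms, function(t) {
    if (t == "education") c("educ_hs", "educ_gths") else t
  }))
  bad <- setdiff(terms, COVARIATE_TERMS)
  if (length(bad)) {
    stop("unknown covariate term(s): ", paste(bad, collapse = ", "),
         " (available: age, wealth, imd, education, married)")
  }
  unique(terms)
}

#' Specify a multi-state model
#'
#' Defines the allowed-transition structure and, for each allowed
#' transition, which covariates scale its intensity. Intensities are
#' log-linear in the covariates (proportional intensities), so each
#' coefficient exponentiates to a hazard ratio:
#' `q_rs(z) = q0_rs * exp(sum_k beta_rs,k * z_k)`.
#'
#' Covariate coding: `age` enters centred at `age_offset` years; `wealth`
#' and `imd` are quintile scores 0..4 (quintile minus one), so the baseline
#' refers to the first quintile and each coefficient is a per-quintile
#' log-hazard increment; `education` expands to two dummies (`educ_hs`,
#' `educ_gths`) with less-than-high-school as reference; `married` is 0/1.
#'
#' By default the age covariate attached to an observation interval is
#' evaluated at the interval midpoint (`age_at = "midpoint"`), which removes
#' the first-order bias of the piecewise-homogeneous approximation for
#' smoothly age-increasing hazards; `age_at = "start"` gives the plain
#' interval-start convention. Non-age time-varying covariates always take
#' their interval-start (wave) values, since that is when they are measured.
#'
#' @param covariates character vector of terms applied to every allowed
#'   transition (`"age"`, `"wealth"`, `"imd"`, `"education"`, `"married"`).
#' @param per_transition optional named list overriding the term set for
#'   specific transitions, names like `"1-2"`, `"2-4"`.
#' @param transitions allowed-transition matrix; defaults to
#'   [default_transitions()]. Must be a subset of it (plus, for reduced toy
#'   models, any pair among states 1..3 to 4 or between 1..3).
#' @param stratum optional label recording the fitting stratum (e.g.
#'   `"women"`); models are fitted separately per gender rather than with a
#'   gender covariate.
#' @param age_offset centring constant for the age covariate, years.
#' @param age_at `"midpoint"` or `"start"`: where within an observation
#'   interval the age covariate is evaluated.
#' @return an object of class `msm_spec`.
#' @export
msm_spec <- function(covariates = "age", per_transition = NULL,
                     transitions = default_transitions(), stratum = NULL,
                     age_offset = 70, age_at = c("midpoint", "start")) {
  age_at <- match.arg(age_at)
  transitions <- as.matrix(transitions)
  storage.mode(transitions) <- "integer"
  if (ncol(transitions) != 2 || nrow(transitions) < 1) {
    stop("transitions must be a matrix with columns from, to")
  }
  if (any(transitions[, 1] == 4L)) stop("no transitions out of the dead state")
  if (any(transitions < 1L | transitions > 4L) ||
      any(transitions[, 1] == transitions[, 2])) {
    stop("transitions must be ordered pairs of distinct states in 1..4")
  }
  labs <- trans_label(transitions)
  if (anyDuplicated(labs)) stop("duplicate transitions")
  design <- rep(list(expand_terms(covariates)), nrow(transitions))
  names(design) <- labs
  if (!is.null(per_transition)) {
    bad <- setdiff(names(per_transition), labs)
    if (length(bad)) stop("per_transition names not allowed transitions: ",
                          paste(bad, collapse = ", "))
    for (nm in names(per_transition)) {
      design[[nm]] <- expand_terms(per_transition[[nm]])
    }
  }
  columns <- intersect(COVARIATE_TERMS, unique(unlist(design)))
  out <- list(
    transitions = transitions, design = design, columns = columns,
    stratum = stratum, age_offset = age_offset, age_at = age_at
  )
  class(out) <- "msm_spec"
  out
}

#' Parameter names of a model specification
#'
#' Baselines are named `q12`, `q21`, ... (log scale); covariate effects
#' `q12:age`, `q24:wealth`, ... in specification order.
#'
#' @param spec an [msm_spec()].
#' @return character vector of parameter names.
#' @export
param_names <- function(spec) {
  stopifnot(inherits(spec, "msm_spec"))
  labs <- trans_label(spec$transitions)
  base <- paste0("q", spec$transitions[, 1], spec$transitions[, 2])
  unlist(lapply(seq_along(labs), function(i) {
    c(base[i], if (length(spec$design[[i]]))
      paste0(base[i], ":", spec$design[[i]]))
  }))
}

#' Construct a parameter vector for a model specification
#'
#' @param spec an [msm_spec()].
#' @param theta named numeric vector; must contain exactly the names from
#'   [param_names()] (any order). Baselines `qrs` are log intensities at the
#'   reference covariate pattern; `qrs:term` entries are log hazard ratios.
#' @return object of class `msm_params` (named vector with the spec
#'   attached).
#' @export
msm_params <- function(spec, theta) {
  nm <- param_names(spec)
  if (!all(nm %in% names(theta)) || length(theta) != length(nm)) {
    stop("theta must have exactly the parameters: ", paste(nm, collapse = ", "))
  }
  theta <- theta[nm]
  if (any(!is.finite(theta))) stop("parameters must be finite")
  structure(as.numeric(theta), names = nm, spec = spec, class = "msm_params")
}

params_spec <- function(object) {
  if (inherits(object, "msm_fit")) return(object$spec)
  if (inherits(object, "msm_params")) return(attr(object, "spec"))
  stop("expected an msm_fit or msm_params object")
}

params_theta <- function(object) {
  if (inherits(object, "msm_fit")) return(object$estimate)
  if (inherits(object, "msm_params")) {
    return(setNames(as.numeric(object), names(object)))
  }
  stop("expected an msm_fit or msm_params object")
}

# theta (named) -> coefficient matrix B: n_trans x (1 + K), structural zeros
# where a term is not in that transition's design
coef_matrix <- function(spec, theta) {
  labs <- trans_label(spec$transitions)
  base <- paste0("q", spec$transitions[, 1], spec$transitions[, 2])
  K <- length(spec$columns)
  B <- matrix(0, nrow = nrow(spec$transitions), ncol = 1 + K)
  for (i in seq_along(labs)) {
    B[i, 1] <- theta[[base[i]]]
    for (term in spec$design[[i]]) {
      B[i, 1 + match(term, spec$columns)] <- theta[[paste0(base[i], ":", term)]]
    }
  }
  B
}

#' A covariate profile for prediction
#'
#' Bundles the socio-economic covariates at which intensities or life
#' expectancies are evaluated. Age is not part of the profile: it is the
#' time scale and is supplied separately.
#'
#' @param wealth_q,imd_q wealth and area-deprivation quintiles (1 =
#'   least wealthy / most deprived, 5 = wealthiest / least deprived).
#' @param education one of `"lt_hs"`, `"hs"`, `"gt_hs"`.
#' @param married logical.
#' @return object of class `covariate_profile`.
#' @export
covariate_profile <- function(wealth_q = 1, imd_q = 1, education = "lt_hs",
                              married = FALSE) {
  if (!wealth_q %in% 1:5 || !imd_q %in% 1:5) stop("quintiles must be in 1..5")
  education <- match.arg(education, EDU_LEVELS)
  out <- list(wealth_q = as.integer(wealth_q), imd_q = as.integer(imd_q),
              education = education, married = as.logical(married))
  class(out) <- "covariate_profile"
  out
}

# numeric design row (length K = length(spec$columns)) for a profile;
# the age column (if present) is filled with `age - age_offset`
profile_row <- function(spec, profile, age = NULL) {
  stopifnot(inherits(profile, "covariate_profile"))
  vals <- c(
    age = if (is.null(age)) 0 else age - spec$age_offset,
    wealth = profile$wealth_q - 1,
    imd = profile$imd_q - 1,
    educ_hs = as.numeric(profile$education == "hs"),
    educ_gths = as.numeric(profile$education == "gt_hs"),
    married = as.numeric(profile$married)
  )
  vals[spec$columns]
}

#' Transition intensity matrix at a covariate pattern
#'
#' Builds the 4x4 generator `Q(z)` with off-diagonal entries
#' `q_rs = exp(log q0_rs + sum_k beta_rs,k z_k)` on the allowed transitions,
#' zeros elsewhere, diagonal minus the row sum, and an all-zero dead row.
#'
#' @param object an `msm_params` or fitted `msm_fit`.
#' @param profile a [covariate_profile()].
#' @param age age in years at which to evaluate age-dependent intensities.
#' @return 4x4 intensity matrix with state dimnames.
#' @export
intensity_matrix <- function(object, profile = covariate_profile(),
                             age = NULL) {
  spec <- params_spec(object)
  theta <- params_theta(object)
  if (is.null(age)) {
    if ("age" %in% spec$columns) {
      stop("the model has an age effect: supply age=")
    }
    age <- spec$age_offset
  }
  B <- coef_matrix(spec, theta)
  x <- profile_row(spec, profile, age = age)
  Q <- matrix(0, 4, 4, dimnames = list(STATE_LABELS, STATE_LABELS))
  for (i in seq_len(nrow(spec$transitions))) {
    eta <- B[i, 1] + sum(B[i, -1] * x)
    q <- exp(eta)
    if (!is.finite(q)) stop("non-finite intensity for transition ",
                            trans_label(spec$transitions)[i])
    Q[spec$transitions[i, 1], spec$transitions[i, 2]] <- q
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix over an interval
#'
#' `P(t) = exp(Qt)` for a time-homogeneous intensity matrix `Q`, computed by
#' Pade scaling-and-squaring. Rows sum to one; `P(0)` is the identity.
#'
#' @param Q 4x4 (or any square) intensity matrix: non-negative off-diagonal,
#'   rows summing to zero.
#' @param t duration in years, `t >= 0`.
#' @return the transition probability matrix.
#' @export
transition_probability <- function(Q, t) {
  Q <- as.matrix(Q)
  if (length(t) != 1 || !is.finite(t) || t < 0) stop("t must be a single value >= 0")
  off <- Q; diag(off) <- 0
  if (any(off < -1e-12)) stop("off-diagonal intensities must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("intensity matrix rows must sum to zero")
  P <- expm_mat(Q * t)
  dimnames(P) <- dimnames(Q)
  # clip tiny negative round-off
  P[P < 0 & P > -1e-12] <- 0
  P
}

# Decompose a validated panel into likelihood intervals.
# Returns list(from, to, dt, is_death, X, subject) with X in spec column
# order. `is_death` = 1 marks exactly observed deaths (state before death
# marginalised); interval-censored deaths keep is_death = 0 with to = 4.
panel_intervals <- function(panel, spec) {
  panel <- panel[order(panel$subject_id, panel$age), , drop = FALSE]
  sid <- panel$subject_id
  n <- nrow(panel)
  first <- !duplicated(sid)
  # interval i pairs row i (start) with row i+1 when both belong to one subject
  start <- seq_len(n - 1)[!first[-1]]
  if (!length(start)) stop("panel has no observation intervals")
  stopi <- start + 1L
  dt <- panel$age[stopi] - panel$age[start]
  if (any(dt <= 0)) stop("ages must be strictly increasing within subject (ties are errors)")
  from <- panel$state[start]
  to <- panel$state[stopi]
  if (any(from == STATE_DEAD)) stop("interval starting in the dead state")
  is_death <- as.integer(to == STATE_DEAD & panel$exact_death[stopi] == 1)

  K <- length(spec$columns)
  X <- matrix(0, nrow = length(start), ncol = K)
  colnames(X) <- spec$columns
  get0 <- function(col, default) {
    if (col %in% names(panel)) panel[[col]][start] else
      rep(default, length(start))
  }
  for (term in spec$columns) {
    X[, term] <- switch(term,
      age = {
        a <- if (spec$age_at == "midpoint") panel$age[start] + dt / 2 else
          panel$age[start]
        a - spec$age_offset
      },
      wealth = get0("wealth_q", 1) - 1,
      imd = get0("imd_q", 1) - 1,
      educ_hs = as.numeric(get0("education", "lt_hs") == "hs"),
      educ_gths = as.numeric(get0("education", "lt_hs") == "gt_hs"),
      married = as.numeric(get0("married", 0))
    )
  }
  if (any(is.na(X))) stop("missing covariate values in panel (complete-case analysis: drop or fill before fitting)")
  age_col <- if ("age" %in% spec$columns) match("age", spec$columns) - 1L else -1L
  # gap between the age at which X's age column was evaluated and the death
  # age (= interval end), used to evaluate the terminal death hazard at the
  # death age itself
  death_shift <- ifelse(is_death == 1,
                        if (spec$age_at == "midpoint") dt / 2 else dt, 0)
  list(from = from, to = to, dt = dt, is_death = is_death, X = X,
       subject = sid[start], age_col = age_col, death_shift = death_shift)
}
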