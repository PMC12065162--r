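#' Validate an interval-censored multi-state panel
#'
#' Enforces the per-subject ordering invariants of the four-state panel and
#' applies the longitudinal inclusion rule: subjects contribute only if they
#' appear in at least two waves alive, or are known to have died after
#' appearing in one wave. Excluded subjects are counted and reported, not
#' silently dropped.
#'
#' Hard errors (data corruption rather than exclusions): duplicate
#' (subject, age) records, any record after a dead record, `exact_death`
#' flagged on a living state, states outside 1..4, non-increasing ages.
#'
#' @param panel data frame with at least `subject_id`, `age`, `state`
#'   (1 = robust, 2 = pre-frail, 3 = frail, 4 = dead) and `exact_death`
#'   (0/1; 1 only on dead records whose age is the death time). Covariate
#'   columns (`gender`, `wealth_q`, `imd_q`, `education`, `married`) are
#'   carried through untouched.
#' @return a list of class `frailspan_panel_validation`:
#'   `panel` (retained rows, ordered by subject and age),
#'   `excluded` (data frame `subject_id`, `reason`), and
#'   `counts` (subjects in / retained / excluded).
#' @export
validate_panel <- function(panel) {
  need <- c("subject_id", "age", "state")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns subject_id, age, state")
  }
  if (!"exact_death" %in% names(panel)) panel$exact_death <- 0L
  panel$state <- as.integer(panel$state)
  if (any(is.na(panel$state)) || any(!panel$state %in% 1:4)) {
    stop("states must be integers in 1..4 (drop records with missing state first)")
  }
  if (any(panel$exact_death == 1 & panel$state != STATE_DEAD)) {
    stop("exact_death flagged on a living record")
  }
  if (any(!is.finite(panel$age)) || any(panel$age <= 0)) {
    stop("ages must be positive and finite")
  }
  panel <- panel[order(panel$subject_id, panel$age), , drop = FALSE]

  key <- paste(panel$subject_id, panel$age)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, age) records: ",
         paste(head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }

  sid <- panel$subject_id
  idx <- split(seq_len(nrow(panel)), sid)
  excluded <- list()
  keep <- rep(TRUE, nrow(panel))
  for (s in names(idx)) {
    i <- idx[[s]]
    st <- panel$state[i]
    dead_at <- which(st == STATE_DEAD)
    if (length(dead_at) > 1) {
      stop("subject ", s, " has more than one dead record")
    }
    if (length(dead_at) == 1 && dead_at != length(i)) {
      stop("subject ", s, " has records after death (death is absorbing)")
    }
    n_living <- sum(st != STATE_DEAD)
    has_death <- length(dead_at) == 1
    if (n_living == 0 || (n_living < 2 && !has_death)) {
      keep[i] <- FALSE
      excluded[[s]] <- if (n_living == 0) "no living observation" else
        "single living observation without known death"
    }
  }
  excluded <- data.frame(
    subject_id = names(excluded),
    reason = unlist(excluded, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  out <- list(
    panel = panel[keep, , drop = FALSE],
    excluded = excluded,
    counts = c(
      subjects_in = length(idx),
      subjects_retained = length(idx) - nrow(excluded),
      subjects_excluded = nrow(excluded)
    )
  )
  class(out) <- "frailspan_panel_validation"
  out
}

#' @export
print.frailspan_panel_validation <- function(x, ...) {
  cat("Validated multi-state panel:", x$counts["subjects_retained"],
      "subjects retained,", x$counts["subjects_excluded"], "excluded,",
      nrow(x$panel), "observations\n")
  invisible(x)
}

#' Draw exact vital dates within year-precision windows
#'
#' Cohort releases often degrade dates of birth and death to roughly 1-year
#' precision. This utility draws exact dates uniformly within the stated
#' windows, respecting the ordering constraints that birth precedes the
#' first interview and death follows the last living interview. Draws are
#' deterministic given `seed`.
#'
#' @param dates data frame with one row per subject: `subject_id`,
#'   `birth_min`, `birth_max` (Date or ISO-8601 strings), optionally
#'   `death_min`, `death_max` (`NA` for survivors), and optionally
#'   `first_interview`, `last_interview` used as ordering constraints.
#' @param seed integer seed controlling the draw.
#' @return data frame `subject_id`, `birth`, `death` (Date; `death` is `NA`
#'   for survivors).
#' @export
jitter_dates <- function(dates, seed) {
  if (!all(c("subject_id", "birth_min", "birth_max") %in% names(dates))) {
    stop("dates must have subject_id, birth_min, birth_max")
  }
  as_d <- function(x) if (inherits(x, "Date")) x else as.Date(as.character(x))
  bmin <- as_d(dates$birth_min)
  bmax <- as_d(dates$birth_max)
  has_death <- "death_min" %in% names(dates) &&
    !all(is.na(dates$death_min))
  dmin <- if ("death_min" %in% names(dates)) as_d(dates$death_min) else
    rep(as.Date(NA), nrow(dates))
  dmax <- if ("death_max" %in% names(dates)) as_d(dates$death_max) else
    rep(as.Date(NA), nrow(dates))
  if ("first_interview" %in% names(dates)) {
    bmax <- pmin(bmax, as_d(dates$first_interview) - 1)
  }
  if ("last_interview" %in% names(dates)) {
    dmin <- pmax(dmin, as_d(dates$last_interview) + 1)
  }
  if (any(bmax < bmin)) {
    stop("empty feasible birth window for subject(s) ",
         paste(head(dates$subject_id[bmax < bmin], 3), collapse = ", "))
  }
  dead <- !is.na(dmin) & !is.na(dmax)
  if (any(dead & dmax < dmin)) {
    stop("empty feasible death window for subject(s) ",
         paste(head(dates$subject_id[dead & dmax < dmin], 3), collapse = ", "))
  }
  set.seed(as.integer(seed))
  n <- nrow(dates)
  # uniform over whole days within the closed window
  birth <- bmin + floor(runif(n) * (as.numeric(bmax - bmin) + 1))
  death <- rep(as.Date(NA), n)
  if (any(dead)) {
    death[dead] <- dmin[dead] +
      floor(runif(sum(dead)) * (as.numeric(dmax[dead] - dmin[dead]) + 1))
  }
  data.frame(subject_id = dates$subject_id, birth = birth, death = death)
}

#' Exact ages at interview (and death) from calendar dates
#'
#' Ages are elapsed days divided by 365.25.
#'
#' @param birth Date of birth (length 1).
#' @param interviews vector of interview Dates, strictly increasing.
#' @param death optional Date of death (after the last interview).
#' @return list with `ages` (per interview) and `death_age` (`NA` if no
#'   death date was supplied).
#' @export
ages_from_dates <- function(birth, interviews, death = NULL) {
  birth <- as.Date(birth)
  interviews <- as.Date(interviews)
  if (is.unsorted(interviews, strictly = TRUE)) {
    stop("interview dates must be strictly increasing")
  }
  ages <- as.numeric(interviews - birth) / 365.25
  if (any(ages <= 0)) stop("interview before birth")
  death_age <- NA_real_
  if (!is.null(death) && !is.na(death)) {
    death <- as.Date(death)
    death_age <- as.numeric(death - birth) / 365.25
    if (death_age <= max(ages)) stop("death not after last interview")
  }
  list(ages = ages, death_age = death_age)
}

#' Read / write a multi-state panel CSV
#'
#' Columns: `subject_id`, `age`, `state` (1-4), `exact_death` (0/1), and the
#' covariates `gender`, `wealth_q`, `imd_q`, `education`
#' (`lt_hs`/`hs`/`gt_hs`), `married` (0/1). Extra columns are preserved.
#'
#' @param file path to CSV.
#' @return `read_panel`: the panel data frame.
#' @export
read_panel <- function(file) {
  x <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "state")
  if (!all(need %in% names(x))) {
    stop("panel CSV must have columns ", paste(need, collapse = ", "))
  }
  x$state <- as.integer(x$state)
  if ("married" %in% names(x)) x$married <- as.integer(x$married)
  x
}

#' @rdname read_panel
#' @param panel panel data frame.
#' @export
write_panel <- function(panel, file) {
  write.csv(panel, file, row.names = FALSE)
  invisible(file)
}
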