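#' Compute a deficit-accumulation frailty index
#'
#' The frailty index of a subject-wave record is the mean of its non-missing
#' deficit values: the proportion of accumulated health deficits out of a
#' fixed list of 60 items. Binary deficits are coded 0/1; graded deficits
#' must already be scaled to \[0, 1\]. Records with too many missing items
#' (completeness below `min_completeness`) yield `NA`: that wave is dropped,
#' not the subject.
#'
#' @param deficits a numeric vector of length 60, or a matrix / data frame
#'   with 60 columns (one row per subject-wave). Values in \[0, 1\]; `NA`
#'   marks a missing item.
#' @param min_completeness minimum fraction of non-missing items required
#'   for the index to be defined. The default 0.8 (at least 48 of 60 items)
#'   follows common frailty-index practice; the threshold is not fixed by
#'   the deficit list itself and can be changed.
#'
#' @return a data frame with columns `value` (the index, `NA` when
#'   completeness is insufficient) and `n_nonmissing`.
#' @examples
#' frailty_index(c(rep(1, 15), rep(0, 45)))  # 15/60 = 0.25
#' @export
frailty_index <- function(deficits, min_completeness = 0.8) {
  if (is.null(dim(deficits))) deficits <- matrix(deficits, nrow = 1)
  deficits <- as.matrix(deficits)
  if (ncol(deficits) != 60L) {
    stop("a deficit record must have exactly 60 items, got ", ncol(deficits))
  }
  if (!is.numeric(deficits)) stop("deficits must be numeric")
  rng <- range(deficits, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
    stop("deficit values must lie in [0, 1]")
  }
  if (length(min_completeness) != 1 || min_completeness <= 0 ||
      min_completeness > 1) {
    stop("min_completeness must be a single value in (0, 1]")
  }
  n_nonmiss <- rowSums(!is.na(deficits))
  value <- ifelse(n_nonmiss > 0, rowMeans(deficits, na.rm = TRUE), NA_real_)
  value[n_nonmiss < min_completeness * 60] <- NA_real_
  data.frame(value = value, n_nonmissing = as.integer(n_nonmiss))
}

#' Classify a frailty index into robust / pre-frail / frail
#'
#' Uses the established categorical cut-points on the frailty index:
#' robust when the index is at most 0.08, frail when it is at least 0.25,
#' pre-frail strictly in between. The boundary values 0.08 and 0.25 belong
#' to robust and frail respectively. Classification never produces the dead
#' state; death enters the panel through vital-status records, not deficits.
#'
#' @param index numeric vector of frailty-index values in \[0, 1\] (`NA`
#'   allowed and propagated).
#' @return an integer vector of state codes (1 = robust, 2 = pre-frail,
#'   3 = frail) with a `"labels"` attribute-free plain coding used across
#'   the package.
#' @examples
#' classify_frailty(c(0.08, 0.10, 0.25))  # 1, 2, 3
#' @export
classify_frailty <- function(index) {
  if (any(index < 0 | index > 1, na.rm = TRUE)) {
    stop("frailty index values must lie in [0, 1]")
  }
  out <- rep(NA_integer_, length(index))
  out[!is.na(index) & index <= 0.08] <- STATE_ROBUST
  out[!is.na(index) & index > 0.08 & index < 0.25] <- STATE_PREFRAIL
  out[!is.na(index) & index >= 0.25] <- STATE_FRAIL
  out
}

#' Frailty index and state for a table of deficit records
#'
#' Convenience wrapper applying [frailty_index()] and [classify_frailty()]
#' to a long deficit table with one row per subject-wave.
#'
#' @param deficit_table data frame with columns `subject_id`, `wave` and 60
#'   deficit columns (any names; all columns other than `subject_id` and
#'   `wave` are taken as deficits, in order).
#' @inheritParams frailty_index
#' @return data frame `subject_id`, `wave`, `frailty_index`, `n_nonmissing`,
#'   `state` (NA state where the index is undefined).
#' @export
frailty_states <- function(deficit_table, min_completeness = 0.8) {
  need <- c("subject_id", "wave")
  if (!all(need %in% names(deficit_table))) {
    stop("deficit table must have subject_id and wave columns")
  }
  dcols <- setdiff(names(deficit_table), need)
  fi <- frailty_index(deficit_table[, dcols, drop = FALSE], min_completeness)
  data.frame(
    subject_id = deficit_table$subject_id,
    wave = as.integer(deficit_table$wave),
    frailty_index = fi$value,
    n_nonmissing = fi$n_nonmissing,
    state = classify_frailty(fi$value)
  )
}

#' Read a deficit table from CSV
#'
#' Expected columns: `subject_id`, `wave`, then 60 deficit columns
#' (`d01`..`d60` by convention); empty cells are missing items.
#'
#' @param file path to a CSV file.
#' @return data frame suitable for [frailty_states()].
#' @export
read_deficit_table <- function(file) {
  x <- read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "wave") %in% names(x))) {
    stop("deficit CSV must have subject_id and wave columns")
  }
  if (ncol(x) != 62L) {
    stop("deficit CSV must have subject_id, wave and 60 deficit columns")
  }
  x
}

#' Write frailty indices and states to CSV
#'
#' @param states data frame from [frailty_states()].
#' @param file output path.
#' @export
write_frailty_states <- function(states, file) {
  write.csv(states[, c("subject_id", "wave", "frailty_index", "state")],
            file, row.names = FALSE)
  invisible(file)
}
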