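#' Contrast a life-expectancy quantity between two groups
#'
#' The point difference is the difference of point estimates; the interval
#' comes from per-draw differences of the bootstrap streams. When both
#' results were produced from the same fitted model with the same bootstrap
#' seed (see [bootstrap_les()]), the draw streams are identical and the
#' contrast is paired: shared parameter noise cancels. Results from
#' separately fitted strata (e.g. women vs men) carry independent streams
#' and the per-draw differences simply convolve the two uncertainties.
#'
#' @param result_a,result_b `le_result` objects from [bootstrap_les()] with
#'   kept draws. The difference is `result_a - result_b`.
#' @param quantity one of `"frailty_free"`, `"frail"`, `"total"`,
#'   `"pct_frailty_free"`, `"pct_frail"`.
#' @param level confidence level.
#' @return object of class `group_contrast`: `quantity`, `difference`,
#'   `ci`, `paired`, `n_draws`.
#' @export
group_contrast <- function(result_a, result_b, quantity = "frailty_free",
                           level = 0.95) {
  quantity <- match.arg(quantity, le_quantities)
  for (r in list(result_a, result_b)) {
    if (!inherits(r, "le_result") || is.null(r$draws)) {
      stop("both results must be bootstrap_les() outputs with kept draws")
    }
    if (!quantity %in% colnames(r$draws)) {
      stop("quantity ", quantity, " not present in draws")
    }
  }
  if (result_a$n_draws != result_b$n_draws) {
    stop("results carry different numbers of draws")
  }
  paired <- !is.null(result_a$boot_id) && !is.null(result_b$boot_id) &&
    sub("/[^/]*$", "", result_a$boot_id) == sub("/[^/]*$", "", result_b$boot_id)
  dd <- result_a$draws[, quantity] - result_b$draws[, quantity]
  a <- (1 - level) / 2
  out <- list(
    quantity = quantity,
    difference = result_a[[quantity]] - result_b[[quantity]],
    ci = unname(quantile(dd, c(a, 1 - a))),
    paired = paired, n_draws = result_a$n_draws, level = level
  )
  class(out) <- "group_contrast"
  out
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("%s difference: %.1f [%.1f, %.1f] (%s draws, %s)\n",
              x$quantity, x$difference, x$ci[1], x$ci[2], x$n_draws,
              if (x$paired) "paired" else "independent"))
  invisible(x)
}

# round-half-even to 1 decimal, formatted with a fixed decimal place
fmt1 <- function(x) formatC(round(x, 1), format = "f", digits = 1)

le_cell <- function(est, ci = NULL) {
  if (is.null(ci)) fmt1(est) else
    sprintf("%s (%s–%s)", fmt1(est), fmt1(ci[1]), fmt1(ci[2]))
}

#' Render a stratified life-expectancy table
#'
#' One row per group; columns give frailty-free, frail and total life
#' expectancies in years and the frailty-free / frail percentages of
#' remaining life, each to one decimal (round-half-even) with bracketed
#' 95% intervals where available. Percentages are computed from the
#' unrounded years and rounded once, at formatting.
#'
#' @param results named list of `le_result` objects (names become the
#'   group labels).
#' @param file optional path; when given the table is written as CSV and a
#'   plain-text rendering is written alongside with extension `.txt`.
#' @return data frame of formatted cells (invisibly when written).
#' @export
render_le_table <- function(results, file = NULL) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  rows <- lapply(names(results), function(g) {
    r <- results[[g]]
    stopifnot(inherits(r, "le_result"))
    ci <- r$ci
    data.frame(
      group = g,
      frailty_free_years = le_cell(r$frailty_free, ci$frailty_free),
      frailty_free_pct = le_cell(r$pct_frailty_free, ci$pct_frailty_free),
      frail_years = le_cell(r$frail, ci$frail),
      frail_pct = le_cell(r$pct_frail, ci$pct_frail),
      total_years = le_cell(r$total, ci$total),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (!is.null(file)) {
    write.csv(tab, file, row.names = FALSE)
    txt <- file.path(dirname(file),
                     sub("\\.[^.]*$", ".txt", basename(file)))
    widths <- pmax(nchar(names(tab)), apply(tab, 2, function(c) max(nchar(c))))
    line <- function(vals) paste(mapply(formatC, vals, width = widths,
                                        flag = "-"), collapse = "  ")
    writeLines(c(line(names(tab)), line(rep("-", length(widths))),
                 apply(tab, 1, line)), txt)
    return(invisible(tab))
  }
  tab
}
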