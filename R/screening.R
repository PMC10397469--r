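#' Rescale change scores onto a six-unit span
#'
#' Z-score normalisation followed by a linear rescale so that the observed
#' range of the series spans exactly 6 units (the minimal important change of
#' the emPHasis-10 instrument). Pearson correlations are invariant to this
#' affine map, so the rescale exists for reporting parity only; the screen in
#' [correlation_screen()] operates on raw changes and cannot differ.
#'
#' @param x Numeric change scores (NAs preserved in place).
#' @param name Series name used in error messages.
#' @return Numeric vector of the same length, mean 0, range 6.
#' @examples
#' normalize_to_six_units(c(-1, 0, 1))  # -3 0 3
#' @export
normalize_to_six_units <- function(x, name = "series") {
  ok <- !is.na(x)
  if (sum(ok) < 3L) stop("need at least 3 observations to normalise ", name)
  s <- sd(x[ok])
  if (!is.finite(s) || s == 0) stop("zero variance in ", name)
  z <- (x - mean(x[ok])) / s
  span <- diff(range(z[ok]))
  z * (6 / span)
}

#' Correlation screen for a metric-anchor pair
#'
#' Admits a metric-anchor pair to MID estimation only when the Pearson
#' correlation between the metric changes and the anchor changes is at least
#' weak: `|r| > threshold` (default 0.20). The absolute value is used because
#' an anchor whose score falls with improvement correlates negatively with a
#' metric that rises with improvement; the magnitude carries the
#' responsiveness information.
#'
#' @param metric_changes,anchor_changes Per-patient change scores; pairs with
#'   a missing value in either series are dropped (pairwise-complete).
#' @param threshold Screening threshold on `|r|` (default 0.20).
#' @return An object of class `mid_screen`: list with `r`, `n`, `passed`,
#'   `threshold`.
#' @examples
#' correlation_screen(1:10, (1:10) * 2)  # r = 1, passed
#' @export
correlation_screen <- function(metric_changes, anchor_changes,
                               threshold = 0.20) {
  ok <- !is.na(metric_changes) & !is.na(anchor_changes)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 complete pairs to screen (have ", n, ")")
  x <- metric_changes[ok]
  y <- anchor_changes[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant series: correlation is undefined")
  }
  r <- cor(x, y)
  structure(list(r = r, n = n, passed = abs(r) > threshold,
                 threshold = threshold),
            class = "mid_screen")
}

#' Screen every metric against every change-threshold anchor
#'
#' Runs [correlation_screen()] for each metric-anchor pair using absolute
#' metric changes and raw anchor changes. Pairs whose screen cannot be
#' computed (too few pairs, constant series) are reported with `r = NA` and
#' `passed = FALSE`.
#'
#' @param cohort Cohort data frame.
#' @param metrics Named list of [metric_definition()]s.
#' @param anchors Named list of [anchor_definition()]s; binary-survival
#'   anchors are skipped (they have no change score to correlate).
#' @param threshold Screening threshold on `|r|`.
#' @return Data frame with columns `metric`, `anchor`, `n`, `r`, `passed`.
#' @export
screen_anchors <- function(cohort, metrics, anchors, threshold = 0.20) {
  rows <- list()
  for (a in anchors) {
    if (a$kind != "change_threshold") next
    d <- anchor_changes(cohort, a)
    for (m in metrics) {
      x <- .metric_changes(cohort, m, "absolute")
      res <- tryCatch(correlation_screen(x, d, threshold),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m$name, anchor = a$name,
        n = if (is.null(res)) sum(!is.na(x) & !is.na(d)) else res$n,
        r = if (is.null(res)) NA_real_ else res$r,
        passed = if (is.null(res)) FALSE else res$passed,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(metric = character(), anchor = character(),
                      n = integer(), r = numeric(), passed = logical()))
  }
  do.call(rbind, rows)
}

#' @export
print.mid_screen <- function(x, ...) {
  cat(sprintf("<screen: r = %.3f on n = %d pairs -> %s (|r| > %.2f)>\n",
              x$r, x$n, ifelse(x$passed, "PASS", "fail"), x$threshold))
  invisible(x)
}
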