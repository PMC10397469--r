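# MID estimators. Sign convention used throughout: improvement MIDs carry the
# sign of beneficial change for the metric (positive for a metric whose
# increase is benefit, negative otherwise); worsening MIDs carry the opposite
# sign. Anchor-based estimators keep their empirical sign, which coincides
# with the convention whenever the planted/observed effect is in the expected
# direction.

.mid_methods <- c("half_sd", "mdc", "change_difference", "glm_regression")
.anchor_based <- c("change_difference", "glm_regression")

.direction_sign <- function(direction, metric = NULL) {
  d <- if (is.null(metric)) 1L else metric$direction_of_benefit
  if (direction == "improvement") d else -d
}

.new_mid_estimate <- function(method, direction, value, sem = NA_real_,
                              n_improved = NA_integer_, n_stable = NA_integer_,
                              n_worsened = NA_integer_, floored = FALSE) {
  structure(
    list(method = method, direction = direction, value = value, sem = sem,
         n_improved = n_improved, n_stable = n_stable,
         n_worsened = n_worsened, floored = floored),
    class = "mid_estimate"
  )
}

#' @export
print.mid_estimate <- function(x, ...) {
  cat(sprintf("<MID %s/%s: %.4g%s%s>\n", x$method, x$direction, x$value,
              if (is.finite(x$sem)) sprintf(" (sem %.4g)", x$sem) else "",
              if (isTRUE(x$floored)) " [floored at sem]" else ""))
  invisible(x)
}

#' Half-standard-deviation MID
#'
#' Distribution-based estimator: half the sample standard deviation
#' (n - 1 denominator) of the change scores within the patient group that
#' changed in the requested direction (improved group for improvement MIDs,
#' worsened group for worsening MIDs).
#'
#' @param changes Change scores of the relevant patient group (metric units).
#' @param direction `"improvement"` or `"worsening"`.
#' @param metric Optional [metric_definition()] used to orient the sign of the
#'   estimate; without it the magnitude is returned with the conventional
#'   `+` / `-` sign for improvement / worsening.
#' @return A `mid_estimate`.
#' @examples
#' half_sd_mid(c(-4, -2, 0, 2, 4), "improvement")$value  # 0.5 * sqrt(10)
#' @export
half_sd_mid <- function(changes, direction = c("improvement", "worsening"),
                        metric = NULL) {
  direction <- match.arg(direction)
  changes <- changes[!is.na(changes)]
  if (length(changes) < 2L) {
    stop("half_sd_mid needs at least 2 patients in the ", direction, " group")
  }
  mag <- 0.5 * sd(changes)
  .new_mid_estimate("half_sd", direction,
                    value = mag * .direction_sign(direction, metric))
}

#' Minimal detectable change (MDC) MID
#'
#' Distribution-based estimator built on the standard error of measurement
#' (SEM): `sem = sd_change * sqrt(1 - icc)` and `MDC = 1.96 * sqrt(2) * sem`,
#' the smallest change distinguishable from measurement error at 95%
#' confidence for a test-retest design.
#'
#' @param sd_change Standard deviation of the change scores (metric units) of
#'   all patients contributing to the anchor analysis.
#' @param icc Test-retest reliability coefficient in `[0, 1]`.
#' @inheritParams half_sd_mid
#' @return A `mid_estimate` with the SEM recorded in `$sem`.
#' @examples
#' est <- mdc_mid(10, 0.96)
#' est$sem    # 2.0
#' est$value  # 5.5437
#' @export
mdc_mid <- function(sd_change, icc, direction = c("improvement", "worsening"),
                    metric = NULL) {
  direction <- match.arg(direction)
  if (!is.numeric(icc) || length(icc) != 1L || is.na(icc) ||
      icc < 0 || icc > 1) {
    stop("icc must be a single value in [0, 1]")
  }
  if (!is.numeric(sd_change) || sd_change < 0) {
    stop("sd_change must be non-negative")
  }
  sem <- sd_change * sqrt(1 - icc)
  mag <- 1.96 * sqrt(2) * sem
  .new_mid_estimate("mdc", direction,
                    value = mag * .direction_sign(direction, metric),
                    sem = sem)
}

# Map a label factor to its contrast/reference groups for a direction.
.contrast_groups <- function(labels, direction) {
  lv <- levels(labels)
  if (all(c("improved", "stable", "worsened") %in% lv)) {
    contrast <- if (direction == "improvement") "improved" else "worsened"
    list(contrast = contrast, reference = "stable", kind = "change_threshold")
  } else if (all(c("survivor", "non_survivor") %in% lv)) {
    if (direction == "improvement") {
      stop("improvement MID is not defined for a survival anchor ",
           "(no improved mortality group exists)")
    }
    list(contrast = "non_survivor", reference = "survivor",
         kind = "binary_survival")
  } else {
    stop("labels must use improved/stable/worsened or survivor/non_survivor")
  }
}

.group_counts <- function(labels) {
  tab <- table(labels)
  if (all(c("improved", "stable", "worsened") %in% names(tab))) {
    c(n_improved = unname(tab["improved"]), n_stable = unname(tab["stable"]),
      n_worsened = unname(tab["worsened"]))
  } else {
    c(n_improved = NA_integer_, n_stable = unname(tab["survivor"]),
      n_worsened = unname(tab["non_survivor"]))
  }
}

#' Change-difference MID
#'
#' Anchor-based estimator: the mean change in the patients who changed
#' (improved or worsened per the anchor; non-survivors for a survival anchor)
#' minus the mean change in the reference group (stable patients; survivors).
#' Subtracting the reference mean adjusts the changed group's change for the
#' drift observed in patients the anchor calls unchanged.
#'
#' @param changes Per-patient change scores (metric units).
#' @param labels Factor from [classify_by_anchor()] or
#'   [classify_by_survival()], aligned with `changes`.
#' @inheritParams half_sd_mid
#' @return A `mid_estimate` with group counts recorded.
#' @examples
#' ch <- c(10, 12, 8, 7, 9, 8, -5, -5)
#' lab <- factor(rep(c("improved", "stable", "worsened"), c(3, 3, 2)),
#'               levels = c("improved", "stable", "worsened"))
#' change_difference_mid(ch, lab, "improvement")$value  # 2
#' @export
change_difference_mid <- function(changes, labels,
                                  direction = c("improvement", "worsening")) {
  direction <- match.arg(direction)
  grp <- .contrast_groups(labels, direction)
  ok <- !is.na(changes) & !is.na(labels)
  changes <- changes[ok]
  labels <- labels[ok]
  xc <- changes[labels == grp$contrast]
  xr <- changes[labels == grp$reference]
  if (length(xc) < 2L || length(xr) < 2L) {
    stop(sprintf("group too small for change difference (%s n=%d, %s n=%d)",
                 grp$contrast, length(xc), grp$reference, length(xr)))
  }
  cnt <- .group_counts(labels)
  .new_mid_estimate("change_difference", direction,
                    value = mean(xc) - mean(xr),
                    n_improved = cnt[["n_improved"]],
                    n_stable = cnt[["n_stable"]],
                    n_worsened = cnt[["n_worsened"]])
}

#' Regression MID from a dummy-coded linear model
#'
#' Anchor-based estimator: an identity-link least-squares fit of the change
#' score on dummy indicators of anchor status with the stable (or survivor)
#' group as the reference level. The intercept `k` is then the reference
#' group's mean change, and the improvement / worsening coefficients are the
#' incremental mean change of the improved / worsened groups relative to the
#' reference -- algebraically identical to [change_difference_mid()], which
#' serves as an independent cross-check in the test suite. A printed
#' formulation with separate indicators for all three groups plus an
#' intercept is rank-deficient; absorbing the stable indicator into the
#' intercept is the estimable parameterisation of the same model.
#'
#' @inheritParams change_difference_mid
#' @return An object of class `mid_glm`: list with the intercept `k`,
#'   coefficients `beta_better` / `beta_worse`, and `mid_estimate`s
#'   `$improvement` and `$worsening` (`$improvement` is `NULL` for a survival
#'   anchor).
#' @export
glm_regression_mid <- function(changes, labels) {
  ok <- !is.na(changes) & !is.na(labels)
  changes <- changes[ok]
  labels <- labels[ok]
  lv <- levels(labels)
  survival_mode <- all(c("survivor", "non_survivor") %in% lv)
  if (survival_mode) {
    ref_levels <- c("survivor", "non_survivor")
  } else if (all(c("improved", "stable", "worsened") %in% lv)) {
    ref_levels <- c("stable", "improved", "worsened")
  } else {
    stop("labels must use improved/stable/worsened or survivor/non_survivor")
  }
  tab <- table(factor(labels, levels = ref_levels))
  if (any(tab < 2L)) {
    stop("every anchor class needs at least 2 patients for the regression (",
         paste(sprintf("%s n=%d", names(tab), as.integer(tab)),
               collapse = ", "), ")")
  }
  fit <- lm(changes ~ status,
            data = data.frame(changes = changes,
                              status = factor(labels, levels = ref_levels)))
  cf <- coef(fit)
  k <- unname(cf["(Intercept)"])
  cnt <- .group_counts(labels)
  if (survival_mode) {
    bw <- unname(cf["statusnon_survivor"])
    out <- list(k = k, beta_better = NA_real_, beta_worse = bw,
                improvement = NULL,
                worsening = .new_mid_estimate("glm_regression", "worsening",
                                              value = bw,
                                              n_improved = cnt[["n_improved"]],
                                              n_stable = cnt[["n_stable"]],
                                              n_worsened = cnt[["n_worsened"]]))
  } else {
    bb <- unname(cf["statusimproved"])
    bw <- unname(cf["statusworsened"])
    out <- list(k = k, beta_better = bb, beta_worse = bw,
                improvement = .new_mid_estimate("glm_regression",
                                                "improvement", value = bb,
                                                n_improved = cnt[["n_improved"]],
                                                n_stable = cnt[["n_stable"]],
                                                n_worsened = cnt[["n_worsened"]]),
                worsening = .new_mid_estimate("glm_regression", "worsening",
                                              value = bw,
                                              n_improved = cnt[["n_improved"]],
                                              n_stable = cnt[["n_stable"]],
                                              n_worsened = cnt[["n_worsened"]]))
  }
  class(out) <- "mid_glm"
  out
}

#' Floor an anchor-based MID at the standard error of measurement
#'
#' An anchor-based MID smaller in magnitude than the SEM is indistinguishable
#' from measurement error; in that case the SEM itself is used as the MID.
#' The inequality is strict: an estimate exactly equal to the SEM is left
#' unfloored. Distribution-based estimates are never floored (the rule exists
#' to keep anchor-based estimates out of the measurement-noise band) and
#' passing one is an error.
#'
#' @param estimate A `mid_estimate` from an anchor-based method.
#' @param sem Standard error of measurement (metric units, non-negative).
#' @param fallback_sign Sign given to a floored zero-valued estimate
#'   (conventionally the direction sign of the metric).
#' @return The estimate, floored if needed, with `$sem` recorded and
#'   `$floored` set.
#' @examples
#' est <- change_difference_mid(
#'   c(1.0, 1.4, 0, 0.2, -0.4, -3, -2),
#'   factor(rep(c("improved", "stable", "worsened"), c(2, 3, 2)),
#'          levels = c("improved", "stable", "worsened")), "improvement")
#' apply_sem_floor(est, sem = 2)$value  # floored to 2
#' @export
apply_sem_floor <- function(estimate, sem, fallback_sign = 1) {
  if (!inherits(estimate, "mid_estimate")) {
    stop("estimate must be a mid_estimate")
  }
  if (!estimate$method %in% .anchor_based) {
    stop("the SEM floor applies to anchor-based MIDs only (got method '",
         estimate$method, "')")
  }
  if (!is.numeric(sem) || length(sem) != 1L || is.na(sem) || sem < 0) {
    stop("sem must be a single non-negative value")
  }
  estimate$sem <- sem
  if (is.finite(estimate$value) && abs(estimate$value) < sem) {
    s <- if (estimate$value == 0) sign(fallback_sign) else sign(estimate$value)
    estimate$value <- s * sem
    estimate$floored <- TRUE
  }
  estimate
}

# One output row of the long MID table.
.mid_row <- function(metric, anchor, scale, method, direction,
                     value = NA_real_, sem = NA_real_, floored = NA,
                     counts = c(n_improved = NA_integer_,
                                n_stable = NA_integer_,
                                n_worsened = NA_integer_),
                     n_total = NA_integer_, r = NA_real_,
                     status = "ok", note = NA_character_) {
  data.frame(metric = metric$name, units = metric$units, anchor = anchor$name,
             method = method, direction = direction, scale = scale,
             value = value, sem = sem, floored = floored,
             n_improved = as.integer(counts[["n_improved"]]),
             n_stable = as.integer(counts[["n_stable"]]),
             n_worsened = as.integer(counts[["n_worsened"]]),
             n_total = as.integer(n_total), r = r,
             status = status, note = note, stringsAsFactors = FALSE)
}

.row_from_estimate <- function(est, metric, anchor, scale, n_total, r) {
  .mid_row(metric, anchor, scale, est$method, est$direction,
           value = est$value, sem = est$sem, floored = est$floored,
           counts = c(n_improved = est$n_improved, n_stable = est$n_stable,
                      n_worsened = est$n_worsened),
           n_total = n_total, r = r)
}

#' Estimate all MIDs for a cohort
#'
#' Orchestrates the four estimators over every screened-in metric x anchor
#' combination, for both directions (improvement, worsening) and both change
#' scales (absolute, relative to baseline). Change-threshold anchors are
#' admitted per metric by the correlation screen; the survival anchor is
#' admitted for any metric that passes the screen against at least one
#' change-threshold anchor (a binary status has no change score of its own to
#' correlate). Anchor-based estimates are floored at the standard error of
#' measurement computed from the change scores of all patients contributing
#' to that anchor's analysis. Estimator failures in one cell (e.g. a group
#' smaller than 2) are reported as `status = "error"` rows and do not abort
#' other cells.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param metrics Named list of [metric_definition()]s.
#' @param anchors Named list of [anchor_definition()]s.
#' @param screen Optional precomputed result of [screen_anchors()]; computed
#'   from the cohort when `NULL`.
#' @param screen_threshold Correlation screen threshold on `|r|`.
#' @param floor Apply the SEM floor to anchor-based estimates (default TRUE).
#' @return Long-format data frame, one row per metric x anchor x method x
#'   direction x scale, with columns `metric`, `units`, `anchor`, `method`,
#'   `direction`, `scale`, `value`, `sem`, `floored`, `n_improved`,
#'   `n_stable`, `n_worsened`, `n_total`, `r`, `status`, `note`. Screened-out
#'   metric-anchor pairs carry a single `status = "screened_out"` row;
#'   improvement cells of the survival anchor are `status = "not_defined"`.
#'   The screen table is attached as attribute `screen`.
#' @export
estimate_all <- function(cohort, metrics, anchors, screen = NULL,
                         screen_threshold = 0.20, floor = TRUE) {
  if (is.null(screen)) {
    screen <- screen_anchors(cohort, metrics, anchors, screen_threshold)
  }
  rows <- list()
  add <- function(x) rows[[length(rows) + 1L]] <<- x

  for (anchor in anchors) {
    if (anchor$kind == "change_threshold") {
      d <- anchor_changes(cohort, anchor)
      lab_full <- classify_by_anchor(d, anchor)
      directions <- c("improvement", "worsening")
    } else {
      lab_full <- classify_by_survival(cohort)
      directions <- "worsening"
    }

    for (metric in metrics) {
      if (anchor$kind == "change_threshold") {
        srow <- screen[screen$metric == metric$name &
                         screen$anchor == anchor$name, , drop = FALSE]
        passed <- nrow(srow) == 1L && isTRUE(srow$passed)
        r <- if (nrow(srow) == 1L) srow$r else NA_real_
      } else {
        mine <- screen[screen$metric == metric$name, , drop = FALSE]
        passed <- nrow(mine) == 0L || any(mine$passed)
        r <- NA_real_
      }
      if (!passed) {
        add(.mid_row(metric, anchor, "absolute", NA_character_,
                     NA_character_, r = r, status = "screened_out",
                     note = sprintf("|r| <= %.2f against this anchor",
                                    screen_threshold)))
        next
      }

      for (scale in c("absolute", "relative")) {
        x_full <- .metric_changes(cohort, metric, scale)
        ok <- !is.na(x_full) & !is.na(lab_full)
        x <- x_full[ok]
        lab <- factor(lab_full[ok], levels = levels(lab_full))
        n_total <- length(x)
        cnt <- .group_counts(lab)
        if (n_total < 3L) {
          add(.mid_row(metric, anchor, scale, NA_character_, NA_character_,
                       counts = cnt, n_total = n_total, r = r,
                       status = "error",
                       note = "too few complete pairs for this anchor"))
          next
        }
        sem <- sd(x) * sqrt(1 - metric$icc)

        glm_fit <- tryCatch(glm_regression_mid(x, lab), error = identity)

        for (direction in directions) {
          fsign <- .direction_sign(direction, metric)

          # half_sd on the direction's changed group
          grp <- if (anchor$kind == "change_threshold") {
            if (direction == "improvement") "improved" else "worsened"
          } else "non_survivor"
          est <- tryCatch(
            half_sd_mid(x[lab == grp], direction, metric),
            error = identity)
          if (inherits(est, "condition")) {
            add(.mid_row(metric, anchor, scale, "half_sd", direction,
                         counts = cnt, n_total = n_total, r = r,
                         status = "error", note = conditionMessage(est)))
          } else {
            est$n_improved <- cnt[["n_improved"]]
            est$n_stable <- cnt[["n_stable"]]
            est$n_worsened <- cnt[["n_worsened"]]
            add(.row_from_estimate(est, metric, anchor, scale, n_total, r))
          }

          # mdc on the change sd of the full anchored sample
          est <- mdc_mid(sd(x), metric$icc, direction, metric)
          est$n_improved <- cnt[["n_improved"]]
          est$n_stable <- cnt[["n_stable"]]
          est$n_worsened <- cnt[["n_worsened"]]
          add(.row_from_estimate(est, metric, anchor, scale, n_total, r))

          # change difference, floored
          est <- tryCatch(change_difference_mid(x, lab, direction),
                          error = identity)
          if (inherits(est, "condition")) {
            add(.mid_row(metric, anchor, scale, "change_difference",
                         direction, counts = cnt, n_total = n_total, r = r,
                         status = "error", note = conditionMessage(est)))
          } else {
            if (floor) est <- apply_sem_floor(est, sem, fsign)
            add(.row_from_estimate(est, metric, anchor, scale, n_total, r))
          }

          # glm regression, floored
          if (inherits(glm_fit, "condition")) {
            add(.mid_row(metric, anchor, scale, "glm_regression", direction,
                         counts = cnt, n_total = n_total, r = r,
                         status = "error",
                         note = conditionMessage(glm_fit)))
          } else {
            est <- glm_fit[[direction]]
            if (floor) est <- apply_sem_floor(est, sem, fsign)
            add(.row_from_estimate(est, metric, anchor, scale, n_total, r))
          }
        }

        if (anchor$kind == "binary_survival") {
          for (method in .mid_methods) {
            add(.mid_row(metric, anchor, scale, method, "improvement",
                         counts = cnt, n_total = n_total, r = r,
                         status = "not_defined",
                         note = "no improved mortality group exists"))
          }
        }
      }
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "screen") <- screen
  out
}
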