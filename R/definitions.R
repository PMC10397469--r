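#' Define a continuous outcome metric
#'
#' A metric is a continuous measurement taken at baseline and follow-up
#' (for example right ventricular ejection fraction from cardiac MRI).
#' The direction of benefit states whether an increase (+1, e.g. RVEF)
#' or a decrease (-1, e.g. RV volumes) represents clinical improvement;
#' the intraclass correlation coefficient (ICC) is the metric's test-retest
#' reliability, used by the minimal-detectable-change estimator and the
#' measurement-error floor.
#'
#' @param name Identifier used in cohort column names (`<name>_baseline`,
#'   `<name>_followup`).
#' @param units Unit label carried into every output row (e.g. `"%"`, `"mL"`).
#' @param direction_of_benefit `+1` if an increase is improvement, `-1` if a
#'   decrease is improvement.
#' @param icc Test-retest reliability coefficient in `[0, 1]`.
#' @param label Human-readable label (defaults to `name`).
#' @return An object of class `mid_metric`.
#' @examples
#' metric_definition("rvef", "%", +1, icc = 0.94, label = "RVEF")
#' @export
metric_definition <- function(name, units, direction_of_benefit, icc,
                              label = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  direction_of_benefit <- as.integer(direction_of_benefit)
  if (!direction_of_benefit %in% c(-1L, 1L)) {
    stop("direction_of_benefit must be +1 or -1 for metric '", name, "'")
  }
  if (!is.numeric(icc) || length(icc) != 1L || is.na(icc) ||
      icc < 0 || icc > 1) {
    stop("icc must be a single value in [0, 1] for metric '", name, "'")
  }
  structure(
    list(name = name, units = units,
         direction_of_benefit = direction_of_benefit,
         icc = as.numeric(icc), label = label),
    class = "mid_metric"
  )
}

#' Define an external anchor of patient change
#'
#' An anchor is an external criterion against which change in a metric is
#' benchmarked. Two kinds are supported: `change_threshold` anchors classify
#' patients as improved / stable / worsened from the change in a score
#' (emPHasis-10 quality of life, incremental shuttle walk test distance),
#' and `binary_survival` anchors contrast survivors with non-survivors of
#' the year following the follow-up measurement.
#'
#' @param name Identifier used in cohort column names
#'   (`<name>_baseline`, `<name>_followup`) for `change_threshold` anchors.
#' @param kind `"change_threshold"` or `"binary_survival"`.
#' @param threshold Positive magnitude of anchor change (in anchor units)
#'   regarded as a meaningful change; e.g. 6 points for emPHasis-10 or
#'   47.5 m for the shuttle walk test. Must be `NULL` for `binary_survival`.
#' @param improvement_sign Sign of anchor change that means improvement:
#'   `-1` for emPHasis-10 (lower is better), `+1` for walk distance.
#' @param label Human-readable label.
#' @return An object of class `mid_anchor`.
#' @examples
#' anchor_definition("e10", "change_threshold", threshold = 6,
#'                   improvement_sign = -1, label = "emPHasis-10")
#' @export
anchor_definition <- function(name,
                              kind = c("change_threshold", "binary_survival"),
                              threshold = NULL, improvement_sign = NULL,
                              label = name) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "change_threshold") {
    if (is.null(threshold) || !is.numeric(threshold) || threshold <= 0) {
      stop("a change_threshold anchor needs a positive threshold ('",
           name, "')")
    }
    improvement_sign <- as.integer(improvement_sign)
    if (!improvement_sign %in% c(-1L, 1L)) {
      stop("improvement_sign must be +1 or -1 for anchor '", name, "'")
    }
  } else {
    if (!is.null(threshold)) {
      stop("threshold is undefined for a binary_survival anchor ('",
           name, "')")
    }
    improvement_sign <- NA_integer_
  }
  structure(
    list(name = name, kind = kind,
         threshold = if (kind == "change_threshold") as.numeric(threshold),
         improvement_sign = improvement_sign, label = label),
    class = "mid_anchor"
  )
}

#' Default cardiac-MRI metric set
#'
#' Right ventricular ejection fraction and volumes with test-retest ICCs
#' typical of automated CMR segmentation. All values can be overridden via
#' [metric_definition()] or a YAML config ([read_metric_config()]).
#'
#' @return Named list of `mid_metric` objects.
#' @export
default_metrics <- function() {
  list(
    rvef  = metric_definition("rvef",  "%",  +1, icc = 0.94, label = "RVEF"),
    rvedv = metric_definition("rvedv", "mL", -1, icc = 0.98, label = "RVEDV"),
    rvesv = metric_definition("rvesv", "mL", -1, icc = 0.97, label = "RVESV"),
    rvsv  = metric_definition("rvsv",  "mL", +1, icc = 0.90, label = "RVSV")
  )
}

#' Default anchor set
#'
#' emPHasis-10 (6-point threshold, lower is better), incremental shuttle walk
#' test (47.5 m threshold, higher is better) and 1-year survival.
#'
#' @return Named list of `mid_anchor` objects.
#' @export
default_anchors <- function() {
  list(
    e10 = anchor_definition("e10", "change_threshold", threshold = 6,
                            improvement_sign = -1, label = "emPHasis-10"),
    iswt = anchor_definition("iswt", "change_threshold", threshold = 47.5,
                             improvement_sign = +1, label = "ISWT"),
    survival = anchor_definition("survival", "binary_survival",
                                 label = "1-year survival")
  )
}

#' Read metric and anchor definitions from a YAML config file
#'
#' The file has two top-level maps, `metrics` and `anchors`, keyed by
#' identifier; see `system.file("extdata", "metrics.yaml", package = "midkit")`
#' for the expected layout.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `metrics` and `anchors`, each a named list of
#'   definitions.
#' @export
read_metric_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$metrics)) stop("config file has no 'metrics' section")
  metrics <- lapply(names(cfg$metrics), function(nm) {
    m <- cfg$metrics[[nm]]
    metric_definition(nm, units = m$units,
                      direction_of_benefit = m$direction_of_benefit,
                      icc = m$icc, label = m$label %||% nm)
  })
  names(metrics) <- names(cfg$metrics)
  anchors <- lapply(names(cfg$anchors %||% list()), function(nm) {
    a <- cfg$anchors[[nm]]
    anchor_definition(nm, kind = a$kind, threshold = a$threshold,
                      improvement_sign = a$improvement_sign,
                      label = a$label %||% nm)
  })
  names(anchors) <- names(cfg$anchors %||% list())
  list(metrics = metrics, anchors = anchors)
}

#' @export
print.mid_metric <- function(x, ...) {
  cat(sprintf("<metric %s [%s], benefit %s, ICC %.2f>\n", x$name, x$units,
              ifelse(x$direction_of_benefit > 0, "increase", "decrease"),
              x$icc))
  invisible(x)
}

#' @export
print.mid_anchor <- function(x, ...) {
  if (x$kind == "change_threshold") {
    cat(sprintf("<anchor %s: |change| >= %g, improvement sign %+d>\n",
                x$name, x$threshold, x$improvement_sign))
  } else {
    cat(sprintf("<anchor %s: binary 1-year survival>\n", x$name))
  }
  invisible(x)
}
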