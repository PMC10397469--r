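#' Read a paired cohort CSV
#'
#' One row per patient. Expected columns: `patient_id`,
#' `<metric>_baseline` / `<metric>_followup` for each metric,
#' `<anchor>_baseline` / `<anchor>_followup` for each change-threshold anchor,
#' and `survived_1yr` (0/1). Empty cells are missing values; patients with a
#' missing anchor timepoint are excluded pairwise from that anchor's analysis.
#'
#' @param path CSV file path.
#' @param metrics,anchors Optional named lists of definitions; when supplied,
#'   the presence of the corresponding columns is checked.
#' @return A data frame.
#' @export
read_cohort <- function(path, metrics = NULL, anchors = NULL) {
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(cohort)) {
    stop("cohort file must have a 'patient_id' column")
  }
  if (anyDuplicated(cohort$patient_id)) {
    stop("patient_id values must be unique")
  }
  need <- character(0)
  for (m in metrics) {
    need <- c(need, paste0(m$name, c("_baseline", "_followup")))
  }
  for (a in anchors) {
    if (a$kind == "change_threshold") {
      need <- c(need, paste0(a$name, c("_baseline", "_followup")))
    } else {
      need <- c(need, "survived_1yr")
    }
  }
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort file is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  cohort
}

# Full-length change vector for a metric (NA where a timepoint is missing or,
# on the relative scale, where baseline = 0).
.metric_changes <- function(cohort, metric, scale = c("absolute", "relative")) {
  scale <- match.arg(scale)
  b <- cohort[[paste0(metric$name, "_baseline")]]
  f <- cohort[[paste0(metric$name, "_followup")]]
  if (is.null(b) || is.null(f)) {
    stop("cohort has no baseline/follow-up columns for metric '",
         metric$name, "'")
  }
  ab <- f - b
  if (scale == "absolute") ab else ifelse(!is.na(b) & b == 0, NA_real_, ab / b)
}

#' Per-patient change scores for one metric
#'
#' The absolute change is follow-up minus baseline; the relative change is the
#' absolute change divided by the baseline value. A zero baseline leaves the
#' relative change undefined (flagged via `relative_defined`, never silently
#' zero). Patients missing either timepoint are excluded; the excluded count
#' is attached as attribute `n_excluded`.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param metric A [metric_definition()].
#' @return Data frame with columns `patient_id`, `baseline`, `followup`,
#'   `absolute_change`, `relative_change`, `relative_defined`, in the input
#'   patient order.
#' @examples
#' coh <- data.frame(patient_id = "P1", rvedv_baseline = 208,
#'                   rvedv_followup = 182)
#' compute_changes(coh, metric_definition("rvedv", "mL", -1, 0.98))
#' @export
compute_changes <- function(cohort, metric) {
  b <- cohort[[paste0(metric$name, "_baseline")]]
  f <- cohort[[paste0(metric$name, "_followup")]]
  if (is.null(b) || is.null(f)) {
    stop("cohort has no baseline/follow-up columns for metric '",
         metric$name, "'")
  }
  complete <- !is.na(b) & !is.na(f)
  out <- data.frame(
    patient_id = cohort$patient_id[complete],
    baseline = b[complete],
    followup = f[complete],
    absolute_change = f[complete] - b[complete],
    stringsAsFactors = FALSE
  )
  out$relative_defined <- out$baseline != 0
  out$relative_change <- ifelse(out$relative_defined,
                                out$absolute_change / out$baseline, NA_real_)
  attr(out, "n_excluded") <- sum(!complete)
  out
}

#' Anchor change scores
#'
#' Signed change (follow-up minus baseline) in a change-threshold anchor's
#' score; `NA` where either timepoint is missing.
#'
#' @param cohort Cohort data frame.
#' @param anchor A change-threshold [anchor_definition()].
#' @return Numeric vector, one element per cohort row.
#' @export
anchor_changes <- function(cohort, anchor) {
  if (anchor$kind != "change_threshold") {
    stop("anchor_changes() is defined only for change_threshold anchors")
  }
  b <- cohort[[paste0(anchor$name, "_baseline")]]
  f <- cohort[[paste0(anchor$name, "_followup")]]
  if (is.null(b) || is.null(f)) {
    stop("cohort has no baseline/follow-up columns for anchor '",
         anchor$name, "'")
  }
  f - b
}

#' Classify patients by a change-threshold anchor
#'
#' A patient is improved when the anchor change, oriented by the anchor's
#' improvement sign, is at least the threshold; worsened when it is at most
#' minus the threshold; stable otherwise. A change whose magnitude equals the
#' threshold exactly counts as changed, because the threshold is itself the
#' minimal important change for the anchor instrument. Missing changes yield
#' `NA` labels; the count is attached as attribute `n_excluded`.
#'
#' @param changes Per-patient anchor change scores (anchor units).
#' @param anchor A change-threshold [anchor_definition()].
#' @return Factor with levels `improved`, `stable`, `worsened` (NA where the
#'   change is missing).
#' @examples
#' e10 <- anchor_definition("e10", "change_threshold", 6, -1)
#' classify_by_anchor(c(-16, 0, 13), e10)
#' @export
classify_by_anchor <- function(changes, anchor) {
  if (anchor$kind != "change_threshold") {
    stop("classify_by_anchor() requires a change_threshold anchor")
  }
  oriented <- changes * anchor$improvement_sign
  lab <- rep(NA_character_, length(changes))
  lab[!is.na(oriented) & oriented >= anchor$threshold] <- "improved"
  lab[!is.na(oriented) & oriented <= -anchor$threshold] <- "worsened"
  lab[!is.na(oriented) & abs(oriented) < anchor$threshold] <- "stable"
  out <- factor(lab, levels = c("improved", "stable", "worsened"))
  attr(out, "n_excluded") <- sum(is.na(changes))
  out
}

#' Classify patients by 1-year survival
#'
#' @param cohort Cohort data frame with a complete `survived_1yr` column
#'   (0/1 or logical).
#' @return Factor with levels `survivor`, `non_survivor`.
#' @export
classify_by_survival <- function(cohort) {
  s <- cohort$survived_1yr
  if (is.null(s)) stop("cohort has no 'survived_1yr' column")
  if (anyNA(s)) stop("survived_1yr must be recorded for all patients")
  factor(ifelse(as.logical(s), "survivor", "non_survivor"),
         levels = c("survivor", "non_survivor"))
}
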