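# Shared helpers for the midkit test suite. Oracles here are deliberately
# independent of the implementation paths they check.

# Two-way consistency ICC for two replicate measurements (ICC(C,1) via the
# standard ANOVA mean squares), used as the oracle for the generator's
# reliability calibration.
icc_consistency <- function(m1, m2) {
  x <- cbind(m1, m2)
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  sse <- sum((x - grand)^2) - msr * (n - 1) - msc * (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

# Random three-class label factor with at least `min_per` patients per class.
rand_labels <- function(n, min_per = 2L) {
  stopifnot(n >= 3L * min_per)
  repeat {
    lab <- sample(c("improved", "stable", "worsened"), n, replace = TRUE)
    if (all(table(factor(lab, levels = c("improved", "stable", "worsened")))
            >= min_per)) {
      return(factor(lab, levels = c("improved", "stable", "worsened")))
    }
  }
}

# Small deterministic cohort for cohort-model unit tests.
tiny_cohort <- function() {
  data.frame(
    patient_id = paste0("P", 1:6),
    rvedv_baseline = c(208, 100, 0, 150, NA, 180),
    rvedv_followup = c(182, 100, 5, 160, 170, NA),
    e10_baseline = c(37, 29, 24, 30, NA, 31),
    e10_followup = c(21, 29, 37, 24, 20, NA),
    survived_1yr = c(1, 1, 0, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

test_metric <- function(direction = +1, icc = 0.95) {
  metric_definition("m", "u", direction, icc)
}

e10_anchor <- function() {
  anchor_definition("e10", "change_threshold", threshold = 6,
                    improvement_sign = -1)
}

iswt_anchor <- function() {
  anchor_definition("iswt", "change_threshold", threshold = 47.5,
                    improvement_sign = +1)
}
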