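# Synthetic paired-cohort generator. The generative model, per patient:
#   1. a latent status class (improved / stable / worsened) is drawn from the
#      mixture;
#   2. each change-threshold anchor's change score is drawn from a Gaussian
#      truncated to the class's threshold region, so the anchor-defined group
#      coincides exactly with the generative class (the study groups are
#      themselves defined by the observed anchor change, so the
#      class-conditional change distribution is supported on the class region
#      by construction);
#   3. each metric's true change is Gaussian around its class mean, coupled
#      to the anchors through a Gaussian copula whose coefficients are
#      calibrated so the population metric-anchor change correlation equals
#      the configured target;
#   4. observed baseline and follow-up add i.i.d. measurement error sized so
#      the metric's test-retest reliability equals the configured ICC;
#   5. 1-year survival is Bernoulli with a class-specific death probability.

.CLASSES <- c("improved", "stable", "worsened")

.named3 <- function(x, what) {
  if (length(x) == 1L) x <- rep(x, 3L)
  if (length(x) != 3L) {
    stop(what, " must have length 1 or 3 (improved, stable, worsened)")
  }
  names(x) <- .CLASSES
  x
}

#' Configure one simulated metric
#'
#' @param definition A [metric_definition()].
#' @param baseline_mean,baseline_sd Moments of the observed baseline value.
#' @param class_mean_change Length-3 vector of mean true change in the
#'   improved, stable and worsened classes (metric units).
#' @param change_sd SD of the true change within class (length 1 or 3).
#' @param target_r Named vector of target population correlations between
#'   this metric's observed change and each anchor's change, one entry per
#'   change-threshold anchor.
#' @return A list consumed by [simulation_config()].
#' @export
sim_metric <- function(definition, baseline_mean, baseline_sd,
                       class_mean_change, change_sd, target_r) {
  stopifnot(inherits(definition, "mid_metric"))
  class_mean_change <- .named3(class_mean_change, "class_mean_change")
  change_sd <- .named3(change_sd, "change_sd")
  if (any(change_sd < 0) || baseline_sd < 0) {
    stop("standard deviations must be non-negative (metric '",
         definition$name, "')")
  }
  if (is.null(names(target_r)) || any(!nzchar(names(target_r)))) {
    stop("target_r must be a named vector (anchor names) for metric '",
         definition$name, "'")
  }
  if (any(abs(target_r) >= 1)) stop("target correlations must be in (-1, 1)")
  list(definition = definition, baseline_mean = baseline_mean,
       baseline_sd = baseline_sd, class_mean_change = class_mean_change,
       change_sd = change_sd, target_r = target_r)
}

#' Configure one simulated change-threshold anchor
#'
#' @param definition A change-threshold [anchor_definition()].
#' @param baseline_mean,baseline_sd Moments of the baseline anchor score.
#' @param class_mean_change Length-3 vector: mean of the parent Gaussian of
#'   the anchor change in each class (truncated to the class region when
#'   sampling).
#' @param change_sd SD of the parent Gaussian of the anchor change.
#' @param missing_frac Fraction of patients with the anchor unobserved at
#'   both timepoints (class-independent attrition).
#' @return A list consumed by [simulation_config()].
#' @export
sim_anchor <- function(definition, baseline_mean, baseline_sd,
                       class_mean_change, change_sd, missing_frac = 0) {
  stopifnot(inherits(definition, "mid_anchor"))
  if (definition$kind != "change_threshold") {
    stop("only change_threshold anchors are configured with sim_anchor(); ",
         "survival is simulated from the class-specific death probabilities")
  }
  class_mean_change <- .named3(class_mean_change, "class_mean_change")
  if (change_sd <= 0 || baseline_sd < 0) {
    stop("anchor change_sd must be positive ('", definition$name, "')")
  }
  if (missing_frac < 0 || missing_frac >= 1) {
    stop("missing_frac must be in [0, 1)")
  }
  list(definition = definition, baseline_mean = baseline_mean,
       baseline_sd = baseline_sd, class_mean_change = class_mean_change,
       change_sd = change_sd, missing_frac = missing_frac)
}

#' Build a simulation configuration
#'
#' @param n_patients Cohort size.
#' @param mixture Length-3 class probabilities (improved, stable, worsened);
#'   must sum to 1 within 1e-12.
#' @param metrics Named list of [sim_metric()]s (names must match the metric
#'   definitions).
#' @param anchors Named list of [sim_anchor()]s.
#' @param death_prob Length-3 class-specific 1-year death probabilities.
#' @param seed Default seed used by [generate_cohort()].
#' @param tails `"gaussian"` (default) or `"t"`: distribution of the metric
#'   change's idiosyncratic component; `"t"` uses a scaled Student-t for a
#'   heavy-tailed robustness variant.
#' @param t_df Degrees of freedom when `tails = "t"` (must exceed 2).
#' @return An object of class `mid_sim_config`.
#' @export
simulation_config <- function(n_patients, mixture, metrics, anchors,
                              death_prob, seed = NULL,
                              tails = c("gaussian", "t"), t_df = 4) {
  tails <- match.arg(tails)
  if (tails == "t" && t_df <= 2) stop("t_df must exceed 2")
  mixture <- .named3(mixture, "mixture")
  if (any(mixture < 0) || any(mixture > 1)) {
    stop("mixture fractions must be probabilities")
  }
  if (abs(sum(mixture) - 1) > 1e-12) stop("mixture must sum to 1")
  death_prob <- .named3(death_prob, "death_prob")
  if (any(death_prob < 0) || any(death_prob > 1)) {
    stop("death probabilities must be in [0, 1]")
  }
  if (is.null(names(metrics)) || is.null(names(anchors))) {
    stop("metrics and anchors must be named lists")
  }
  for (nm in names(metrics)) {
    if (!identical(nm, metrics[[nm]]$definition$name)) {
      stop("metric list name '", nm, "' does not match its definition name")
    }
    unknown <- setdiff(names(metrics[[nm]]$target_r), names(anchors))
    if (length(unknown)) {
      stop("metric '", nm, "' targets unknown anchor(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  for (nm in names(anchors)) {
    if (!identical(nm, anchors[[nm]]$definition$name)) {
      stop("anchor list name '", nm, "' does not match its definition name")
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), mixture = mixture,
         metrics = metrics, anchors = anchors, death_prob = death_prob,
         seed = seed, tails = tails, t_df = t_df),
    class = "mid_sim_config"
  )
}

# Per anchor x class: truncated-change moments and the copula covariance
# gamma = cov(z, change) used by the correlation calibration.
.anchor_class_stats <- function(config) {
  lapply(config$anchors, function(a) {
    out <- lapply(.CLASSES, function(cl) {
      reg <- .class_region(a$definition, cl)
      mu <- a$class_mean_change[[cl]]
      sg <- a$change_sd
      mom <- .tn_moments(mu, sg, reg[1], reg[2])
      mom$gamma <- .tn_gamma(mu, sg, reg[1], reg[2])
      mom$mu <- mu
      mom$sigma <- sg
      mom$lo <- reg[1]
      mom$hi <- reg[2]
      mom
    })
    names(out) <- .CLASSES
    out
  })
}

#' Calibrate copula coefficients to the target correlations
#'
#' Solves, in closed form, for the Gaussian-copula coefficient linking each
#' metric's change to each anchor's (truncated) change so that the population
#' Pearson correlation between the observed changes equals the configured
#' target. The population correlation decomposes into a between-class part
#' (class mean structure, fixed by the config) and a within-class part linear
#' in the copula coefficient; infeasible targets (coefficient outside
#' (-0.99, 0.99), or a metric's coefficients with squared sum above 0.99)
#' raise a validation error before any sampling.
#'
#' @param config A [simulation_config()].
#' @return Matrix of copula coefficients, metrics x anchors.
#' @export
calibrate_correlations <- function(config) {
  astats <- .anchor_class_stats(config)
  pi_ <- config$mixture
  anames <- names(config$anchors)
  mnames <- names(config$metrics)

  a_mean <- a_var <- numeric(length(anames))
  names(a_mean) <- names(a_var) <- anames
  for (e in anames) {
    m <- vapply(astats[[e]], `[[`, numeric(1), "mean")
    v <- vapply(astats[[e]], `[[`, numeric(1), "var")
    a_mean[e] <- sum(pi_ * m)
    a_var[e] <- sum(pi_ * (v + (m - a_mean[e])^2))
  }

  rho <- matrix(0, length(mnames), length(anames),
                dimnames = list(mnames, anames))
  for (mn in mnames) {
    mc <- config$metrics[[mn]]
    err_var <- (1 - mc$definition$icc) * mc$baseline_sd^2
    mu_x <- mc$class_mean_change
    mbar <- sum(pi_ * mu_x)
    var_x <- sum(pi_ * (mc$change_sd^2 + 2 * err_var + (mu_x - mbar)^2))
    for (e in names(mc$target_r)) {
      target <- mc$target_r[[e]]
      am <- vapply(astats[[e]], `[[`, numeric(1), "mean")
      ag <- vapply(astats[[e]], `[[`, numeric(1), "gamma")
      A <- sum(pi_ * mc$change_sd * ag)
      B <- sum(pi_ * (mu_x - mbar) * (am - a_mean[e]))
      r_need <- (target * sqrt(var_x * a_var[e]) - B) / A
      if (!is.finite(r_need) || abs(r_need) > 0.99) {
        stop(sprintf(
          "correlation target %.3f for %s~%s is infeasible under the class structure (needs copula coefficient %.3f)",
          target, mn, e, r_need))
      }
      rho[mn, e] <- r_need
    }
    if (sum(rho[mn, ]^2) > 0.99) {
      stop("combined correlation targets are infeasible for metric '",
           mn, "' (copula coefficients too large jointly)")
    }
  }
  rho
}

#' Generate a synthetic paired cohort
#'
#' Draws a cohort under a [simulation_config()] and returns it together with
#' the planted truth: the class-wise mean changes, the true change-difference
#' MIDs (class mean minus stable mean) per metric and direction, the target
#' correlations with the calibrated copula coefficients, and the latent class
#' of every patient. The same seed and config always reproduce the same
#' cohort.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (defaults to `config$seed`; required).
#' @param rho Optional precomputed copula-coefficient matrix from
#'   [calibrate_correlations()]; pass it when generating many replicates of
#'   the same config to skip the (deterministic) calibration step.
#' @return An object of class `mid_simulation`: list with `cohort` (data
#'   frame in the cohort CSV layout), `truth` (list with `mids`,
#'   `correlations`, `class`), `rho`, `config`, `seed`.
#' @export
generate_cohort <- function(config, seed = config$seed, rho = NULL) {
  stopifnot(inherits(config, "mid_sim_config"))
  if (is.null(seed)) stop("a seed is required (argument or config$seed)")
  seed <- as.integer(seed)
  if (is.null(rho)) rho <- calibrate_correlations(config)
  astats <- .anchor_class_stats(config)

  set.seed(seed)
  n <- config$n_patients
  cls <- sample(seq_len(3L), n, replace = TRUE, prob = config$mixture)

  cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                       stringsAsFactors = FALSE)

  # anchors: copula coordinate, truncated change, baseline, missingness
  anames <- names(config$anchors)
  z_anchor <- matrix(0, n, length(anames), dimnames = list(NULL, anames))
  for (e in anames) {
    a <- config$anchors[[e]]
    z <- rnorm(n)
    z_anchor[, e] <- z
    u <- pnorm(z)
    d <- numeric(n)
    for (k in seq_len(3L)) {
      idx <- cls == k
      if (!any(idx)) next
      st <- astats[[e]][[.CLASSES[k]]]
      d[idx] <- .tn_quantile(u[idx], st$mu, st$sigma, st$lo, st$hi)
    }
    base <- rnorm(n, a$baseline_mean, a$baseline_sd)
    miss <- runif(n) < a$missing_frac
    base[miss] <- NA_real_
    follow <- base + d
    cohort[[paste0(e, "_baseline")]] <- base
    cohort[[paste0(e, "_followup")]] <- follow
  }

  # metrics: coupled true change + test-retest measurement error
  for (mn in names(config$metrics)) {
    mc <- config$metrics[[mn]]
    icc <- mc$definition$icc
    load <- rho[mn, anames, drop = TRUE]
    resid <- sqrt(max(1 - sum(load^2), 0))
    eta <- if (config$tails == "t") {
      rt(n, config$t_df) / sqrt(config$t_df / (config$t_df - 2))
    } else {
      rnorm(n)
    }
    z_m <- as.vector(z_anchor %*% load) + resid * eta
    true_change <- mc$class_mean_change[cls] + mc$change_sd[cls] * z_m
    base_true <- rnorm(n, mc$baseline_mean, mc$baseline_sd * sqrt(icc))
    err_sd <- mc$baseline_sd * sqrt(1 - icc)
    e1 <- rnorm(n, 0, err_sd)
    e2 <- rnorm(n, 0, err_sd)
    cohort[[paste0(mn, "_baseline")]] <- base_true + e1
    cohort[[paste0(mn, "_followup")]] <- base_true + true_change + e2
  }

  cohort$survived_1yr <- as.integer(runif(n) >= config$death_prob[cls])

  truth_mids <- do.call(rbind, lapply(names(config$metrics), function(mn) {
    mu <- config$metrics[[mn]]$class_mean_change
    data.frame(metric = mn,
               mean_change_improved = mu[["improved"]],
               mean_change_stable = mu[["stable"]],
               mean_change_worsened = mu[["worsened"]],
               true_mid_improvement = mu[["improved"]] - mu[["stable"]],
               true_mid_worsening = mu[["worsened"]] - mu[["stable"]],
               stringsAsFactors = FALSE)
  }))
  truth_cor <- do.call(rbind, lapply(names(config$metrics), function(mn) {
    tr <- config$metrics[[mn]]$target_r
    data.frame(metric = mn, anchor = names(tr), target_r = unname(tr),
               rho = rho[mn, names(tr)], stringsAsFactors = FALSE)
  }))
  rownames(truth_cor) <- NULL

  structure(
    list(cohort = cohort,
         truth = list(mids = truth_mids, correlations = truth_cor,
                      class = factor(.CLASSES[cls], levels = .CLASSES)),
         rho = rho, config = config, seed = seed),
    class = "mid_simulation"
  )
}

#' Write a simulated cohort (and optionally its truth) to CSV
#'
#' Missing values are written as empty cells, matching the cohort CSV
#' contract of [read_cohort()].
#'
#' @param sim A `mid_simulation` from [generate_cohort()] (or a bare cohort
#'   data frame).
#' @param path Output CSV path for the cohort.
#' @param truth_path Optional path for the planted-truth table (class-wise
#'   mean changes, true change-difference MIDs, correlation targets).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(sim, path, truth_path = NULL) {
  cohort <- if (inherits(sim, "mid_simulation")) sim$cohort else sim
  write.csv(cohort, path, row.names = FALSE, na = "")
  if (!is.null(truth_path)) {
    if (!inherits(sim, "mid_simulation")) {
      stop("truth output needs a mid_simulation object")
    }
    truth <- merge(sim$truth$mids, sim$truth$correlations, by = "metric")
    write.csv(truth, truth_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Simulate same-day test-retest replicate measurements
#'
#' Two replicate measurements of the same underlying value, with measurement
#' error sized so the test-retest reliability equals `icc`; used to verify
#' the generator's reliability calibration.
#'
#' @param n Number of subjects.
#' @param baseline_mean,baseline_sd Observed-value moments.
#' @param icc Target test-retest reliability.
#' @param seed Integer seed.
#' @return Data frame with columns `replicate1`, `replicate2`.
#' @export
simulate_test_retest <- function(n, baseline_mean, baseline_sd, icc, seed) {
  set.seed(as.integer(seed))
  true <- rnorm(n, baseline_mean, baseline_sd * sqrt(icc))
  err_sd <- baseline_sd * sqrt(1 - icc)
  data.frame(replicate1 = true + rnorm(n, 0, err_sd),
             replicate2 = true + rnorm(n, 0, err_sd))
}

#' Registry-calibrated default configuration
#'
#' A ready-made configuration emulating a treatment-naive pulmonary arterial
#' hypertension cohort of 254 patients with paired cardiac-MRI metrics (RVEF,
#' RVEDV, RVESV, RVSV), emPHasis-10 and shuttle-walk anchors with realistic
#' attrition (anchored samples of about 118 and 146), a 35/47/18
#' improved/stable/worsened mixture, weak metric-anchor change correlations,
#' and a 1-year death fraction of about 10%. RVSV is the planted screen-out
#' metric: equal class means and |r| = 0.10 against both anchors. See the
#' methods vignette for the provenance of every number.
#'
#' @param seed Optional default seed stored in the config.
#' @return A `mid_sim_config`.
#' @export
paper_calibrated_config <- function(seed = NULL) {
  metrics <- list(
    rvef = sim_metric(
      metric_definition("rvef", "%", +1, icc = 0.94, label = "RVEF"),
      baseline_mean = 34, baseline_sd = 11,
      class_mean_change = c(10.5, 7, 5), change_sd = 10,
      target_r = c(e10 = -0.25, iswt = 0.20)),
    rvedv = sim_metric(
      metric_definition("rvedv", "mL", -1, icc = 0.98, label = "RVEDV"),
      baseline_mean = 207, baseline_sd = 71,
      class_mean_change = c(-22.5, -5.5, -3), change_sd = 40,
      target_r = c(e10 = 0.28, iswt = -0.28)),
    rvesv = sim_metric(
      metric_definition("rvesv", "mL", -1, icc = 0.97, label = "RVESV"),
      baseline_mean = 141, baseline_sd = 62,
      class_mean_change = c(-36, -19, -13), change_sd = 35,
      target_r = c(e10 = 0.32, iswt = -0.34)),
    rvsv = sim_metric(
      metric_definition("rvsv", "mL", +1, icc = 0.90, label = "RVSV"),
      baseline_mean = 66, baseline_sd = 20,
      class_mean_change = c(4, 4, 4), change_sd = 20,
      target_r = c(e10 = -0.10, iswt = 0.10))
  )
  anchors <- list(
    e10 = sim_anchor(
      anchor_definition("e10", "change_threshold", threshold = 6,
                        improvement_sign = -1, label = "emPHasis-10"),
      baseline_mean = 31, baseline_sd = 12,
      class_mean_change = c(-16, 0, 13), change_sd = 8,
      missing_frac = 1 - 118 / 254),
    iswt = sim_anchor(
      anchor_definition("iswt", "change_threshold", threshold = 47.5,
                        improvement_sign = +1, label = "ISWT"),
      baseline_mean = 207, baseline_sd = 175,
      class_mean_change = c(160, -1, -101), change_sd = 90,
      missing_frac = 1 - 146 / 254)
  )
  simulation_config(
    n_patients = 254, mixture = c(0.35, 0.47, 0.18),
    metrics = metrics, anchors = anchors,
    death_prob = c(improved = 0.02, stable = 0.08, worsened = 0.30),
    seed = seed
  )
}

#' Screening-benchmark configuration
#'
#' Three synthetic metrics with population metric-anchor correlations of 0.30
#' (strong enough to screen in), 0.10 (below threshold) and 0.00 (null),
#' against the same two anchors and attrition pattern as
#' [paper_calibrated_config()]. As for a genuinely responsive metric, the
#' non-null correlations arise from class-mean structure plus within-class
#' coupling. Used to characterise the operating behaviour of the correlation
#' screen at realistic anchored sample sizes.
#'
#' @param seed Optional default seed.
#' @return A `mid_sim_config`.
#' @export
screening_benchmark_config <- function(seed = NULL) {
  mk <- function(name, r, spread) {
    sim_metric(
      metric_definition(name, "units", +1, icc = 0.95),
      baseline_mean = 100, baseline_sd = 15,
      class_mean_change = c(spread, 0, -spread), change_sd = 10,
      target_r = c(e10 = -r, iswt = r))
  }
  metrics <- list(m_strong = mk("m_strong", 0.30, 5),
                  m_weak = mk("m_weak", 0.10, 1.5),
                  m_null = mk("m_null", 0.00, 0))
  anchors <- paper_calibrated_config()$anchors
  simulation_config(
    n_patients = 254, mixture = c(0.35, 0.47, 0.18),
    metrics = metrics, anchors = anchors,
    death_prob = c(0.02, 0.08, 0.30), seed = seed
  )
}

#' @export
print.mid_sim_config <- function(x, ...) {
  cat(sprintf(
    "<simulation config: n = %d, mixture %s, %d metrics, %d anchors>\n",
    x$n_patients, paste(sprintf("%.2f", x$mixture), collapse = "/"),
    length(x$metrics), length(x$anchors)))
  invisible(x)
}

#' @export
print.mid_simulation <- function(x, ...) {
  cat(sprintf("<simulated cohort: n = %d (seed %d), classes %s>\n",
              nrow(x$cohort), x$seed,
              paste(table(x$truth$class), collapse = "/")))
  invisible(x)
}
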