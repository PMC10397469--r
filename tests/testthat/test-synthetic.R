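test_that("configs are validated before any sampling", {
  cfg <- paper_calibrated_config()
  expect_error(simulation_config(100, c(0.5, 0.4, 0.2), cfg$metrics,
                                 cfg$anchors, c(0.1, 0.1, 0.1)),
               "sum to 1")
  expect_error(simulation_config(100, c(0.35, 0.47, 0.18), cfg$metrics,
                                 cfg$anchors, c(0.1, 1.3, 0.1)),
               "probabilities")
  # an unreachable correlation target fails at calibration, not sampling
  bad <- cfg
  bad$metrics$rvef$target_r[["e10"]] <- -0.95
  expect_error(calibrate_correlations(bad), "infeasible")
  expect_error(generate_cohort(bad, seed = 1), "infeasible")
  expect_error(generate_cohort(cfg), "seed")
})

test_that("the same seed and config reproduce the cohort byte for byte", {
  cfg <- paper_calibrated_config()
  s1 <- generate_cohort(cfg, seed = 7)
  s2 <- generate_cohort(cfg, seed = 7)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth, s2$truth)
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_cohort(s1, p1)
  write_cohort(s2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # a different seed gives a different cohort
  expect_false(identical(generate_cohort(cfg, seed = 8)$cohort, s1$cohort))
})

test_that("class counts, attrition and deaths match the configured cohort", {
  cfg <- paper_calibrated_config()
  sim <- generate_cohort(cfg, seed = 104729)
  counts <- table(sim$truth$class)
  for (k in seq_along(cfg$mixture)) {
    expect_gte(counts[k], qbinom(0.005, 254, cfg$mixture[k]))
    expect_lte(counts[k], qbinom(0.995, 254, cfg$mixture[k]))
  }
  # anchor-defined labels coincide with the generative classes where observed
  e10 <- cfg$anchors$e10$definition
  lab <- classify_by_anchor(anchor_changes(sim$cohort, e10), e10)
  obs <- !is.na(lab)
  expect_identical(as.character(lab[obs]),
                   as.character(sim$truth$class[obs]))
  # attrition and mortality near their configured rates
  expect_gt(sum(obs), qbinom(0.005, 254, 118 / 254))
  expect_lt(sum(obs), qbinom(0.995, 254, 118 / 254))
  p_death <- sum(cfg$mixture * cfg$death_prob)
  expect_gte(sum(sim$cohort$survived_1yr == 0), qbinom(0.005, 254, p_death))
  expect_lte(sum(sim$cohort$survived_1yr == 0), qbinom(0.995, 254, p_death))
})

test_that("planted metric-anchor correlations are achieved in the population", {
  cfg <- paper_calibrated_config()
  cfg$n_patients <- 20000L
  for (a in names(cfg$anchors)) cfg$anchors[[a]]$missing_frac <- 0
  sim <- generate_cohort(cfg, seed = 13)
  for (i in seq_len(nrow(sim$truth$correlations))) {
    m <- sim$truth$correlations$metric[i]
    a <- sim$truth$correlations$anchor[i]
    x <- sim$cohort[[paste0(m, "_followup")]] -
      sim$cohort[[paste0(m, "_baseline")]]
    d <- sim$cohort[[paste0(a, "_followup")]] -
      sim$cohort[[paste0(a, "_baseline")]]
    expect_lt(abs(cor(x, d) - sim$truth$correlations$target_r[i]), 0.03,
              label = sprintf("empirical-vs-target r gap for %s~%s", m, a))
  }
})

test_that("test-retest replicates achieve the configured reliability", {
  for (icc in c(0.80, 0.94, 0.98)) {
    tr <- simulate_test_retest(5000, 100, 15, icc, seed = round(1000 * icc))
    expect_equal(icc_consistency(tr$replicate1, tr$replicate2), icc,
                 tolerance = 0.02, label = sprintf("ICC target %.2f", icc))
  }
})

test_that("the pipeline recovers planted change-difference MIDs (3 MC SEs)", {
  cfg <- paper_calibrated_config()
  rho <- calibrate_correlations(cfg)
  mets <- lapply(cfg$metrics[c("rvef", "rvedv", "rvesv")], `[[`, "definition")
  ancs <- lapply(cfg$anchors, `[[`, "definition")
  nrep <- 200L
  res <- list()
  for (i in seq_len(nrep)) {
    sim <- generate_cohort(cfg, seed = 5000 + i, rho = rho)
    coh <- sim$cohort
    labs <- lapply(ancs, function(a) {
      classify_by_anchor(anchor_changes(coh, a), a)
    })
    labs$survival <- classify_by_survival(coh)
    for (m in names(mets)) {
      x <- coh[[paste0(m, "_followup")]] - coh[[paste0(m, "_baseline")]]
      for (a in names(labs)) {
        dirs <- if (a == "survival") "worsening" else
          c("improvement", "worsening")
        for (dd in dirs) {
          v <- tryCatch(change_difference_mid(x, labs[[a]], dd)$value,
                        error = function(e) NA_real_)
          res[[paste(m, a, dd, sep = ".")]] <-
            c(res[[paste(m, a, dd, sep = ".")]], v)
        }
      }
    }
  }
  truth <- cfg$metrics
  # analytic estimand of the survival-anchored contrast (groups are mixtures
  # of the latent classes weighted by survival status)
  surv_truth <- function(m) {
    mu <- truth[[m]]$class_mean_change
    w_dead <- cfg$mixture * cfg$death_prob
    w_alive <- cfg$mixture * (1 - cfg$death_prob)
    sum(w_dead * mu) / sum(w_dead) - sum(w_alive * mu) / sum(w_alive)
  }
  for (m in names(mets)) {
    mu <- truth[[m]]$class_mean_change
    expected <- c(
      e10.improvement = mu[["improved"]] - mu[["stable"]],
      e10.worsening = mu[["worsened"]] - mu[["stable"]],
      iswt.improvement = mu[["improved"]] - mu[["stable"]],
      iswt.worsening = mu[["worsened"]] - mu[["stable"]],
      survival.worsening = surv_truth(m))
    for (cell in names(expected)) {
      est <- res[[paste(m, cell, sep = ".")]]
      est <- est[!is.na(est)]
      mc_se <- sd(est) / sqrt(length(est))
      expect_lt(abs(mean(est) - expected[[cell]]), 3 * mc_se,
                label = sprintf("|bias| for %s.%s vs 3 MC SEs", m, cell))
    }
  }
})

test_that("with no planted effect anchor-based MIDs centre on 0 and floor often", {
  cfg <- paper_calibrated_config()
  cfg$metrics$rvef$class_mean_change <- c(improved = 7, stable = 7,
                                          worsened = 7)
  rho <- calibrate_correlations(cfg)
  e10 <- cfg$anchors$e10$definition
  rvef <- cfg$metrics$rvef$definition
  vals <- floored <- numeric(0)
  for (i in seq_len(100)) {
    sim <- generate_cohort(cfg, seed = 9000 + i, rho = rho)
    coh <- sim$cohort
    lab <- classify_by_anchor(anchor_changes(coh, e10), e10)
    x <- (coh$rvef_followup - coh$rvef_baseline)[!is.na(lab)]
    l <- lab[!is.na(lab)]
    est <- tryCatch(change_difference_mid(x, l, "improvement"),
                    error = function(e) NULL)
    if (is.null(est)) next
    sem <- sd(x) * sqrt(1 - rvef$icc)
    fl <- apply_sem_floor(est, sem)
    vals <- c(vals, est$value)
    floored <- c(floored, fl$floored)
  }
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
  expect_gt(mean(floored), 0.5)
})
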