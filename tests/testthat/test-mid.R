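test_that("half-sd MID is half the sample sd of the changed group", {
  # sd of {-4,-2,0,2,4} is sqrt(10)
  est <- half_sd_mid(c(-4, -2, 0, 2, 4), "improvement")
  expect_equal(est$value, 0.5 * sqrt(10))
  expect_equal(est$value, 1.5811, tolerance = 1e-4)
  expect_equal(half_sd_mid(rep(3, 5), "improvement")$value, 0)
  expect_equal(half_sd_mid(3 * c(-4, -2, 0, 2, 4), "improvement")$value,
               3 * est$value)
  expect_error(half_sd_mid(1, "improvement"), "at least 2")
  # sign follows the metric's direction of benefit
  vol <- test_metric(direction = -1)
  expect_lt(half_sd_mid(c(-4, 0, 4), "improvement", vol)$value, 0)
  expect_gt(half_sd_mid(c(-4, 0, 4), "worsening", vol)$value, 0)
})

test_that("MDC follows the closed form 1.96 * sqrt(2) * sem", {
  est <- mdc_mid(10, 0.96)
  expect_equal(est$sem, 2)
  expect_equal(est$value, 1.96 * sqrt(2) * 2)
  expect_equal(est$value, 5.5437, tolerance = 5e-5)
  expect_equal(mdc_mid(10, 1)$value, 0)
  expect_equal(mdc_mid(10, 0)$value, 27.719, tolerance = 5e-4)
  expect_error(mdc_mid(10, 1.2), "icc")
  expect_error(mdc_mid(-1, 0.5), "non-negative")
  # monotone increasing in sd, decreasing in icc
  set.seed(41)
  sds <- sort(runif(10, 0, 50))
  expect_true(all(diff(vapply(sds, function(s) mdc_mid(s, 0.9)$value,
                              numeric(1))) >= 0))
  iccs <- sort(runif(10))
  expect_true(all(diff(vapply(iccs, function(i) mdc_mid(10, i)$value,
                              numeric(1))) <= 0))
})

test_that("change difference contrasts group means against the stable group", {
  ch <- c(10, 12, 8, 7, 9, 8, -5, -5)
  lab <- factor(rep(c("improved", "stable", "worsened"), c(3, 3, 2)),
                levels = c("improved", "stable", "worsened"))
  up <- change_difference_mid(ch, lab, "improvement")
  expect_equal(up$value, 2)  # mean 10 vs mean 8
  expect_equal(up$n_improved, 3L)
  expect_equal(change_difference_mid(ch, lab, "worsening")$value, -13)
  # identically distributed groups give 0
  ch0 <- c(1, 2, 3, 1, 2, 3, 1, 2)
  expect_equal(change_difference_mid(ch0, lab, "improvement")$value, 0)
  # smallness errors
  lab1 <- factor(c("improved", rep("stable", 5), "worsened", "worsened"),
                 levels = levels(lab))
  expect_error(change_difference_mid(ch, lab1, "improvement"), "too small")
  # survival anchor: non-survivors vs survivors, worsening only
  slab <- factor(rep(c("survivor", "non_survivor"), c(5, 3)),
                 levels = c("survivor", "non_survivor"))
  sch <- c(5, 5, 5, 5, 5, -1, -1, -1)
  expect_equal(change_difference_mid(sch, slab, "worsening")$value, -6)
  expect_error(change_difference_mid(sch, slab, "improvement"),
               "not defined")
})

test_that("dummy-coded regression reproduces group-mean contrasts", {
  ch <- c(10, 12, 8, 7, 9, 8, -5, -5)
  lab <- factor(rep(c("improved", "stable", "worsened"), c(3, 3, 2)),
                levels = c("improved", "stable", "worsened"))
  fit <- glm_regression_mid(ch, lab)
  # oracle: hand-computed group means
  expect_equal(fit$k, mean(c(7, 9, 8)))
  expect_equal(fit$beta_better, mean(c(10, 12, 8)) - mean(c(7, 9, 8)))
  expect_equal(fit$beta_worse, -5 - 8)
  expect_equal(fit$improvement$value, 2)
  # a design with a missing class is refused
  lab_deg <- factor(rep("stable", 8),
                    levels = c("improved", "stable", "worsened"))
  expect_error(glm_regression_mid(ch, lab_deg), "at least 2")
  # survival mode: coefficient is the worsening MID
  slab <- factor(rep(c("survivor", "non_survivor"), c(5, 3)),
                 levels = c("survivor", "non_survivor"))
  sch <- c(5, 4, 6, 5, 5, -1, 0, -2)
  sfit <- glm_regression_mid(sch, slab)
  expect_equal(sfit$beta_worse, mean(c(-1, 0, -2)) - mean(c(5, 4, 6, 5, 5)))
  expect_null(sfit$improvement)
})

test_that("regression and change-difference MIDs agree on arbitrary data", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(30:300, 1)
    lab <- rand_labels(n)
    ch <- rnorm(n, mean = sample(-20:20, 1), sd = runif(1, 0.5, 30))
    fit <- glm_regression_mid(ch, lab)
    expect_equal(fit$beta_better,
                 change_difference_mid(ch, lab, "improvement")$value,
                 tolerance = 1e-8)
    expect_equal(fit$beta_worse,
                 change_difference_mid(ch, lab, "worsening")$value,
                 tolerance = 1e-8)
  }
})

test_that("the SEM floor lifts small anchor-based MIDs and nothing else", {
  lab <- factor(rep(c("improved", "stable", "worsened"), c(2, 3, 2)),
                levels = c("improved", "stable", "worsened"))
  est <- change_difference_mid(c(1.1, 1.3, 0, 0, 0, -4, -4), lab,
                               "improvement")
  expect_equal(est$value, 1.2)
  fl <- apply_sem_floor(est, 2)
  expect_equal(fl$value, 2)
  expect_true(fl$floored)
  expect_equal(fl$sem, 2)
  # above the floor: unchanged
  big <- change_difference_mid(c(5, 5, 0, 0, 0, -4, -4), lab, "improvement")
  expect_false(apply_sem_floor(big, 2)$floored)
  # exactly at the floor: strict inequality, not floored
  at <- change_difference_mid(c(2, 2, 0, 0, 0, -4, -4), lab, "improvement")
  expect_false(apply_sem_floor(at, 2)$floored)
  # negative estimates floor to minus the sem
  neg <- change_difference_mid(c(-1, -1, 0, 0, 0, -4, -4), lab,
                               "improvement")
  expect_equal(apply_sem_floor(neg, 2)$value, -2)
  # the rule is for anchor-based estimates only
  expect_error(apply_sem_floor(half_sd_mid(c(1, 2, 3), "improvement"), 2),
               "anchor-based")
  expect_error(apply_sem_floor(mdc_mid(10, 0.9), 2), "anchor-based")
})

test_that("estimate_all produces the full cell grid with screening markers", {
  cfg <- paper_calibrated_config()
  sim <- generate_cohort(cfg, seed = 8)
  mets <- lapply(cfg$metrics, `[[`, "definition")
  ancs <- c(lapply(cfg$anchors, `[[`, "definition"),
            list(survival = anchor_definition("survival", "binary_survival")))
  mids <- estimate_all(sim$cohort, mets, ancs)

  scr <- attr(mids, "screen")
  expect_s3_class(scr, "data.frame")
  for (a in c("e10", "iswt")) {
    for (m in names(mets)) {
      sub <- mids[mids$metric == m & mids$anchor == a, , drop = FALSE]
      if (scr$passed[scr$metric == m & scr$anchor == a]) {
        # 4 methods x 2 directions x 2 scales
        expect_equal(nrow(sub[sub$status == "ok", ]), 16L)
      } else {
        expect_equal(sub$status, "screened_out")
      }
    }
  }
  # survival anchor: worsening cells estimated, improvement marked
  for (m in names(mets)) {
    sub <- mids[mids$metric == m & mids$anchor == "survival", , drop = FALSE]
    if (any(scr$passed[scr$metric == m])) {
      expect_equal(nrow(sub[sub$status == "ok" &
                              sub$direction == "worsening", ]), 8L)
      expect_equal(nrow(sub[sub$status == "not_defined" &
                              sub$direction == "improvement", ]), 8L)
    } else {
      expect_equal(sub$status, "screened_out")
    }
  }
  # floored anchor-based estimates sit exactly at the sem
  fl <- mids[!is.na(mids$floored) & mids$floored, ]
  expect_true(all(fl$method %in% c("change_difference", "glm_regression")))
  expect_equal(abs(fl$value), fl$sem)
  # group counts partition each anchored sample
  ok <- mids[mids$status == "ok" & mids$anchor %in% c("e10", "iswt"), ]
  expect_true(all(ok$n_improved + ok$n_stable + ok$n_worsened == ok$n_total))
})

test_that("absolute MIDs scale with the metric and relative MIDs do not", {
  cfg <- paper_calibrated_config()
  cfg$n_patients <- 150L
  for (a in names(cfg$anchors)) cfg$anchors[[a]]$missing_frac <- 0
  sim <- generate_cohort(cfg, seed = 12)
  coh <- sim$cohort
  coh3 <- coh
  coh3$rvedv_baseline <- coh$rvedv_baseline * 3
  coh3$rvedv_followup <- coh$rvedv_followup * 3
  mets <- list(rvedv = cfg$metrics$rvedv$definition)
  ancs <- list(e10 = cfg$anchors$e10$definition)
  m1 <- estimate_all(coh, mets, ancs, floor = FALSE)
  m3 <- estimate_all(coh3, mets, ancs, floor = FALSE)
  ok <- m1$status == "ok"
  expect_identical(ok, m3$status == "ok")
  abs1 <- m1[ok & m1$scale == "absolute", ]
  abs3 <- m3[ok & m3$scale == "absolute", ]
  expect_equal(abs3$value, abs1$value * 3, tolerance = 1e-10)
  rel1 <- m1[ok & m1$scale == "relative", ]
  rel3 <- m3[ok & m3$scale == "relative", ]
  expect_equal(rel3$value, rel1$value, tolerance = 1e-10)
})
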