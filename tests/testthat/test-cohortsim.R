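# Synthetic cohort generator: determinism, covariate structure, tracer links,
# longitudinal decline, image rendering.

test_that("cohorts are deterministic and noise-free values equal covariate predictions", {
  cfg <- cohort_config(n_hc = 40, subject_cv = 0, noise_sd_reference = 0)
  s1 <- simulate_cohort(cfg, "hc", seed = 3)
  s2 <- simulate_cohort(cfg, "hc", seed = 3)
  expect_identical(s1$sbr, s2$sbr)
  expect_identical(s1$truth, s2$truth)
  # every striatum SBR equals its covariate-predicted value exactly
  str <- s1$sbr[s1$sbr$region == "striatum" & s1$sbr$side == "bilateral", ]
  mu <- centamine:::config_hc_mu(cfg, "striatum")
  pred <- (cfg$age_slope_cm * str$age + cfg$sex_offset_cm * str$sex +
             cfg$cm_intercept) / 100 * mu
  expect_equal(str$value, pred, tolerance = 1e-12)
  # cardinality: n x 5 regions x 3 sides
  expect_equal(nrow(s1$sbr), 40 * 5 * 3)
  # invalid mixes are rejected
  expect_error(cohort_config(n_h2h_hc = 99), "group mix")
  expect_error(cohort_config(noise_sd_reference = -1), ">= 0")
})

test_that("deficit gradient orders PD medians post < pre < caudate", {
  cfg <- cohort_config(n_h2h = 120)
  sim <- simulate_cohort(cfg, "h2h", seed = 9)
  pd_ids <- sim$subjects$subject[sim$subjects$group == "pd"]
  pd <- sim$truth[sim$truth$subject %in% pd_ids &
                    sim$truth$side == "bilateral", ]
  med <- tapply(pd$true_cm, pd$region, median)
  expect_lt(med[["post_commissural_putamen"]],
            med[["pre_commissural_putamen"]])
  expect_lt(med[["pre_commissural_putamen"]], med[["caudate"]])
})

test_that("head-to-head links recover the generating maps and default layout", {
  # noise-free: level-2 recovers the generating (a, b) exactly in the
  # primitive regions
  cfg0 <- cohort_config(n_h2h = 30, subject_cv = 0.1,
                        noise_sd_reference = 0,
                        noise_sd_second = c(
                          striatum = 0, putamen = 0, caudate = 0,
                          pre_commissural_putamen = 0,
                          post_commissural_putamen = 0))
  sim0 <- simulate_head2head(simulate_cohort(cfg0, "h2h", seed = 21))
  anch <- structure(
    data.frame(region = c("caudate", "pre_commissural_putamen",
                          "post_commissural_putamen"),
               mu = unname(cfg0$hc_mean_sbr), sd = 0.2, n = 30),
    class = c("cm_anchors", "data.frame"), tracer = "ioflupane",
    side = "bilateral")
  m <- fit_level2(sim0$sbr, anch, "av133")
  map <- cfg0$tracer_map
  for (r in anch$region) {
    expect_equal(m$table$a[m$table$region == r],
                 map$a[map$region == r], tolerance = 1e-10)
    expect_equal(m$table$b[m$table$region == r],
                 map$b[map$region == r], tolerance = 1e-10)
  }
  # default pipeline: 68 subjects, 45 longitudinal, 162 paired sessions
  cfg <- cohort_config()
  sim <- simulate_head2head(simulate_longitudinal(
    simulate_cohort(cfg, "h2h", seed = 1), cfg), cfg)
  sess <- unique(sim$sbr[sim$sbr$tracer == "av133",
                         c("subject", "session_years")])
  expect_equal(nrow(sess), 162L)
  expect_equal(length(unique(sim$sbr$subject)), 68L)
  # fitted R-squared lands in a moderate-strong band under pinned noise
  anch_full <- level1_anchors(
    simulate_cohort(cfg, "hc", seed = 2)$sbr)
  m2 <- fit_level2(sim$sbr, anch_full, "av133")
  expect_true(all(m2$table$r2 > 0.4 & m2$table$r2 < 0.9))
  # missing mapping region is an error
  cfg_bad <- cfg
  cfg_bad$tracer_map <- cfg$tracer_map[cfg$tracer_map$region != "caudate", ]
  expect_error(simulate_head2head(simulate_cohort(cfg, "h2h", seed = 1),
                                  cfg_bad), "caudate")
})

test_that("longitudinal visits follow the config and noise-free decline is exact", {
  cfg <- cohort_config(n_h2h = 45, n_h2h_hc = 0, n_longitudinal = 45,
                       subject_cv = 0, noise_sd_reference = 0,
                       decline_cm_per_yr = c(
                         caudate = -7.4, pre_commissural_putamen = -7.4,
                         post_commissural_putamen = -7.4))
  sim <- simulate_longitudinal(simulate_cohort(cfg, "h2h", seed = 4), cfg)
  # 45 subjects x 3 visits, plus one extra visit for the first four
  sess <- unique(sim$sbr[, c("subject", "session_years")])
  expect_equal(nrow(sess), 45 * 3 + 4)
  # noise-free: annual_change returns the generating decline exactly
  cm <- sim$truth
  cm_tab <- cm[, c("subject", "tracer", "session_years", "age", "sex",
                   "region", "side")]
  cm_tab$value <- cm$true_cm
  res <- annual_change(cm_tab, regions = "caudate")
  expect_equal(res$abs_change_per_yr, -7.4, tolerance = 1e-9)
  # zero decline, zero noise: all visits identical
  cfg_flat <- cohort_config(n_h2h = 6, n_h2h_hc = 6, n_longitudinal = 6,
                            subject_cv = 0, noise_sd_reference = 0,
                            age_slope_cm = 0, sex_offset_cm = 0)
  sim_flat <- simulate_longitudinal(simulate_cohort(cfg_flat, "h2h",
                                                    seed = 4), cfg_flat)
  spread <- tapply(sim_flat$truth$true_sbr,
                   paste(sim_flat$truth$subject, sim_flat$truth$region,
                         sim_flat$truth$side),
                   function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
  # negative visit times are rejected
  cfg_bad <- cohort_config(visits = c(0, -1, 2))
  expect_error(simulate_longitudinal(simulate_cohort(cfg_bad, "h2h",
                                                     seed = 1), cfg_bad),
               "nonnegative")
  cfg_one <- cohort_config(visits = c(1, 1))
  expect_error(simulate_longitudinal(simulate_cohort(cfg_one, "h2h",
                                                     seed = 1), cfg_one),
               "at least 2")
})

test_that("rendered images carry reproducible ground truth", {
  bank <- test_bank()
  cfg <- cohort_config(n_h2h = 10, noise_sd_reference = 0)
  sim <- simulate_cohort(cfg, "h2h", seed = 6)
  ims <- render_images(sim, bank, seed = 7)
  expect_length(ims$scans, 10L)
  ims2 <- render_images(sim, bank, seed = 7)
  expect_identical(ims$scans[[3]]$volume$values,
                   ims2$scans[[3]]$volume$values)
  expect_identical(ims$scans[[3]]$truth$transform$matrix,
                   ims2$scans[[3]]$truth$transform$matrix)
  # painted subregion values agree with the tabular truth
  sc <- ims$scans[[5]]
  atlas <- bank$atlas
  tr <- sim$truth[sim$truth$subject == sc$subject &
                    sim$truth$side == "left", ]
  pre_codes <- atlas$region_table$code[
    atlas$region_table$name == "pre_dorsal_putamen" &
      atlas$region_table$side == "left"]
  expect_equal(unname(sc$truth$values[as.character(pre_codes)]),
               1 + tr$true_sbr[tr$region == "pre_commissural_putamen"])
})
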