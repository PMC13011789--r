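# Three-level Centamine calibration: anchors, mappings, conversions,
# pipeline calibration.

test_that("level-1 anchors reproduce cohort means and enforce preconditions", {
  hc <- make_sbr_table(c("a", "b"), "ioflupane", c(1.3, 1.5))
  anch <- level1_anchors(hc)
  expect_equal(anch$mu, 1.4)
  expect_equal(anch$n, 2L)
  # single record per region is rejected
  expect_error(level1_anchors(make_sbr_table("a", "ioflupane", 1.3)),
               "at least 2")
  # mixed tracers are rejected (level 1 is reference-tracer only)
  two <- rbind(hc, make_sbr_table(c("a", "b"), "av133", c(2, 3)))
  expect_error(level1_anchors(two), "exactly one")
  # sampling bound: cohort drawn around the published striatum mean
  set.seed(7)
  sim <- make_sbr_table(sprintf("s%03d", 1:224), "ioflupane",
                        rnorm(224, 1.41, 0.2))
  a2 <- level1_anchors(sim)
  expect_lt(abs(a2$mu - 1.41), 3 * 0.2 / sqrt(224))
})

test_that("reference-tracer conversion anchors CM 0 and 100 exactly", {
  hc <- make_sbr_table(c("a", "b"), "ioflupane", c(1.3, 1.5))
  anch <- level1_anchors(hc)
  expect_equal(cm_reference(1.4, anch, "striatum"), 100)
  expect_equal(cm_reference(0, anch, "striatum"), 0)
  expect_equal(cm_reference(0.7, anch, "striatum"), 50)
  expect_error(cm_reference(1, anch, "putamen"), "not present")
})

test_that("level-2 fits recover exact generating lines and their anchors", {
  # noise-free pairs on the line y = 1.93 x + 0.64 recover it exactly
  x <- seq(0.1, 2.5, length.out = 50)
  pairs <- rbind(
    make_sbr_table(sprintf("s%02d", 1:50), "ioflupane", x, "putamen"),
    make_sbr_table(sprintf("s%02d", 1:50), "av133", 1.93 * x + 0.64,
                   "putamen"))
  anch <- structure(
    data.frame(region = "putamen", mu = 1.56, sd = 0.2, n = 50),
    class = c("cm_anchors", "data.frame"), tracer = "ioflupane",
    side = "bilateral")
  m <- fit_level2(pairs, anch, "av133")
  expect_equal(m$table$a, 1.93, tolerance = 1e-10)
  expect_equal(m$table$b, 0.64, tolerance = 1e-10)
  # anchor identity: SBR@CM0 = b exactly; SBR@CM100 = a mu + b
  expect_identical(m$table$sbr_cm0, m$table$b)
  expect_equal(m$table$sbr_cm100, 1.93 * 1.56 + 0.64, tolerance = 1e-10)
  # the fitted line maps its own anchors to 0 and 100
  expect_equal(cm_mapped(m$table$sbr_cm100, m, "putamen"), 100,
               tolerance = 1e-10)
  expect_equal(cm_mapped(m$table$sbr_cm0, m, "putamen"), 0,
               tolerance = 1e-10)
  # below-anchor SBR extrapolates to negative Centamines
  expect_lt(cm_mapped(0.5, m, "putamen"), 0)
  # degenerate reference variance is an error
  flat <- pairs; flat$value[flat$tracer == "ioflupane"] <- 1
  expect_error(fit_level2(flat, anch, "av133"), "degenerate")
  # too few pairs is an error naming the region
  expect_error(fit_level2(pairs[c(1, 2, 51, 52), ], anch, "av133"),
               "putamen")
})

test_that("published-coefficient mappings reproduce printed anchor arithmetic", {
  m <- mapping_from_coefficients("striatum", a = 1.48, b = 0.81,
                                 mu_hc = 1.41, tracer = "av133")
  expect_equal(m$table$sbr_cm0, 0.81)
  expect_equal(round_half_up(m$table$sbr_cm100, 2), 2.90)
  expect_equal(cm_mapped(2.8968, m, "striatum"), 100, tolerance = 1e-10)
  # non-positive slope flags the mapping invalid and blocks conversion
  bad <- mapping_from_coefficients("striatum", a = -0.2, b = 0.8,
                                   mu_hc = 1.41)
  expect_false(bad$table$valid)
  expect_error(cm_mapped(1, bad, "striatum"), "invalid")
})

test_that("repeated sessions are independent points unless clustering is requested", {
  x <- c(1, 2, 1.5)
  pairs <- do.call(rbind, lapply(1:3, function(i) rbind(
    make_sbr_table(paste0("s", i), "ioflupane", x + 0.1 * i,
                   session_years = c(0, 1, 2)),
    make_sbr_table(paste0("s", i), "av133", 2 * (x + 0.1 * i) + 0.5,
                   session_years = c(0, 1, 2)))))
  anch <- structure(
    data.frame(region = "striatum", mu = 1.41, sd = 0.2, n = 10),
    class = c("cm_anchors", "data.frame"), tracer = "ioflupane",
    side = "bilateral")
  m_all <- fit_level2(pairs, anch, "av133")
  expect_equal(m_all$table$n, 9L)
  m_one <- fit_level2(pairs, anch, "av133", one_pair_per_subject = TRUE)
  expect_equal(m_one$table$n, 3L)
  # sessions further apart than the window are not paired
  shifted <- pairs
  shifted$session_years[shifted$tracer == "av133"] <-
    shifted$session_years[shifted$tracer == "av133"] + 0.5
  expect_error(fit_level2(shifted, anch, "av133"), "at least 3")
})

test_that("level-3 equals the composed level-2 mapping on consistent data", {
  a1 <- 1.5; b1 <- 0.7    # reference -> X
  a2 <- 0.8; b2 <- -0.2   # X -> Y
  mu <- 1.41
  x_ref <- seq(0.2, 2.2, length.out = 40)
  subs <- sprintf("s%02d", 1:40)
  sx <- a1 * x_ref + b1
  sy <- a2 * sx + b2
  tab <- rbind(make_sbr_table(subs, "ioflupane", x_ref),
               make_sbr_table(subs, "tracerX", sx),
               make_sbr_table(subs, "tracerY", sy))
  anch <- structure(
    data.frame(region = "striatum", mu = mu, sd = 0.2, n = 40),
    class = c("cm_anchors", "data.frame"), tracer = "ioflupane",
    side = "bilateral")
  mx <- fit_level2(tab, anch, "tracerX")
  my <- fit_level3(tab, mx, "tracerY")
  expect_equal(my$level, 3L)
  # identity chain: Y = X gives Y anchors equal to X anchors
  tab_id <- rbind(tab[tab$tracer != "tracerY", ],
                  make_sbr_table(subs, "tracerY", sx))
  my_id <- fit_level3(tab_id, mx, "tracerY")
  expect_equal(my_id$table$sbr_cm0, mx$table$sbr_cm0, tolerance = 1e-10)
  expect_equal(my_id$table$sbr_cm100, mx$table$sbr_cm100, tolerance = 1e-10)
  # composition oracle: level-3 CM equals the directly composed level-2 map
  direct <- mapping_from_coefficients("striatum", a = a2 * a1,
                                      b = a2 * b1 + b2, mu_hc = mu,
                                      tracer = "tracerY")
  probe <- seq(-0.5, 4, length.out = 23)
  expect_equal(cm_mapped(probe, my, "striatum"),
               cm_mapped(probe, direct, "striatum"), tolerance = 1e-10)
  # composite coefficients recorded on the reference scale
  expect_equal(my$table$composite_a, a2 * a1, tolerance = 1e-10)
  expect_equal(my$table$composite_b, a2 * b1 + b2, tolerance = 1e-10)
  # level-3 CM agrees with converting the underlying reference SBR directly
  expect_equal(cm_mapped(sy[5], my, "striatum"),
               cm_reference(x_ref[5], anch, "striatum"), tolerance = 1e-8)
  # degenerate constant X is an error
  tab_const <- tab
  tab_const$value[tab_const$tracer == "tracerX"] <- 1
  expect_error(fit_level3(tab_const, mx, "tracerY"), "degenerate")
})

test_that("scale equivariance: rescaling a tracer's SBR leaves Centamines unchanged", {
  set.seed(31)
  x <- seq(0.2, 2.2, length.out = 30)
  subs <- sprintf("s%02d", 1:30)
  y <- 1.6 * x + 0.5 + rnorm(30, 0, 0.05)
  anch <- structure(
    data.frame(region = "striatum", mu = 1.41, sd = 0.2, n = 30),
    class = c("cm_anchors", "data.frame"), tracer = "ioflupane",
    side = "bilateral")
  alpha <- 3.7
  m1 <- fit_level2(rbind(make_sbr_table(subs, "ioflupane", x),
                         make_sbr_table(subs, "av133", y)), anch, "av133")
  m2 <- fit_level2(rbind(make_sbr_table(subs, "ioflupane", x),
                         make_sbr_table(subs, "av133", alpha * y)),
                   anch, "av133")
  expect_equal(m2$table$a, alpha * m1$table$a, tolerance = 1e-10)
  expect_equal(m2$table$b, alpha * m1$table$b, tolerance = 1e-10)
  expect_equal(cm_mapped(alpha * y, m2, "striatum"),
               cm_mapped(y, m1, "striatum"), tolerance = 1e-8)
})

test_that("round trip: reference CM via anchors equals CM via a self-pair mapping", {
  x <- seq(0.2, 2.2, length.out = 30)
  subs <- sprintf("s%02d", 1:30)
  anch <- structure(
    data.frame(region = "striatum", mu = 1.41, sd = 0.2, n = 30),
    class = c("cm_anchors", "data.frame"), tracer = "ioflupane",
    side = "bilateral")
  selfpairs <- rbind(make_sbr_table(subs, "ioflupane", x),
                     make_sbr_table(subs, "self", x))
  m <- fit_level2(selfpairs, anch, "self")
  expect_equal(m$table$a, 1, tolerance = 1e-10)
  expect_equal(m$table$b, 0, tolerance = 1e-10)
  expect_equal(cm_mapped(x, m, "striatum"),
               cm_reference(x, anch, "striatum"), tolerance = 1e-10)
})

test_that("pipeline calibration recovers closed-form maps and reports alignment", {
  mu <- 1.41
  sbr <- seq(0.2, 2.4, length.out = 12)
  subs <- sprintf("s%02d", 1:12)
  own <- make_sbr_table(subs, "ioflupane", sbr)
  provided <- make_sbr_table(subs, "ioflupane", 100 * sbr / mu)
  pc <- calibrate_pipeline(own, provided)
  expect_equal(pc$slope, 100 / mu, tolerance = 1e-10)
  expect_equal(pc$intercept, 0, tolerance = 1e-8)
  expect_lt(pc$alignment_mae, 1e-8)
  # doubling the pipeline's SBRs halves the slope
  own2 <- own; own2$value <- 2 * own$value
  pc2 <- calibrate_pipeline(own2, provided)
  expect_equal(pc2$slope, 100 / mu / 2, tolerance = 1e-10)
  expect_equal(pc2$intercept, 0, tolerance = 1e-8)
  # additive offset delta gives intercept -slope * delta exactly
  delta <- 0.3
  own3 <- own; own3$value <- own$value + delta
  pc3 <- calibrate_pipeline(own3, provided)
  expect_equal(pc3$intercept, -pc3$slope * delta, tolerance = 1e-8)
  # empty join is an error
  other <- provided; other$subject <- paste0("x", other$subject)
  expect_error(calibrate_pipeline(own, other), "no overlapping")
})

test_that("mapping objects expose the standard modelling verbs", {
  m <- mapping_from_coefficients(c("striatum", "putamen"),
                                 a = c(1.48, 1.93), b = c(0.81, 0.64),
                                 mu_hc = c(1.41, 1.56), tracer = "av133")
  expect_output(print(m), "level 2")
  expect_named(coef(m), c("striatum", "putamen"))
  expect_equal(predict(m, 2.8968, "striatum"), 100, tolerance = 1e-10)
})
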