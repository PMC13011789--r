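# Endpoints: age/sex correction, deficit classification, concordance,
# annualized change.

make_cm_cohort <- function(n, a_age, b_sex, c_int, noise_sd = 0,
                           region = "putamen", seed = 1) {
  set.seed(seed)
  age <- runif(n, 40, 85)
  sex <- rbinom(n, 1, 0.5)
  if (length(unique(sex)) == 1L) sex[1] <- 1 - sex[1]
  cm <- a_age * age + b_sex * sex + c_int + rnorm(n, 0, noise_sd)
  data.frame(subject = sprintf("s%03d", 1:n), tracer = "ioflupane",
             session_years = 0, age = age, sex = sex, region = region,
             side = "bilateral", value = cm, stringsAsFactors = FALSE)
}

test_that("age/sex model recovers exact planes and rejects degenerate cohorts", {
  d <- make_cm_cohort(60, a_age = -0.3, b_sex = -12, c_int = 125)
  m <- fit_agesex(d)
  expect_equal(m$a_age, -0.3, tolerance = 1e-10)
  expect_equal(m$b_sex, -12, tolerance = 1e-10)
  expect_equal(m$c_intercept, 125, tolerance = 1e-8)
  # all-female cohort: sex coefficient unidentifiable
  dall <- d; dall$sex <- 0
  expect_error(fit_agesex(dall), "one sex")
  dage <- d; dage$age <- 65
  expect_error(fit_agesex(dage), "age has no variation")
  expect_error(fit_agesex(d[1:3, ]), "at least 4")
})

test_that("CM* anchors to the 65-year sex-average person", {
  m <- fit_agesex(make_cm_cohort(60, a_age = -0.3, b_sex = -12, c_int = 125))
  # at the anchor covariates the correction is the identity
  expect_equal(cm_star(88, 65, 0.5, m, "putamen"), 88, tolerance = 1e-10)
  # degenerate model (no age/sex effect): CM* = CM for any age and sex
  m0 <- fit_agesex(make_cm_cohort(60, a_age = 0, b_sex = 0, c_int = 100))
  expect_equal(cm_star(70, 40, 1, m0, "putamen"), 70, tolerance = 1e-6)
  # CM* is positively proportional to CM at fixed covariates
  k <- cm_star(1, 80, 1, m, "putamen")
  expect_gt(k, 0)
  expect_equal(cm_star(c(50, 100), 80, 1, m, "putamen"), k * c(50, 100))
  # extrapolation past a non-positive expected CM is an error
  msteep <- fit_agesex(make_cm_cohort(60, a_age = -2, b_sex = 0,
                                      c_int = 100))
  expect_error(cm_star(50, 120, 0, msteep, "putamen"), "not positive")
})

test_that("on a synthetic healthy cohort CM* recentres means and shrinks variance", {
  d <- make_cm_cohort(227, a_age = -0.24, b_sex = -14.8,
                      c_int = 100 + 0.24 * 65 + 14.8 * 0.5, noise_sd = 5,
                      seed = 11)
  m <- fit_agesex(d)
  star <- cm_star(d$value, d$age, d$sex, m, "putamen")
  expect_lt(abs(mean(star) - 100), 1)
  expect_lte(var(star), var(d$value))
})

test_that("deficit classification applies the strict lowest-side rule", {
  res <- classify_deficit(c(80, 75, 120), c(74.9, 75, 110))
  expect_equal(res$label, c("deficit", "no-deficit", "no-deficit"))
  expect_equal(res$value, c(74.9, 75, 110))
  expect_error(classify_deficit(c(80, NA), c(70, 70)), "both sides")
  expect_error(classify_deficit(80, c(70, 60)), "equal length")
  # monotone: raising either side never flips no-deficit -> deficit
  grid <- expand.grid(l = seq(60, 90, 5), r = seq(60, 90, 5))
  base <- classify_deficit(grid$l, grid$r)$label
  up <- classify_deficit(grid$l + 10, grid$r)$label
  expect_true(all(!(base == "no-deficit" & up == "deficit")))
})

test_that("cohort classification joins sides by subject and session", {
  cmtab <- rbind(
    make_sbr_table(c("a", "b"), "ioflupane", c(80, 60), region = "putamen",
                   side = "left"),
    make_sbr_table(c("a", "b"), "ioflupane", c(90, 95), region = "putamen",
                   side = "right"))
  lab <- classify_cohort(cmtab)
  expect_equal(lab$label[lab$subject == "a"], "no-deficit")
  expect_equal(lab$label[lab$subject == "b"], "deficit")
  expect_equal(lab$value, c(80, 60))
  one_side <- cmtab[cmtab$side == "left", ]
  expect_error(classify_cohort(one_side), "both sides")
})

test_that("Cohen's kappa matches brute-force contingency enumeration", {
  keyed <- function(labels) data.frame(
    subject = sprintf("s%03d", seq_along(labels)), session_years = 0,
    label = labels, stringsAsFactors = FALSE)
  # identical sets: perfect agreement
  la <- keyed(rep(c("deficit", "no-deficit"), c(10, 5)))
  r <- concordance(la, la)
  expect_equal(r$agreement, 100)
  expect_equal(r$kappa, 1)
  # enumerated 2x2 tables against an independent direct computation
  for (cell in list(c(45, 5, 3, 2), c(10, 10, 0, 0), c(30, 2, 8, 1),
                    c(1, 1, 1, 1))) {
    dd <- cell[1]; nn <- cell[2]; dn <- cell[3]; nd <- cell[4]
    n <- sum(cell)
    a_lab <- rep(c("deficit", "no-deficit", "deficit", "no-deficit"), cell)
    b_lab <- rep(c("deficit", "no-deficit", "no-deficit", "deficit"), cell)
    r <- concordance(keyed(a_lab), keyed(b_lab))
    po <- (dd + nn) / n
    pe <- ((dd + dn) / n) * ((dd + nd) / n) +
      ((nn + nd) / n) * ((nn + dn) / n)
    expect_equal(r$agreement, 100 * po, tolerance = 1e-12)
    expect_equal(r$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
    expect_gte(r$kappa, -1); expect_lte(r$kappa, 1)
  }
  # independent random labels: kappa near zero at large n
  set.seed(5)
  ra <- keyed(sample(c("deficit", "no-deficit"), 4000, replace = TRUE))
  rb <- ra; rb$label <- sample(rb$label)
  expect_lt(abs(concordance(ra, rb)$kappa), 0.05)
  # both raters constant and identical: kappa defined as 1
  ca <- keyed(rep("deficit", 8))
  expect_equal(concordance(ca, ca)$kappa, 1)
  # disjoint keys are an error
  cb <- ca; cb$subject <- paste0("x", cb$subject)
  expect_error(concordance(ca, cb), "no .subject, session. keys")
})

test_that("annualized change recovers linear declines", {
  two_pt <- rbind(
    make_sbr_table("s1", "ioflupane", 100, session_years = 0),
    make_sbr_table("s1", "ioflupane", 93, session_years = 1))
  res <- annual_change(two_pt)
  expect_equal(res$abs_change_per_yr, -7)
  expect_equal(res$pct_change_per_yr, -7)
  # zero-noise flat trajectories give exactly zero slopes
  flat <- rbind(
    make_sbr_table(c("s1", "s2"), "ioflupane", 90, session_years = 0),
    make_sbr_table(c("s1", "s2"), "ioflupane", 90, session_years = 1),
    make_sbr_table(c("s1", "s2"), "ioflupane", 90, session_years = 2))
  expect_equal(annual_change(flat)$abs_change_per_yr, 0)
  # single-timepoint-only input is an error
  expect_error(annual_change(two_pt[1, ]), "timepoints")
  # per-subject percent convention is available behind the switch
  res2 <- annual_change(two_pt, percent = "per_subject")
  expect_equal(res2$pct_change_per_yr, -7)
})
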