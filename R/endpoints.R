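# Derived endpoints: age/sex-corrected Centamines (CM*), dopaminergic-deficit
# classification with cross-tracer concordance, and annualized longitudinal
# change.

#' Fit the age/sex correction model on healthy-control Centamines
#'
#' Per-region ordinary least squares `CM = a x age + b x sex + c` on
#' healthy-control Centamine values, with sex coded 0 for female and 1 for
#' male subjects.
#'
#' @param hc_cm A CM table (columns `subject`, `tracer`, `session_years`,
#'   `age`, `sex`, `region`, `side`, `value`) of healthy controls only.
#' @param regions Regions to fit (default: all present).
#' @param side Side policy (default "bilateral").
#' @return A `cm_agesex` object: data frame `region`, `a_age`, `b_sex`,
#'   `c_intercept`, `se_age`, `se_sex`, `r2`, `n`, with the CM* anchor (age
#'   65, sex 0.5) as attributes.
#' @export
fit_agesex <- function(hc_cm, regions = NULL, side = "bilateral") {
  check_sbr_table(hc_cm)
  if (!all(c("age", "sex") %in% names(hc_cm)))
    stop("CM table must contain `age` and `sex` columns", call. = FALSE)
  d <- hc_cm[hc_cm$side == side, , drop = FALSE]
  if (is.null(regions)) regions <- unique(d$region)
  rows <- lapply(regions, function(r) {
    dr <- d[d$region == r, , drop = FALSE]
    if (nrow(dr) < 4L)
      stop("need at least 4 records for region '", r, "'", call. = FALSE)
    if (stats::var(dr$age) < 1e-12)
      stop("age has no variation in region '", r, "'", call. = FALSE)
    if (length(unique(dr$sex)) < 2L)
      stop("sex effect unidentifiable in region '", r,
           "': only one sex present", call. = FALSE)
    fit <- stats::lm(value ~ age + sex, data = dr)
    cf <- stats::coef(fit)
    se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
    data.frame(region = r, a_age = unname(cf["age"]),
               b_sex = unname(cf["sex"]), c_intercept = unname(cf[1]),
               se_age = unname(se["age"]), se_sex = unname(se["sex"]),
               r2 = suppressWarnings(summary(fit))$r.squared, n = nrow(dr),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("cm_agesex", "data.frame"),
            anchor_age = 65, anchor_sex = 0.5)
}

#' @export
print.cm_agesex <- function(x, ...) {
  cat(sprintf("<cm_agesex> CM ~ age + sex (anchor: age %g, sex %g)\n",
              attr(x, "anchor_age"), attr(x, "anchor_sex")))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.cm_agesex <- function(object, ...) {
  m <- as.matrix(object[, c("a_age", "b_sex", "c_intercept")])
  rownames(m) <- object$region
  m
}

agesex_row <- function(model, region) {
  i <- match(region, model$region)
  if (is.na(i))
    stop("region '", region, "' not present in age/sex model", call. = FALSE)
  model[i, , drop = FALSE]
}

#' Age/sex-corrected Centamine (CM*)
#'
#' Rescales an individual's Centamine value by the ratio of the model-expected
#' CM for the anchor person (age 65, sex-average 0.5) to the model-expected CM
#' for the subject's own age and sex:
#' `CM* = CM x (a x 65 + b x 0.5 + c) / (a x age + b x sex + c)`.
#'
#' @param cm Centamine value(s) in percent.
#' @param age Age(s) at scan in years.
#' @param sex Sex coding (0 = female, 1 = male).
#' @param model A `cm_agesex` model.
#' @param region Region name (must be in the model).
#' @return CM* value(s) in percent.
#' @export
cm_star <- function(cm, age, sex, model, region) {
  stopifnot(inherits(model, "cm_agesex"))
  row <- agesex_row(model, region)
  num <- row$a_age * attr(model, "anchor_age") +
    row$b_sex * attr(model, "anchor_sex") + row$c_intercept
  den <- row$a_age * age + row$b_sex * sex + row$c_intercept
  if (any(den <= 0))
    stop("expected CM is not positive at the requested age/sex; ",
         "model extrapolated beyond validity", call. = FALSE)
  cm * num / den
}

#' Classify dopaminergic deficit from lowest-sided putamen CM*
#'
#' The deciding value is the minimum of the left and right putamen CM*; the
#' label is "deficit" when that value lies strictly below the threshold (the
#' boundary itself classifies as "no-deficit").
#'
#' @param cm_star_left,cm_star_right Per-side putamen CM* values (vectors).
#' @param threshold Classification threshold in percent (default 75).
#' @return A data frame with `value` (deciding value), `label` ("deficit" or
#'   "no-deficit") and `threshold`.
#' @export
classify_deficit <- function(cm_star_left, cm_star_right, threshold = 75) {
  if (length(cm_star_left) != length(cm_star_right))
    stop("left and right inputs must have equal length", call. = FALSE)
  if (anyNA(cm_star_left) || anyNA(cm_star_right))
    stop("both sides must be present (no missing values)", call. = FALSE)
  value <- pmin(cm_star_left, cm_star_right)
  data.frame(value = value,
             label = ifelse(value < threshold, "deficit", "no-deficit"),
             threshold = threshold, stringsAsFactors = FALSE)
}

#' Deficit labels for a cohort CM* table
#'
#' Applies [classify_deficit()] to each (subject, tracer, session) using the
#' left and right records of the given region.
#'
#' @param cm_table A CM* table with left/right records.
#' @param region Region used for classification (default "putamen").
#' @param threshold Threshold in percent (default 75).
#' @return A data frame with `subject`, `tracer`, `session_years`, `value`,
#'   `label`, `threshold`.
#' @export
classify_cohort <- function(cm_table, region = "putamen", threshold = 75) {
  check_sbr_table(cm_table)
  d <- cm_table[cm_table$region == region &
                  cm_table$side %in% c("left", "right"), , drop = FALSE]
  wide <- stats::reshape(
    d[, c("subject", "tracer", "session_years", "side", "value")],
    direction = "wide", idvar = c("subject", "tracer", "session_years"),
    timevar = "side")
  if (!all(c("value.left", "value.right") %in% names(wide)))
    stop("both sides must be present for region '", region, "'",
         call. = FALSE)
  cls <- classify_deficit(wide$value.left, wide$value.right, threshold)
  data.frame(wide[, c("subject", "tracer", "session_years")], cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Agreement and Cohen's kappa between two label sets
#'
#' Joins the label sets on (subject, session) and computes the percent
#' agreement and Cohen's kappa with chance agreement from the marginal label
#' frequencies.  When both raters are constant and identical (chance
#' agreement 1), kappa is defined as 1.
#'
#' @param labels_a,labels_b Data frames with `subject`, `session_years`,
#'   `label` (e.g. from [classify_cohort()]).
#' @return A list with `agreement` (percent) and `kappa`.
#' @export
concordance <- function(labels_a, labels_b) {
  need <- c("subject", "session_years", "label")
  stopifnot(all(need %in% names(labels_a)), all(need %in% names(labels_b)))
  m <- merge(labels_a[, need], labels_b[, need],
             by = c("subject", "session_years"), suffixes = c("_a", "_b"))
  if (!nrow(m))
    stop("label sets share no (subject, session) keys", call. = FALSE)
  po <- mean(m$label_a == m$label_b)
  levs <- union(m$label_a, m$label_b)
  pa <- table(factor(m$label_a, levs)) / nrow(m)
  pb <- table(factor(m$label_b, levs)) / nrow(m)
  pe <- sum(pa * pb)
  kappa <- if (abs(1 - pe) < 1e-12) 1 else (po - pe) / (1 - pe)
  list(agreement = 100 * po, kappa = kappa)
}

#' Annualized Centamine change
#'
#' Per subject and region, the slope of an ordinary least-squares line of CM
#' against years from baseline; the group absolute change is the mean of the
#' per-subject slopes and the percent change per annum divides that mean by
#' the group mean baseline CM (or, optionally, averages per-subject percent
#' slopes).
#'
#' @param cm_long A longitudinal CM table.
#' @param regions Regions to analyze (default: all present).
#' @param side Side policy (default "bilateral").
#' @param percent Denominator convention: "group_baseline" (default) or
#'   "per_subject".
#' @return A data frame with `region`, `n_subjects`, `abs_change_per_yr`,
#'   `pct_change_per_yr`.
#' @export
annual_change <- function(cm_long, regions = NULL, side = "bilateral",
                          percent = c("group_baseline", "per_subject")) {
  check_sbr_table(cm_long)
  percent <- match.arg(percent)
  d <- cm_long[cm_long$side == side, , drop = FALSE]
  if (is.null(regions)) regions <- unique(d$region)
  rows <- lapply(regions, function(r) {
    dr <- d[d$region == r, , drop = FALSE]
    slopes <- c(); baselines <- c()
    for (s in unique(dr$subject)) {
      ds <- dr[dr$subject == s, , drop = FALSE]
      if (length(unique(ds$session_years)) < 2L) next
      t <- ds$session_years; y <- ds$value
      slope <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
      slopes <- c(slopes, slope)
      baselines <- c(baselines, y[which.min(t)])
    }
    if (!length(slopes))
      stop("no subject has >= 2 timepoints in region '", r, "'",
           call. = FALSE)
    abs_change <- mean(slopes)
    pct <- if (percent == "group_baseline") {
      100 * abs_change / mean(baselines)
    } else {
      mean(100 * slopes / baselines)
    }
    data.frame(region = r, n_subjects = length(slopes),
               abs_change_per_yr = abs_change, pct_change_per_yr = pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
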