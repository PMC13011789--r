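# Three-level Centamine calibration.
#
# Level 1 defines the scale from healthy-control reference-tracer SBR values:
# CM = 100 x SBR / mu_HC, so 100% is the mean healthy-control specific
# binding and 0% is absent specific binding.  Level 2 maps a new tracer via
# per-region ordinary least squares on head-to-head data against the
# reference tracer, giving SBR anchors at CM 0% (the intercept) and CM 100%
# (slope x mu_HC + intercept).  Level 3 chains a further tracer through an
# existing level-2 mapping by transforming that mapping's anchors.

check_sbr_table <- function(x) {
  need <- c("subject", "tracer", "session_years", "region", "side", "value")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("expected a long-format table with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Level-1 anchors: define the Centamine scale from healthy controls
#'
#' Computes the per-region mean, standard deviation and count of
#' reference-tracer SBR values in a healthy-control cohort.  The SBR anchor
#' at CM 0% is exactly 0 and the anchor at CM 100% is the healthy-control
#' mean.
#'
#' @param hc An SBR table containing a single (reference) tracer.
#' @param regions Regions to anchor (default: all present).
#' @param side Side policy used for anchoring (default "bilateral").
#' @return A `cm_anchors` object: data frame `region`, `mu`, `sd`, `n` with
#'   the tracer as an attribute.
#' @examples
#' hc <- data.frame(subject = c("a", "b"), tracer = "ioflupane",
#'                  session_years = 0, region = "striatum",
#'                  side = "bilateral", value = c(1.3, 1.5))
#' level1_anchors(hc)
#' @export
level1_anchors <- function(hc, regions = NULL, side = "bilateral") {
  check_sbr_table(hc)
  tracers <- unique(hc$tracer)
  if (length(tracers) != 1L)
    stop("level-1 table must contain exactly one (reference) tracer; found: ",
         paste(tracers, collapse = ", "), call. = FALSE)
  d <- hc[hc$side == side, , drop = FALSE]
  if (is.null(regions)) regions <- unique(d$region)
  tab <- lapply(regions, function(r) {
    v <- d$value[d$region == r]
    if (length(v) < 2L)
      stop("need at least 2 healthy-control records for region '", r, "'",
           call. = FALSE)
    data.frame(region = r, mu = mean(v), sd = stats::sd(v), n = length(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tab)
  if (any(out$mu <= 0))
    stop("healthy-control mean SBR must be positive", call. = FALSE)
  structure(out, class = c("cm_anchors", "data.frame"),
            tracer = tracers, side = side)
}

#' @export
print.cm_anchors <- function(x, ...) {
  cat(sprintf("<cm_anchors> Centamine level-1 anchors (%s, %s)\n",
              attr(x, "tracer"), attr(x, "side")))
  df <- as.data.frame(x)
  df$cm0_sbr <- 0
  df$cm100_sbr <- df$mu
  print.data.frame(df, row.names = FALSE, digits = 4)
  invisible(x)
}

anchor_mu <- function(anchors, region) {
  i <- match(region, anchors$region)
  if (anyNA(i))
    stop("region(s) not present in anchors: ",
         paste(region[is.na(i)], collapse = ", "), call. = FALSE)
  anchors$mu[i]
}

#' Convert reference-tracer SBR to Centamines
#'
#' `CM = 100 x SBR / mu_HC` for the given region.  Values below 0 or above
#' 100 are legal (linear extrapolation) and reported as-is.
#'
#' @param sbr Numeric SBR value(s).
#' @param anchors A `cm_anchors` object.
#' @param region Region name (scalar or vectorized alongside `sbr`).
#' @return Centamine value(s) in percent.
#' @export
cm_reference <- function(sbr, anchors, region) {
  stopifnot(inherits(anchors, "cm_anchors"))
  mu <- anchor_mu(anchors, region)
  if (any(mu <= 0)) stop("mu_HC must be positive", call. = FALSE)
  100 * sbr / mu
}

# Pair head-to-head records of two tracers on (subject, session) within a
# matching window (years).
match_pairs <- function(pairs, tracer_x, tracer_y, region, side,
                        window_years) {
  a <- pairs[pairs$tracer == tracer_x & pairs$region == region &
               pairs$side == side, , drop = FALSE]
  b <- pairs[pairs$tracer == tracer_y & pairs$region == region &
               pairs$side == side, , drop = FALSE]
  m <- merge(a[, c("subject", "session_years", "value")],
             b[, c("subject", "session_years", "value")],
             by = "subject", suffixes = c("_x", "_y"))
  m <- m[abs(m$session_years_x - m$session_years_y) <= window_years, ,
         drop = FALSE]
  m
}

new_mapping <- function(table, tracer, upstream, level, reference_tracer) {
  structure(list(tracer = tracer, upstream = upstream, level = level,
                 reference_tracer = reference_tracer, table = table),
            class = "cm_mapping")
}

#' Level-2 calibration: map a tracer onto the Centamine scale
#'
#' Per-region ordinary least squares of the new tracer's SBR on the reference
#' tracer's SBR over head-to-head pairs matched on subject and session (all
#' available paired sessions treated as independent points).  Anchors follow
#' from the fit: `SBR@CM0 = b` and `SBR@CM100 = a x mu_HC + b`.  A
#' non-positive slope flags the region's mapping invalid.
#'
#' @param pairs An SBR table containing both tracers.
#' @param anchors Level-1 `cm_anchors` for the reference tracer.
#' @param new_tracer Tracer id being calibrated.
#' @param reference_tracer Reference tracer id (default: the anchors' tracer).
#' @param regions Regions to fit (default: the anchors' regions).
#' @param side Side policy (default "bilateral").
#' @param window_years Maximum |session difference| for a pair (default 100
#'   days).
#' @param one_pair_per_subject If TRUE, keep only each subject's first pair
#'   (subject-level clustering sensitivity analysis); default FALSE.
#' @return A `cm_mapping` with per-region slope `a`, intercept `b`, 95%
#'   confidence intervals, `r2`, `n`, anchors `sbr_cm0`/`sbr_cm100`,
#'   composite coefficients to the reference scale, and a `valid` flag.
#' @export
fit_level2 <- function(pairs, anchors, new_tracer,
                       reference_tracer = attr(anchors, "tracer"),
                       regions = anchors$region, side = "bilateral",
                       window_years = 100 / 365.25,
                       one_pair_per_subject = FALSE) {
  check_sbr_table(pairs)
  stopifnot(inherits(anchors, "cm_anchors"))
  rows <- lapply(regions, function(r) {
    m <- match_pairs(pairs, reference_tracer, new_tracer, r, side,
                     window_years)
    if (one_pair_per_subject)
      m <- m[!duplicated(m$subject), , drop = FALSE]
    if (nrow(m) < 3L)
      stop("need at least 3 complete pairs for region '", r, "'",
           call. = FALSE)
    if (stats::var(m$value_x) < 1e-12)
      stop("degenerate reference-tracer variance in region '", r, "'",
           call. = FALSE)
    fit <- stats::lm(value_y ~ value_x, data = m)
    ci <- suppressWarnings(stats::confint(fit, level = 0.95))
    a <- unname(stats::coef(fit)[2])
    b <- unname(stats::coef(fit)[1])
    mu <- anchor_mu(anchors, r)
    data.frame(region = r, a = a, b = b,
               a_lo = ci[2, 1], a_hi = ci[2, 2],
               b_lo = ci[1, 1], b_hi = ci[1, 2],
               r2 = suppressWarnings(summary(fit))$r.squared, n = nrow(m),
               mu_hc = mu,
               sbr_cm0 = b, sbr_cm100 = a * mu + b,
               composite_a = a, composite_b = b,
               valid = a > 0, stringsAsFactors = FALSE)
  })
  new_mapping(do.call(rbind, rows), new_tracer, reference_tracer, 2L,
              reference_tracer)
}

#' Construct a level-2 mapping directly from known coefficients
#'
#' Builds the mapping and its anchors from externally supplied per-region
#' slope/intercept values and level-1 healthy-control means, e.g. published
#' calibration coefficients.  `SBR@CM0 = b`; `SBR@CM100 = a x mu_hc + b`.
#'
#' @param region,a,b,mu_hc Equal-length vectors of region names, slopes,
#'   intercepts and healthy-control mean SBRs.
#' @param tracer,reference_tracer Tracer ids.
#' @return A `cm_mapping` (confidence intervals and fit statistics `NA`).
#' @export
mapping_from_coefficients <- function(region, a, b, mu_hc,
                                      tracer = "tracerX",
                                      reference_tracer = "ioflupane") {
  stopifnot(length(region) == length(a), length(a) == length(b),
            length(b) == length(mu_hc))
  tab <- data.frame(region = region, a = a, b = b,
                    a_lo = NA_real_, a_hi = NA_real_,
                    b_lo = NA_real_, b_hi = NA_real_,
                    r2 = NA_real_, n = NA_integer_, mu_hc = mu_hc,
                    sbr_cm0 = b, sbr_cm100 = a * mu_hc + b,
                    composite_a = a, composite_b = b,
                    valid = a > 0, stringsAsFactors = FALSE)
  new_mapping(tab, tracer, reference_tracer, 2L, reference_tracer)
}

#' Level-3 calibration: chain a tracer through an existing mapping
#'
#' Per-region ordinary least squares of the new tracer's SBR on the SBR of an
#' already-calibrated (level-2) tracer; the new anchors are the upstream
#' anchors pushed through the fitted line, and the composite coefficients to
#' the reference scale are the algebraic composition of both regressions.
#'
#' @param pairs An SBR table containing both tracers.
#' @param mapping_x The upstream tracer's `cm_mapping` (all regions valid).
#' @param new_tracer Tracer id being calibrated.
#' @param regions,side,window_years,one_pair_per_subject As [fit_level2()].
#' @return A `cm_mapping` with `level = 3`.
#' @export
fit_level3 <- function(pairs, mapping_x, new_tracer,
                       regions = mapping_x$table$region, side = "bilateral",
                       window_years = 100 / 365.25,
                       one_pair_per_subject = FALSE) {
  check_sbr_table(pairs)
  stopifnot(inherits(mapping_x, "cm_mapping"))
  if (!all(mapping_x$table$valid))
    stop("upstream mapping has invalid regions", call. = FALSE)
  rows <- lapply(regions, function(r) {
    up <- mapping_x$table[mapping_x$table$region == r, , drop = FALSE]
    if (!nrow(up))
      stop("region '", r, "' missing from upstream mapping", call. = FALSE)
    m <- match_pairs(pairs, mapping_x$tracer, new_tracer, r, side,
                     window_years)
    if (one_pair_per_subject)
      m <- m[!duplicated(m$subject), , drop = FALSE]
    if (nrow(m) < 3L)
      stop("need at least 3 complete pairs for region '", r, "'",
           call. = FALSE)
    if (stats::var(m$value_x) < 1e-12)
      stop("degenerate upstream-tracer variance in region '", r, "'",
           call. = FALSE)
    fit <- stats::lm(value_y ~ value_x, data = m)
    ci <- suppressWarnings(stats::confint(fit, level = 0.95))
    a <- unname(stats::coef(fit)[2])
    b <- unname(stats::coef(fit)[1])
    data.frame(region = r, a = a, b = b,
               a_lo = ci[2, 1], a_hi = ci[2, 2],
               b_lo = ci[1, 1], b_hi = ci[1, 2],
               r2 = suppressWarnings(summary(fit))$r.squared, n = nrow(m),
               mu_hc = up$mu_hc,
               sbr_cm0 = a * up$sbr_cm0 + b,
               sbr_cm100 = a * up$sbr_cm100 + b,
               composite_a = a * up$composite_a,
               composite_b = a * up$composite_b + b,
               valid = a > 0, stringsAsFactors = FALSE)
  })
  new_mapping(do.call(rbind, rows), new_tracer, mapping_x$tracer, 3L,
              mapping_x$reference_tracer)
}

#' Convert a calibrated tracer's SBR to Centamines
#'
#' `CM = 100 x (SBR - SBR@CM0) / (SBR@CM100 - SBR@CM0)` using the mapping's
#' per-region anchors; for a level-3 mapping this equals the composed form
#' through the upstream tracer.  Values outside `[0, 100]` are legal and
#' reported as-is.
#'
#' @param sbr Numeric SBR value(s).
#' @param mapping A `cm_mapping`.
#' @param region Region name (scalar or vectorized alongside `sbr`).
#' @return Centamine value(s) in percent.
#' @export
cm_mapped <- function(sbr, mapping, region) {
  stopifnot(inherits(mapping, "cm_mapping"))
  i <- match(region, mapping$table$region)
  if (anyNA(i))
    stop("region(s) not present in mapping: ",
         paste(region[is.na(i)], collapse = ", "), call. = FALSE)
  if (!all(mapping$table$valid[i]))
    stop("mapping flagged invalid (non-positive slope) for region(s): ",
         paste(unique(region[!mapping$table$valid[i]]), collapse = ", "),
         call. = FALSE)
  cm0 <- mapping$table$sbr_cm0[i]
  gap <- mapping$table$sbr_cm100[i] - cm0
  if (any(gap <= 0))
    stop("anchor gap must be positive", call. = FALSE)
  100 * (sbr - cm0) / gap
}

#' @export
print.cm_mapping <- function(x, ...) {
  cat(sprintf("<cm_mapping> %s onto the Centamine scale (level %d via %s)\n",
              x$tracer, x$level, x$upstream))
  cols <- c("region", "a", "b", "r2", "n", "sbr_cm0", "sbr_cm100", "valid")
  print.data.frame(x$table[, cols], row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.cm_mapping <- function(object, ...) {
  cat(sprintf("Centamine level-%d mapping: %s (upstream: %s, reference: %s)\n",
              object$level, object$tracer, object$upstream,
              object$reference_tracer))
  tab <- object$table
  tab$a_ci <- sprintf("[%.2f, %.2f]", tab$a_lo, tab$a_hi)
  tab$b_ci <- sprintf("[%.2f, %.2f]", tab$b_lo, tab$b_hi)
  tab$sbr_cm0 <- round_half_up(tab$sbr_cm0, 2)
  tab$sbr_cm100 <- round_half_up(tab$sbr_cm100, 2)
  print.data.frame(tab[, c("region", "a", "a_ci", "b", "b_ci", "r2", "n",
                           "sbr_cm0", "sbr_cm100", "valid")],
                   row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
coef.cm_mapping <- function(object, ...) {
  stats::setNames(
    split(object$table[, c("a", "b")], seq_len(nrow(object$table))),
    object$table$region)
}

#' Predict Centamine values from a mapping
#' @param object A `cm_mapping`.
#' @param sbr Numeric SBR values.
#' @param region Region name(s).
#' @param ... Unused.
#' @return Centamine values in percent.
#' @export
predict.cm_mapping <- function(object, sbr, region, ...) {
  cm_mapped(sbr, object, region)
}

#' Calibrate an independent analysis pipeline into Centamines
#'
#' Per-region ordinary least squares of provided Centamine values on the new
#' pipeline's own SBR values over jointly processed scans, giving a direct
#' SBR-to-CM mapping for that pipeline, plus an alignment report (mean
#' absolute CM difference after calibration).
#'
#' @param own_sbr SBR table from the new pipeline.
#' @param provided_cm CM table (same key structure, `value` in percent).
#' @param regions Regions to calibrate (default: those shared).
#' @param side Side policy.
#' @return A `cm_pipeline_calibration`: data frame `region`, `slope`,
#'   `intercept`, `r2`, `n`, `alignment_mae`.
#' @export
calibrate_pipeline <- function(own_sbr, provided_cm, regions = NULL,
                               side = "bilateral") {
  check_sbr_table(own_sbr)
  check_sbr_table(provided_cm)
  a <- own_sbr[own_sbr$side == side, , drop = FALSE]
  b <- provided_cm[provided_cm$side == side, , drop = FALSE]
  m <- merge(a[, c("subject", "session_years", "region", "value")],
             b[, c("subject", "session_years", "region", "value")],
             by = c("subject", "session_years", "region"),
             suffixes = c("_sbr", "_cm"))
  if (!nrow(m))
    stop("no overlapping (subject, session, region) records", call. = FALSE)
  if (is.null(regions)) regions <- unique(m$region)
  rows <- lapply(regions, function(r) {
    d <- m[m$region == r, , drop = FALSE]
    if (nrow(d) < 3L)
      stop("need at least 3 joint records for region '", r, "'",
           call. = FALSE)
    fit <- stats::lm(value_cm ~ value_sbr, data = d)
    data.frame(region = r,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r2 = suppressWarnings(summary(fit))$r.squared, n = nrow(d),
               alignment_mae = mean(abs(stats::residuals(fit))),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("cm_pipeline_calibration", "data.frame"))
}

#' @export
print.cm_pipeline_calibration <- function(x, ...) {
  cat("<cm_pipeline_calibration> per-region SBR -> Centamine mapping\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
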