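# Spatial normalization: affine registration of a scan to a nonnegative
# linear combination of the 17-template bank, weighted towards the basal
# ganglia.

# Lawson-Hanson active-set nonnegative least squares on the normal equations:
# minimises ||A x - b||^2 subject to x >= 0 given G = A'A and atb = A'b.
# Problem sizes here are tiny (17-23 unknowns) while the row dimension is an
# image, so working on the Gram matrix avoids refactorising the dense design.
nnls_gram <- function(gram, atb, tol = NULL, max_iter = NULL) {
  n <- length(atb)
  if (is.null(tol)) tol <- 1e-10 * max(abs(atb), 1)
  if (is.null(max_iter)) max_iter <- 30L * n
  x <- numeric(n)
  passive <- rep(FALSE, n)
  solve_passive <- function(p) {
    gp <- gram[p, p, drop = FALSE]
    out <- tryCatch(solve(gp, atb[p]),
                    error = function(e)
                      solve(gp + diag(1e-10 * max(diag(gp)), sum(p)), atb[p]))
    out
  }
  iter <- 0L
  repeat {
    w <- atb - as.vector(gram %*% x)
    free <- which(!passive)
    if (!length(free) || max(w[free]) <= tol) break
    passive[free[which.max(w[free])]] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(pmax(x, 0))
      s <- numeric(n)
      s[passive] <- solve_passive(passive)
      if (min(s[passive]) > 0) { x <- s; break }
      drop_set <- passive & s <= 0
      alpha <- min(x[drop_set] / (x[drop_set] - s[drop_set]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
  }
  x
}

#' Basal-ganglia weighting image for registration
#'
#' A smooth nonnegative weight map used in the registration cost: baseline
#' weight inside the head, elevated over the (smoothly dilated) basal-ganglia
#' union, and zero outside the head.  The elevation saturates over the
#' basal-ganglia cores, so the maximum weight is attained on (among others)
#' putamen voxels.
#'
#' @param atlas A `cm_atlas`.
#' @param w_bg Weight over the basal ganglia (default 10).
#' @param w_baseline Baseline weight inside the head (default 1).
#' @param transition_fwhm_mm Width of the smooth dilation/transition (mm).
#' @return A `cm_volume` of weights.
#' @export
weight_image <- function(atlas, w_bg = 10, w_baseline = 1,
                         transition_fwhm_mm = 8) {
  stopifnot(inherits(atlas, "cm_atlas"))
  head <- atlas$labels > 0L
  bg_codes <- region_codes(atlas, "basal_ganglia", "bilateral")
  bg <- array(as.numeric(atlas$labels %in% bg_codes), dim(atlas$labels))
  sm <- gaussian_smooth(new_volume(bg, atlas$voxel_size_mm),
                        transition_fwhm_mm)$values
  dilated <- array(as.numeric(sm > 0.05), dim(atlas$labels))
  ramp <- gaussian_smooth(new_volume(dilated, atlas$voxel_size_mm),
                          transition_fwhm_mm)$values
  elev <- pmin(1, ramp / 0.6)
  w <- (w_baseline + (w_bg - w_baseline) * elev) * head
  new_volume(array(w, dim(atlas$labels)), atlas$voxel_size_mm)
}

#' Spatially normalize a scan to the template bank
#'
#' Jointly estimates a 12-parameter affine transform and 17 nonnegative
#' template-combination weights (which absorb the global intensity scale) by
#' minimizing the weighted sum of squared differences between the resampled
#' scan and the weighted template combination.  For any candidate affine the
#' combination weights have a closed-form nonnegative least-squares solution,
#' so they are profiled out and a box-bounded quasi-Newton search (L-BFGS-B
#' with numerical gradients) runs on the affine parameters: first a rigid
#' (6-parameter) pass on extra-smoothed images, then a full 12-parameter pass
#' at native smoothness.  The parameter box keeps the search inside
#' plausible transforms; accepted iterations never increase the cost
#' (monotone descent).
#'
#' @param scan A `cm_volume` on the canonical grid (must be non-degenerate).
#' @param bank A `cm_template_bank`.
#' @param weights Optional weighting `cm_volume` (default [weight_image()] of
#'   the bank's atlas).
#' @param control List of optimizer settings: `maxit_rigid`, `maxit_full`,
#'   `factr`, `coarse_fwhm_mm` (extra smoothing for the rigid pass),
#'   `baseline_stride` (thinning of baseline-weight voxels in the cost
#'   quadrature) and the parameter `bounds`.
#' @return A `cm_normalization`: `transform` (pull-back `cm_affine` mapping
#'   canonical coordinates into the scan), `weights` (17 nonnegative
#'   combination weights), `normalized` (the scan resampled onto the canonical
#'   grid), `cost`, `converged`, `qc` flags and the accepted-cost `trace`.
#' @export
register_to_bank <- function(scan, bank, weights = NULL, control = list()) {
  stopifnot(is_volume(scan), inherits(bank, "cm_template_bank"))
  if (all(scan$values == 0))
    stop("degenerate scan: all voxels are zero", call. = FALSE)
  atlas <- bank$atlas
  if (!all(dim(scan) == dim(atlas$labels)))
    stop("scan is not on the template grid", call. = FALSE)
  ctl <- utils::modifyList(list(maxit_rigid = 60, maxit_full = 120,
                                factr = 1e7, coarse_fwhm_mm = 8,
                                baseline_stride = 3L,
                                bounds = list(translation = 25,
                                              rotation = 0.45,
                                              scale = c(0.75, 1.35),
                                              shear = 0.2)),
                           control)
  if (is.null(weights)) weights <- weight_image(atlas)
  idx <- which(weights$values > 0)
  # stratified thinning: keep all elevated (basal-ganglia) voxels, every
  # `baseline_stride`-th baseline voxel (deterministic; a subsampled
  # quadrature of the same weighted cost)
  if (ctl$baseline_stride > 1L) {
    wv <- weights$values[idx]
    elevated <- wv > 1.5 * min(wv)
    keep <- elevated
    base_pos <- which(!elevated)
    keep[base_pos[seq(1L, length(base_pos), by = ctl$baseline_stride)]] <- TRUE
    idx <- idx[keep]
  }
  sqrtw <- sqrt(weights$values[idx])
  coords <- grid_coords_mm(dim(atlas$labels), atlas$voxel_size_mm, idx)

  # optimize on an intensity-normalized copy: the combination weights absorb
  # any global scale, and normalizing makes the optimizer path (and hence
  # the recovered transform) exactly invariant to input scaling
  scan_scale <- sqrt(sum(scan$values^2))
  scan_n <- new_volume(scan$values / scan_scale, scan$voxel_size_mm)

  make_stage <- function(vols, scanvol) {
    tm <- vapply(vols, function(v) v$values[idx] * sqrtw,
                 numeric(length(idx)))
    gram <- crossprod(tm)
    trace_env <- new.env()
    trace_env$best <- Inf
    trace_env$trace <- numeric(0)
    cost_fn <- function(p12) {
      m <- affine_from_params(p12)$matrix
      y <- sample_volume(scanvol, apply_affine_pts(m, coords)) * sqrtw
      atb <- as.vector(crossprod(tm, y))
      x <- nnls_gram(gram, atb)
      cost <- sum(y * y) - 2 * sum(x * atb) +
        as.numeric(t(x) %*% gram %*% x)
      cost <- max(cost, 0)
      if (cost < trace_env$best) {
        trace_env$best <- cost
        trace_env$trace <- c(trace_env$trace, cost)
      }
      cost
    }
    list(cost = cost_fn, gram = gram, tm = tm, trace_env = trace_env)
  }

  # box bounds keep the search inside plausible transforms and exclude the
  # degenerate zero-overlap solution (scan out of view, all weights zero)
  b <- ctl$bounds
  lo <- c(rep(-b$translation, 3), rep(-b$rotation, 3), rep(b$scale[1], 3),
          rep(-b$shear, 3))
  hi <- c(rep(b$translation, 3), rep(b$rotation, 3), rep(b$scale[2], 3),
          rep(b$shear, 3))
  ps <- c(2, 2, 2, 0.02, 0.02, 0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)

  # rigid pass on extra-smoothed images to widen the basin of attraction
  vols_c <- lapply(bank$volumes, gaussian_smooth,
                   fwhm_mm = ctl$coarse_fwhm_mm)
  scan_c <- gaussian_smooth(scan_n, ctl$coarse_fwhm_mm)
  st1 <- make_stage(vols_c, scan_c)
  f6 <- function(q) st1$cost(c(q, 1, 1, 1, 0, 0, 0))
  o1 <- stats::optim(rep(0, 6), f6, method = "L-BFGS-B",
                     lower = lo[1:6], upper = hi[1:6],
                     control = list(maxit = ctl$maxit_rigid,
                                    factr = ctl$factr, parscale = ps[1:6]))

  st2 <- make_stage(bank$volumes, scan_n)
  p0 <- c(o1$par, 1, 1, 1, 0, 0, 0)
  o2 <- stats::optim(p0, st2$cost, method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(maxit = ctl$maxit_full,
                                    factr = ctl$factr, parscale = ps))
  transform <- affine_from_params(o2$par)
  # final combination weights on the original (unnormalized) intensities
  y <- sample_volume(scan, apply_affine_pts(transform$matrix, coords)) * sqrtw
  atb <- as.vector(crossprod(st2$tm, y))
  comb <- nnls_gram(st2$gram, atb)

  qc <- list(
    translation_ok = all(abs(transform$translation) <= 25),
    rotation_ok = all(abs(transform$rotation) <= 0.45),
    scale_ok = all(transform$scale >= 0.75 & transform$scale <= 1.35),
    cost_finite = is.finite(o2$value))
  # L-BFGS-B reports 52 (abnormal line-search termination) when no descent
  # direction exists, e.g. starting at an exact zero-cost minimum; that is
  # convergence, not failure
  opt_ok <- o2$convergence %in% c(0L, 52L)
  structure(list(transform = transform, weights = comb,
                 normalized = resample(scan, transform),
                 cost = o2$value,
                 converged = opt_ok && all(unlist(qc)),
                 qc = qc,
                 trace = st2$trace_env$trace),
            class = "cm_normalization")
}

# Refine an affine against a fixed subject-specific model image (painted
# fitted values, smoothed): profiled global scale, weighted SSD, warm start.
refine_transform <- function(scan, atlas, model_vol, init, weights,
                             control = list()) {
  ctl <- utils::modifyList(list(maxit = 60, factr = 1e7,
                                baseline_stride = 3L,
                                bounds = list(translation = 25,
                                              rotation = 0.45,
                                              scale = c(0.75, 1.35),
                                              shear = 0.2)),
                           control)
  idx <- which(weights$values > 0)
  if (ctl$baseline_stride > 1L) {
    wv <- weights$values[idx]
    elevated <- wv > 1.5 * min(wv)
    keep <- elevated
    base_pos <- which(!elevated)
    keep[base_pos[seq(1L, length(base_pos), by = ctl$baseline_stride)]] <- TRUE
    idx <- idx[keep]
  }
  sqrtw <- sqrt(weights$values[idx])
  coords <- grid_coords_mm(dim(atlas$labels), atlas$voxel_size_mm, idx)
  m_ref <- model_vol$values[idx] * sqrtw
  mtm <- sum(m_ref * m_ref)
  # intensity-normalized copy for an exactly scale-invariant search path
  scan_n <- new_volume(scan$values / sqrt(sum(scan$values^2)),
                       scan$voxel_size_mm)
  cost <- function(p) {
    m <- affine_from_params(p)$matrix
    y <- sample_volume(scan_n, apply_affine_pts(m, coords)) * sqrtw
    s <- if (mtm > 0) sum(y * m_ref) / mtm else 0
    sum((y - s * m_ref)^2)
  }
  b <- ctl$bounds
  lo <- c(rep(-b$translation, 3), rep(-b$rotation, 3), rep(b$scale[1], 3),
          rep(-b$shear, 3))
  hi <- c(rep(b$translation, 3), rep(b$rotation, 3), rep(b$scale[2], 3),
          rep(b$shear, 3))
  p0 <- c(init$translation, init$rotation, init$scale, init$shear)
  o <- stats::optim(p0, cost, method = "L-BFGS-B", lower = lo, upper = hi,
                    control = list(maxit = ctl$maxit, factr = ctl$factr,
                                   parscale = c(2, 2, 2, 0.02, 0.02, 0.02,
                                                0.01, 0.01, 0.01,
                                                0.01, 0.01, 0.01)))
  list(transform = affine_from_params(o$par), cost = o$value,
       converged = o$convergence == 0L)
}

#' Register and quantify one scan against the template bank
#'
#' The full single-scan pipeline: affine registration to the 17-template
#' combination, then alternating refinement in which the forward model is
#' fitted in scan space through the current affine ([fit_template_model()]),
#' a subject-specific model image is painted and smoothed from the fitted
#' values, and the affine is re-optimized against that image.  The
#' subject-specific model can represent regional patterns outside the
#' template span (e.g. anterior-posterior putamen gradients), which tightens
#' the alignment and with it the fitted regional values.  Regional SBR
#' estimates are formed from the final fit.
#'
#' @param scan A `cm_volume` on the canonical grid.
#' @param bank A `cm_template_bank`.
#' @param refine Number of refinement alternations (default 2).
#' @param weights Optional weighting image (default [weight_image()]).
#' @param regions,sides,reference Quantification request, as
#'   [fit_regional_sbr()].
#' @param control Optimizer controls passed to [register_to_bank()].
#' @return A list with `sbr` (data frame region/side/sbr), `fit` (the final
#'   `cm_template_fit`), `registration` (the initial `cm_normalization`) and
#'   `transform` (the refined affine).
#' @export
quantify_scan <- function(scan, bank, refine = 2,
                          weights = NULL,
                          regions = target_regions(),
                          sides = c("left", "right", "bilateral"),
                          reference = "cerebral_white_matter",
                          control = list()) {
  atlas <- bank$atlas
  if (is.null(weights)) weights <- weight_image(atlas)
  reg <- register_to_bank(scan, bank, weights = weights, control = control)
  transform <- reg$transform
  fit <- NULL
  for (it in seq_len(max(0, refine))) {
    fit <- fit_template_model(scan, atlas, transform = transform)
    model_vol <- gaussian_smooth(
      paint_template(atlas, fit$values), fit$fwhm_mm)
    ref <- refine_transform(scan, atlas, model_vol, transform, weights,
                            control)
    transform <- ref$transform
  }
  sb <- fit_regional_sbr(scan, atlas, regions = regions, sides = sides,
                         reference = reference, transform = transform)
  list(sbr = sb, fit = attr(sb, "fit"), registration = reg,
       transform = transform)
}

#' @export
print.cm_normalization <- function(x, ...) {
  cat(sprintf("<cm_normalization> cost %.4g, %sconverged\n", x$cost,
              if (x$converged) "" else "NOT "))
  cat(sprintf("  dominant template: %d (weight %.3g)\n",
              which.max(x$weights), max(x$weights)))
  invisible(x)
}
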