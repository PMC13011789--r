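# Digital striatal phantom: regional-value painting, the 17-member
# disease-stage template bank, forward-model fitting, and synthetic scan
# generation with known ground truth.

# Disease-stage scaling table: fraction of the healthy-control value applied
# to the putamen and caudate (per side) for each of the 17 templates; all
# other regions stay at 100%.
.template_fractions <- matrix(c(
  1.00, 1.00, 1.00, 1.00,
  0.75, 1.00, 1.00, 1.00,
  0.50, 1.00, 1.00, 1.00,
  0.25, 1.00, 1.00, 1.00,
  1.00, 0.75, 1.00, 1.00,
  1.00, 0.50, 1.00, 1.00,
  1.00, 0.25, 1.00, 1.00,
  0.00, 0.00, 1.00, 1.00,
  0.00, 0.00, 0.75, 1.00,
  0.00, 0.00, 0.50, 1.00,
  0.00, 0.00, 0.25, 1.00,
  0.00, 0.00, 1.00, 0.75,
  0.00, 0.00, 1.00, 0.50,
  0.00, 0.00, 1.00, 0.25,
  0.00, 0.00, 0.75, 0.75,
  0.00, 0.00, 0.50, 0.50,
  0.00, 0.00, 0.25, 0.25), ncol = 4, byrow = TRUE,
  dimnames = list(NULL, c("putamen_left", "putamen_right",
                          "caudate_left", "caudate_right")))

#' Disease-stage template scaling specification
#'
#' The 17-row table of putamen/caudate scaling fractions (per hemisphere, as a
#' fraction of the healthy-control regional value) that defines the template
#' bank, together with the smoothing kernel width.  Template 1 is the
#' healthy-control template (all fractions 1); templates 8-17 have zero signal
#' in both putamina with graded caudate loss.
#'
#' @param fwhm_mm Full width at half maximum of the template smoothing kernel
#'   in mm (default 12).
#' @return A `cm_template_spec`: `fractions` (17 x 4 matrix) and `fwhm_mm`.
#' @export
template_spec <- function(fwhm_mm = 12) {
  if (fwhm_mm <= 0) stop("`fwhm_mm` must be positive", call. = FALSE)
  structure(list(fractions = .template_fractions, fwhm_mm = fwhm_mm),
            class = "cm_template_spec")
}

# Default healthy-control SBR by base region name (dimensionless, relative to
# the cerebral white matter reference).  Target-region values follow the
# healthy-control reference anchors (caudate 1.23, pre-commissural putamen
# 1.86, post-commissural putamen 1.33); non-quantified basal-ganglia and
# tissue-class values are plausible fixed configuration.
.default_hc_sbr <- c(
  pre_caudate = 1.23, post_caudate = 1.23,
  pre_dorsal_putamen = 1.86, pre_ventral_putamen = 1.86,
  post_dorsal_putamen = 1.33, post_ventral_putamen = 1.33,
  accumbens = 1.10, globus_pallidus = 0.70, ventral_pallidum = 0.50,
  cerebral_white_matter = 0.00, grey_matter = 0.25,
  csf = -0.75, skull = -0.85, soft_tissue = -0.70)

#' Default healthy-control regional values for an atlas
#'
#' Painted activity values (arbitrary units, white matter = 1) per base
#' region code: `value = 1 + SBR` relative to the cerebral white matter
#' reference.
#'
#' @param atlas A `cm_atlas`.
#' @return Named numeric vector indexed by region code (as character).
#' @export
default_hc_values <- function(atlas) {
  rt <- atlas$region_table
  sbr <- .default_hc_sbr[rt$name]
  if (any(is.na(sbr)))
    stop("no default value for region(s): ",
         paste(rt$name[is.na(sbr)], collapse = ", "), call. = FALSE)
  stats::setNames(1 + as.numeric(sbr), as.character(rt$code))
}

#' Paint an atlas with regional values
#'
#' Each voxel receives exactly the value associated with its base label;
#' background voxels are 0.  This is the (pre-smoothing) forward-model
#' painting step.
#'
#' @param atlas A `cm_atlas`.
#' @param values Named numeric vector of values keyed by region code (as
#'   character); every label present in the atlas must have a value.
#' @return A `cm_volume`.
#' @export
paint_template <- function(atlas, values) {
  stopifnot(inherits(atlas, "cm_atlas"))
  codes <- atlas$region_table$code
  if (is.null(names(values))) {
    if (length(values) != length(codes))
      stop("`values` must be named by region code or have one entry per code",
           call. = FALSE)
    names(values) <- as.character(codes)
  }
  missing <- setdiff(as.character(codes), names(values))
  if (length(missing))
    stop("missing painted value for region code(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  lut <- c(0, as.numeric(values[as.character(codes)]))
  vals <- lut[atlas$labels + 1L]
  new_volume(array(vals, dim(atlas$labels)), atlas$voxel_size_mm)
}

# Multiply a regional-value vector by per-side putamen/caudate fractions
# (template-row style).  `fractions` is a length-4 named vector.
scale_values_by_fractions <- function(atlas, values, fractions) {
  want <- c("putamen_left", "putamen_right", "caudate_left", "caudate_right")
  if (is.null(names(fractions)) && length(fractions) == 4L)
    names(fractions) <- want
  if (!all(want %in% names(fractions)))
    stop("`fractions` must contain ", paste(want, collapse = ", "),
         call. = FALSE)
  if (any(fractions < 0 | fractions > 1))
    stop("deficit fractions must lie in [0, 1]", call. = FALSE)
  out <- values
  for (side in c("left", "right")) {
    pc <- as.character(region_codes(atlas, "putamen", side))
    cc <- as.character(region_codes(atlas, "caudate", side))
    out[pc] <- out[pc] * fractions[[paste0("putamen_", side)]]
    out[cc] <- out[cc] * fractions[[paste0("caudate_", side)]]
  }
  out
}

#' Build the 17-member disease-stage template bank
#'
#' For each row of the scaling specification, the healthy-control regional
#' values are scaled in the putamen and caudate (per hemisphere), painted into
#' the atlas, and convolved with the Gaussian kernel.  Template 1 equals the
#' healthy-control template.
#'
#' @param atlas A `cm_atlas`.
#' @param hc_values Healthy-control regional values keyed by region code
#'   (default [default_hc_values()]).
#' @param spec A `cm_template_spec` (default [template_spec()]).
#' @return A `cm_template_bank`: the atlas, spec, `hc_values`, the 23 x 17
#'   pre-smoothing value matrix, and the 17 smoothed template volumes.
#' @export
build_template_bank <- function(atlas, hc_values = default_hc_values(atlas),
                                spec = template_spec()) {
  stopifnot(inherits(atlas, "cm_atlas"), inherits(spec, "cm_template_spec"))
  if (nrow(spec$fractions) != 17L)
    stop("template specification must have exactly 17 rows", call. = FALSE)
  codes <- as.character(atlas$region_table$code)
  vmat <- matrix(NA_real_, length(codes), 17,
                 dimnames = list(codes, NULL))
  volumes <- vector("list", 17)
  for (k in 1:17) {
    vk <- scale_values_by_fractions(atlas, hc_values[codes],
                                    spec$fractions[k, ])
    vmat[, k] <- vk
    volumes[[k]] <- gaussian_smooth(paint_template(atlas, vk), spec$fwhm_mm)
  }
  structure(list(atlas = atlas, spec = spec, hc_values = hc_values[codes],
                 values = vmat, volumes = volumes),
            class = "cm_template_bank")
}

#' @export
print.cm_template_bank <- function(x, ...) {
  cat(sprintf("<cm_template_bank> 17 templates, fwhm %.1f mm, grid %s\n",
              x$spec$fwhm_mm, paste(dim(x$atlas$labels), collapse = " x ")))
  invisible(x)
}

# ---- forward-model fitting --------------------------------------------------

.basis_cache <- new.env(parent = emptyenv())

# Fitting mask: head voxels dilated by one smoothing width so spill-out is
# captured.  Cached per atlas.
fit_mask_idx <- function(atlas, fwhm_mm) {
  key <- paste0(atlas$hash, "-mask-", round(fwhm_mm, 2))
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])
  head <- new_volume(array(as.numeric(atlas$labels > 0L), dim(atlas$labels)),
                     atlas$voxel_size_mm)
  dil <- gaussian_smooth(head, fwhm_mm)
  idx <- which(dil$values > 1e-4)
  .basis_cache[[key]] <- idx
  idx
}

# Smooth a single region indicator, restricted to its bounding box padded by
# the kernel radius: exact, because the indicator is zero outside the box.
smooth_indicator <- function(atlas, code, fwhm_mm) {
  d <- dim(atlas$labels)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  hit <- which(atlas$labels == code)
  out <- array(0, d)
  if (!length(hit)) return(out)
  i <- (hit - 1L) %% d[1] + 1L
  j <- ((hit - 1L) %/% d[1]) %% d[2] + 1L
  k <- (hit - 1L) %/% (d[1] * d[2]) + 1L
  rng <- list(range(i), range(j), range(k))
  lo <- integer(3); hi <- integer(3)
  for (a in 1:3) {
    pad <- as.integer(ceiling(4 * sigma_mm / atlas$voxel_size_mm[a])) + 1L
    lo[a] <- max(1L, rng[[a]][1] - pad)
    hi[a] <- min(d[a], rng[[a]][2] + pad)
  }
  sub <- array(as.numeric(
    atlas$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] == code),
    hi - lo + 1L)
  sm <- gaussian_smooth(new_volume(sub, atlas$voxel_size_mm), fwhm_mm)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sm$values
  out
}

# Canonical fitting mask as a binary volume (for carrying through affines).
fit_mask_volume <- function(atlas, fwhm_mm) {
  key <- paste0(atlas$hash, "-maskvol-", round(fwhm_mm, 2))
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])
  m <- array(0, dim(atlas$labels))
  m[fit_mask_idx(atlas, fwhm_mm)] <- 1
  out <- new_volume(m, atlas$voxel_size_mm)
  .basis_cache[[key]] <- out
  out
}

# Full smoothed-indicator volumes (one per region code) for a kernel width,
# cached per (atlas, fwhm); used when the basis must be resampled through an
# affine.
basis_volumes <- function(atlas, fwhm_mm) {
  key <- paste0(atlas$hash, "-basisvol-", sprintf("%.4f", fwhm_mm))
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])
  out <- lapply(atlas$region_table$code, function(code)
    new_volume(smooth_indicator(atlas, code, fwhm_mm), atlas$voxel_size_mm))
  .basis_cache[[key]] <- out
  out
}

# Smoothed-indicator basis (mask voxels x 23) for a given kernel width,
# cached per (atlas, fwhm) together with its Gram matrix.
smoothed_basis <- function(atlas, fwhm_mm, idx) {
  key <- paste0(atlas$hash, "-basis-", sprintf("%.4f", fwhm_mm))
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])
  codes <- atlas$region_table$code
  b <- matrix(0, length(idx), length(codes))
  for (j in seq_along(codes)) {
    b[, j] <- smooth_indicator(atlas, codes[j], fwhm_mm)[idx]
  }
  out <- list(b = b, gram = crossprod(b))
  .basis_cache[[key]] <- out
  out
}

#' Fit the paint-and-smooth forward model to a target volume
#'
#' Finds the 23 nonnegative regional values and (optionally) the Gaussian
#' kernel width that minimize the sum of squared voxel differences between
#' the forward model (regional painting followed by isotropic Gaussian
#' smoothing) and the target.  For a fixed kernel width the model is linear in
#' the regional values, so values are profiled out by nonnegative least
#' squares on the smoothed-indicator basis; the kernel width is found by a
#' coarse grid search with parabolic refinement.
#'
#' When `transform` is supplied (the pull-back affine estimated by
#' [register_to_bank()], i.e. `normalized(x) = target(M x)`), the model is
#' instead fitted in the target's own space: the smoothed-indicator basis is
#' carried through the affine and regressed against the raw scan voxels.
#' This avoids interpolating the data and keeps the kernel exactly isotropic
#' in aligned space, which matters because deconvolving regions smaller than
#' the kernel is sensitive to kernel mismatch.
#'
#' @param target A `cm_volume` on the atlas grid.
#' @param atlas A `cm_atlas`.
#' @param fwhm_mm If supplied, the kernel width is fixed and only regional
#'   values are estimated.
#' @param fwhm_grid Candidate kernel widths (mm) for the grid search.
#' @param transform Optional `cm_affine` mapping canonical coordinates into
#'   the target (pull-back convention); fits in target space when given.
#' @return A `cm_template_fit`: `values` (named by region code), `fwhm_mm`,
#'   `residual_rmse`, `cost` and a `converged` flag (FALSE when the width is
#'   unidentifiable, e.g. for an all-zero target, in which case the grid
#'   midpoint is returned).
#' @export
fit_template_model <- function(target, atlas, fwhm_mm = NULL,
                               fwhm_grid = seq(8, 16, by = 2),
                               transform = NULL) {
  stopifnot(is_volume(target), inherits(atlas, "cm_atlas"))
  if (!all(dim(target) == dim(atlas$labels)))
    stop("target volume is not on the atlas grid", call. = FALSE)
  codes <- as.character(atlas$region_table$code)

  if (is.null(transform)) {
    idx <- fit_mask_idx(atlas, max(fwhm_grid, fwhm_mm))
    y <- target$values[idx]
    solve_at <- function(f) {
      bs <- smoothed_basis(atlas, f, idx)
      atb <- as.vector(crossprod(bs$b, y))
      x <- nnls_gram(bs$gram, atb)
      cost <- sum(y * y) - 2 * sum(x * atb) +
        as.numeric(t(x) %*% bs$gram %*% x)
      list(x = x, cost = max(cost, 0))
    }
  } else {
    stopifnot(inherits(transform, "cm_affine"))
    # target(x) = aligned(A x) with A the inverse of the registration
    # pull-back; fit over target voxels whose aligned position lies in the
    # canonical fitting mask
    a_mat <- solve(transform$matrix)
    pts <- grid_coords_mm(dim(target), target$voxel_size_mm)
    u <- apply_affine_pts(a_mat, pts)
    mask_vol <- fit_mask_volume(atlas, max(fwhm_grid, fwhm_mm))
    inside <- sample_volume(mask_vol, u) > 0.25
    u <- u[inside, , drop = FALSE]
    y <- as.vector(target$values)[inside]
    solve_at <- function(f) {
      vols <- basis_volumes(atlas, f)
      b <- vapply(vols, function(v) sample_volume(v, u), numeric(length(y)))
      gram <- crossprod(b)
      atb <- as.vector(crossprod(b, y))
      x <- nnls_gram(gram, atb)
      cost <- sum(y * y) - 2 * sum(x * atb) +
        as.numeric(t(x) %*% gram %*% x)
      list(x = x, cost = max(cost, 0))
    }
  }
  yty <- sum(y * y)

  if (yty == 0) {
    f0 <- if (!is.null(fwhm_mm)) fwhm_mm else stats::median(fwhm_grid)
    return(structure(list(values = stats::setNames(numeric(length(codes)),
                                                   codes),
                          fwhm_mm = f0, residual_rmse = 0, cost = 0,
                          converged = FALSE),
                     class = "cm_template_fit"))
  }

  if (!is.null(fwhm_mm)) {
    s <- solve_at(fwhm_mm)
    best_f <- fwhm_mm
    best <- s
    converged <- TRUE
  } else {
    costs <- vapply(fwhm_grid, function(f) solve_at(f)$cost, numeric(1))
    if (diff(range(costs)) <= 1e-12 * max(costs, 1e-300)) {
      # width unidentifiable (e.g. constant target)
      f0 <- stats::median(fwhm_grid)
      s <- solve_at(f0)
      return(structure(list(
        values = stats::setNames(s$x, codes), fwhm_mm = f0,
        residual_rmse = sqrt(s$cost / length(y)), cost = s$cost,
        converged = FALSE), class = "cm_template_fit"))
    }
    k <- which.min(costs)
    best_f <- fwhm_grid[k]
    best_cost <- costs[k]
    # parabolic refinement on the local triple, iterated to a 0.005 mm
    # lattice: regional values of sub-kernel-size regions are sensitive to
    # kernel mismatch, so the width must be resolved finely
    tri_f <- fwhm_grid
    tri_c <- costs
    for (round in 1:8) {
      ord <- order(abs(tri_f - best_f))[1:3]
      f3 <- tri_f[ord]; c3 <- tri_c[ord]
      denom <- (f3[1] - f3[2]) * (f3[1] - f3[3]) * (f3[2] - f3[3])
      if (abs(denom) < 1e-9) break
      a <- (f3[3] * (c3[2] - c3[1]) + f3[2] * (c3[1] - c3[3]) +
              f3[1] * (c3[3] - c3[2])) / denom
      b <- (f3[3]^2 * (c3[1] - c3[2]) + f3[2]^2 * (c3[3] - c3[1]) +
              f3[1]^2 * (c3[2] - c3[3])) / denom
      if (a <= 0) break
      f_new <- max(min(-b / (2 * a), max(fwhm_grid)), min(fwhm_grid))
      # snap to a 0.005 mm lattice so refined widths hit the basis cache
      f_new <- round(f_new / 0.005) * 0.005
      if (abs(f_new - best_f) < 0.005 || any(abs(tri_f - f_new) < 1e-9))
        break
      c_new <- solve_at(f_new)$cost
      tri_f <- c(tri_f, f_new); tri_c <- c(tri_c, c_new)
      if (c_new < best_cost) { best_f <- f_new; best_cost <- c_new }
    }
    best <- solve_at(best_f)
    converged <- TRUE
  }

  structure(list(values = stats::setNames(best$x, codes), fwhm_mm = best_f,
                 residual_rmse = sqrt(best$cost / length(y)),
                 cost = best$cost, converged = converged),
            class = "cm_template_fit")
}

#' @export
print.cm_template_fit <- function(x, ...) {
  cat(sprintf("<cm_template_fit> fwhm %.2f mm, residual RMSE %.4g%s\n",
              x$fwhm_mm, x$residual_rmse,
              if (x$converged) "" else " (flagged: not converged)"))
  invisible(x)
}

#' Synthesize a scan from the forward model with known ground truth
#'
#' Scales the healthy-control regional values by per-side putamen/caudate
#' deficit fractions (or uses explicit regional values), paints and smooths
#' them, applies a global intensity scale, resamples through a misalignment
#' affine, and adds voxelwise Gaussian noise.  Deterministic under a fixed
#' seed; the ground-truth record carries the exact regional values, transform
#' and configuration.
#'
#' @param bank A `cm_template_bank`.
#' @param fractions Length-4 deficit fractions (putamen_left, putamen_right,
#'   caudate_left, caudate_right), each in `[0, 1]`; ignored when `values` is
#'   given.
#' @param values Optional explicit painted regional values keyed by region
#'   code.
#' @param scale Global intensity scale (> 0).
#' @param noise_sd Standard deviation of additive voxelwise Gaussian noise
#'   (>= 0), applied after smoothing and scaling.
#' @param transform Optional `cm_affine` misalignment; the synthesized scan is
#'   the aligned image resampled through it.
#' @param seed Optional integer seed controlling the noise draw only.
#' @return A list with `volume` and a `truth` record (`values`, `scale`,
#'   `transform`, `noise_sd`, `seed`, `fwhm_mm`).
#' @export
synthesize_scan <- function(bank, fractions = c(1, 1, 1, 1), values = NULL,
                            scale = 1, noise_sd = 0, transform = NULL,
                            seed = NULL) {
  stopifnot(inherits(bank, "cm_template_bank"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  atlas <- bank$atlas
  if (is.null(values)) {
    values <- scale_values_by_fractions(atlas, bank$hc_values, fractions)
  } else {
    codes <- as.character(atlas$region_table$code)
    if (is.null(names(values)) && length(values) == length(codes))
      names(values) <- codes
  }
  v <- gaussian_smooth(paint_template(atlas, values), bank$spec$fwhm_mm)
  a <- v$values * scale
  if (!is.null(transform)) {
    stopifnot(inherits(transform, "cm_affine"))
    a <- resample(new_volume(a, atlas$voxel_size_mm), transform)$values
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old_seed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit({
        if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old_seed, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    a <- a + stats::rnorm(length(a), sd = noise_sd)
  }
  list(volume = new_volume(array(a, dim(atlas$labels)), atlas$voxel_size_mm),
       truth = list(values = values, scale = scale, transform = transform,
                    noise_sd = noise_sd, seed = seed,
                    fwhm_mm = bank$spec$fwhm_mm))
}
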