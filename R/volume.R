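# 3-D scalar volumes on a regular grid, Gaussian smoothing, affine transforms
# and trilinear resampling.  Physical coordinates are in millimetres with the
# origin at the grid centre; axis order is right-anterior-superior.

#' Create a 3-D volume
#'
#' A volume is a 3-D array of finite scalar values together with the physical
#' voxel size in millimetres per axis.  All images, masks and templates in the
#' package live on such grids; the canonical analysis grid is 91 x 109 x 91
#' voxels at 2 mm isotropic.
#'
#' @param values A numeric 3-D array of finite values.
#' @param voxel_size_mm Numeric length-3 (or scalar, recycled) voxel size in
#'   millimetres per axis; all entries must be positive.
#' @return An object of class `cm_volume` with fields `values` and
#'   `voxel_size_mm`.
#' @examples
#' v <- new_volume(array(0, c(10, 12, 10)), 2)
#' dim(v)
#' @export
new_volume <- function(values, voxel_size_mm = c(2, 2, 2)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (!all(is.finite(values)))
    stop("volume values must all be finite", call. = FALSE)
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    stop("voxel sizes must be positive and finite", call. = FALSE)
  structure(list(values = values, voxel_size_mm = voxel_size_mm),
            class = "cm_volume")
}

#' @export
dim.cm_volume <- function(x) dim(x$values)

#' @export
print.cm_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<cm_volume> %d x %d x %d voxels at %s mm; range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size_mm, trim = TRUE), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "cm_volume")

# Physical axis coordinates (mm) of the voxel centres along one axis,
# origin at the grid centre.
axis_coords_mm <- function(n, voxel_mm) (seq_len(n) - (n + 1) / 2) * voxel_mm

# n x 3 matrix of physical coordinates for the given linear voxel indices
# (or all voxels, in array linear order).
grid_coords_mm <- function(shape, voxel_size_mm, idx = NULL) {
  ax <- lapply(1:3, function(a) axis_coords_mm(shape[a], voxel_size_mm[a]))
  if (is.null(idx)) idx <- seq_len(prod(shape))
  i <- (idx - 1L) %% shape[1] + 1L
  j <- ((idx - 1L) %/% shape[1]) %% shape[2] + 1L
  k <- (idx - 1L) %/% (shape[1] * shape[2]) + 1L
  cbind(ax[[1]][i], ax[[2]][j], ax[[3]][k])
}

# Zero-padded 1-D convolution of a 3-D array along one axis, implemented as a
# shift-and-add over kernel taps (vectorised over the other two axes).
conv_axis <- function(a, w, axis) {
  r <- (length(w) - 1L) %/% 2L
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  for (k in seq_along(w)) {
    s <- k - r - 1L
    i_lo <- max(1L, 1L - s)
    i_hi <- min(n, n - s)
    if (i_lo > i_hi) next
    src <- (i_lo + s):(i_hi + s)
    dst <- i_lo:i_hi
    if (axis == 1L) {
      out[dst, , ] <- out[dst, , ] + w[k] * a[src, , ]
    } else if (axis == 2L) {
      out[, dst, ] <- out[, dst, ] + w[k] * a[, src, ]
    } else {
      out[, , dst] <- out[, , dst] + w[k] * a[, , src]
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  w <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  w / sum(w)
}

#' Smooth a volume with an isotropic Gaussian kernel
#'
#' Separable Gaussian convolution with standard deviation
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis, expressed in voxel units via
#' the voxel size.  The kernel is truncated at 4 sigma and renormalized to
#' unit sum, and zero padding is used at the grid boundary, so the total image
#' sum is conserved for content away from the grid edge.
#'
#' @param v A [new_volume()] object.
#' @param fwhm_mm Full width at half maximum of the kernel, millimetres
#'   (strictly positive).
#' @return A smoothed `cm_volume` on the same grid.
#' @export
gaussian_smooth <- function(v, fwhm_mm) {
  stopifnot(is_volume(v))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm <= 0)
    stop("`fwhm_mm` must be a single positive number", call. = FALSE)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  a <- v$values
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / v$voxel_size_mm[axis]
    if (sigma_vox < 1e-6) next
    a <- conv_axis(a, gaussian_kernel_1d(sigma_vox), axis)
  }
  new_volume(a, v$voxel_size_mm)
}

#' Build an affine transform from its 12 parameters
#'
#' The transform maps physical (mm) coordinates of the output (canonical)
#' space to sampling coordinates in the source space, i.e. it is stored in
#' pull-back convention: `resample()` evaluates the source volume at `M x`
#' for each output-grid point `x`.  The 4 x 4 matrix is composed in the fixed
#' order `M = T . Rz . Ry . Rx . Shear . Scale` (translation in mm, rotations
#' in radians about the grid centre, unit-diagonal upper-triangular shear).
#'
#' @param translation,rotation,scale,shear Numeric length-3 parameter blocks.
#' @return An object of class `cm_affine` with the parameters and the
#'   equivalent 4 x 4 matrix.
#' @export
affine_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                             scale = c(1, 1, 1), shear = c(0, 0, 0)) {
  p <- c(rep_len(translation, 3), rep_len(rotation, 3),
         rep_len(scale, 3), rep_len(shear, 3))
  if (!all(is.finite(p))) stop("affine parameters must be finite", call. = FALSE)
  affine_from_params(p)
}

affine_from_params <- function(p) {
  tr <- p[1:3]; rot <- p[4:6]; sc <- p[7:9]; sh <- p[10:12]
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  shm <- matrix(c(1, 0, 0, sh[1], 1, 0, sh[2], sh[3], 1), 3, 3)
  a <- rz %*% ry %*% rx %*% shm %*% diag(sc)
  m <- rbind(cbind(a, tr), c(0, 0, 0, 1))
  dimnames(m) <- NULL
  if (abs(det(a)) < 1e-12)
    stop("affine transform is not invertible", call. = FALSE)
  structure(list(translation = tr, rotation = rot, scale = sc, shear = sh,
                 matrix = m),
            class = "cm_affine")
}

#' Wrap an arbitrary invertible 4 x 4 matrix as an affine transform
#'
#' Parameter blocks are set to `NA` because a general matrix has no unique
#' parameter decomposition; resampling and inversion only use the matrix.
#' @param m A 4 x 4 matrix with last row (0, 0, 0, 1).
#' @return A `cm_affine` object.
#' @export
affine_from_matrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("last row of an affine matrix must be (0, 0, 0, 1)", call. = FALSE)
  if (abs(det(m[1:3, 1:3])) < 1e-12)
    stop("affine transform is not invertible", call. = FALSE)
  structure(list(translation = rep(NA_real_, 3), rotation = rep(NA_real_, 3),
                 scale = rep(NA_real_, 3), shear = rep(NA_real_, 3),
                 matrix = m),
            class = "cm_affine")
}

#' Invert an affine transform
#' @param t A `cm_affine` object.
#' @return The inverse transform (as a matrix-backed `cm_affine`).
#' @export
invert_affine <- function(t) {
  stopifnot(inherits(t, "cm_affine"))
  affine_from_matrix(solve(t$matrix))
}

#' @export
print.cm_affine <- function(x, ...) {
  cat("<cm_affine>\n")
  if (all(is.finite(x$translation))) {
    cat(sprintf("  translation (mm): %s\n",
                paste(format(x$translation, digits = 4), collapse = ", ")))
    cat(sprintf("  rotation (rad):   %s\n",
                paste(format(x$rotation, digits = 4), collapse = ", ")))
    cat(sprintf("  scale:            %s\n",
                paste(format(x$scale, digits = 4), collapse = ", ")))
    cat(sprintf("  shear:            %s\n",
                paste(format(x$shear, digits = 4), collapse = ", ")))
  } else {
    cat("  (matrix-defined, no parameter decomposition)\n")
  }
  invisible(x)
}

# Trilinear interpolation of a volume at arbitrary physical points (n x 3 mm
# matrix).  Points outside the field of view sample as 0.
sample_volume <- function(v, pts) {
  d <- dim(v$values)
  vox <- v$voxel_size_mm
  cx <- pts[, 1] / vox[1] + (d[1] + 1) / 2
  cy <- pts[, 2] / vox[2] + (d[2] + 1) / 2
  cz <- pts[, 3] / vox[3] + (d[3] + 1) / 2
  valid <- cx >= 1 & cx <= d[1] & cy >= 1 & cy <= d[2] & cz >= 1 & cz <= d[3]
  out <- numeric(nrow(pts))
  if (!any(valid)) return(out)
  cx <- cx[valid]; cy <- cy[valid]; cz <- cz[valid]
  i0 <- pmin(floor(cx), d[1] - 1); fx <- cx - i0
  j0 <- pmin(floor(cy), d[2] - 1); fy <- cy - j0
  k0 <- pmin(floor(cz), d[3] - 1); fz <- cz - k0
  n12 <- d[1] * d[2]
  base <- i0 + (j0 - 1) * d[1] + (k0 - 1) * n12
  a <- v$values
  val <-
    a[base]                  * (1 - fx) * (1 - fy) * (1 - fz) +
    a[base + 1]              * fx       * (1 - fy) * (1 - fz) +
    a[base + d[1]]           * (1 - fx) * fy       * (1 - fz) +
    a[base + d[1] + 1]       * fx       * fy       * (1 - fz) +
    a[base + n12]            * (1 - fx) * (1 - fy) * fz +
    a[base + n12 + 1]        * fx       * (1 - fy) * fz +
    a[base + n12 + d[1]]     * (1 - fx) * fy       * fz +
    a[base + n12 + d[1] + 1] * fx       * fy       * fz
  out[valid] <- val
  out
}

apply_affine_pts <- function(m, pts) {
  pts %*% t(m[1:3, 1:3]) + matrix(m[1:3, 4], nrow(pts), 3, byrow = TRUE)
}

#' Resample a volume through an affine transform
#'
#' Pull-back convention with trilinear interpolation: the value at each output
#' voxel is the source volume sampled at the transformed physical coordinate
#' of that voxel; coordinates falling outside the source field of view give 0.
#'
#' @param v Source `cm_volume`.
#' @param transform A `cm_affine`; defaults to the identity.
#' @param shape,voxel_size_mm Output grid; defaults to the source grid.
#' @return A `cm_volume` on the output grid.
#' @export
resample <- function(v, transform = affine_transform(), shape = dim(v),
                     voxel_size_mm = v$voxel_size_mm) {
  stopifnot(is_volume(v), inherits(transform, "cm_affine"))
  pts <- grid_coords_mm(shape, rep_len(voxel_size_mm, 3))
  vals <- sample_volume(v, apply_affine_pts(transform$matrix, pts))
  new_volume(array(vals, shape), rep_len(voxel_size_mm, 3))
}

#' Round half away from zero
#'
#' Presentation rounding for anchor tables (base R's `round()` is half-even).
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return `x` rounded half away from zero at `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
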