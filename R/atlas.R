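# Synthetic 23-region striatal atlas: a geometric stand-in with ellipsoidal
# basal-ganglia subregions and nested tissue-class shells on a fixed
# MNI152-like grid.  Exact shapes are configuration, not science; all
# downstream quantification is shape-agnostic.

# Basal-ganglia subregion geometry (right hemisphere; left is mirrored in x).
# Centres/radii in mm, hand-proportioned to basal-ganglia anatomy.  Painted in
# this order; later paint never overwrites earlier labels.
.bg_geometry <- data.frame(
  name = c("pre_caudate", "post_caudate", "accumbens",
           "pre_dorsal_putamen", "pre_ventral_putamen",
           "post_dorsal_putamen", "post_ventral_putamen",
           "globus_pallidus", "ventral_pallidum"),
  cx = c(14, 17, 9, 23, 24, 28, 29, 17, 11),
  cy = c(14, -4, 12, 8, 8, -6, -6, 0, 2),
  cz = c(8, 12, -8, 6, -5, 4, -7, -1, -10),
  rx = c(5.5, 4.5, 4.5, 5, 5, 5, 5, 4.5, 4),
  ry = c(9, 7, 5, 7.5, 7.5, 8, 8, 6.5, 5),
  rz = c(6.5, 5.5, 4.5, 5.5, 5, 5.5, 5, 5, 4),
  stringsAsFactors = FALSE
)

# Tissue-class ellipsoids, painted after the basal ganglia from the inside
# out, so each later class forms the shell between consecutive ellipsoids.
.tissue_geometry <- data.frame(
  name = c("cerebral_white_matter", "grey_matter", "csf", "skull",
           "soft_tissue"),
  class = c("reference", "other-tissue", "other-tissue", "other-tissue",
            "other-tissue"),
  rx = c(48, 56, 60, 64, 68),
  ry = c(62, 70, 74, 78, 82),
  rz = c(45, 53, 57, 61, 65),
  stringsAsFactors = FALSE
)

.composite_children <- list(
  caudate = c("pre_caudate", "post_caudate"),
  pre_commissural_putamen = c("pre_dorsal_putamen", "pre_ventral_putamen"),
  post_commissural_putamen = c("post_dorsal_putamen", "post_ventral_putamen"),
  putamen = c("pre_dorsal_putamen", "pre_ventral_putamen",
              "post_dorsal_putamen", "post_ventral_putamen"),
  striatum = c("pre_caudate", "post_caudate",
               "pre_dorsal_putamen", "pre_ventral_putamen",
               "post_dorsal_putamen", "post_ventral_putamen"),
  basal_ganglia = .bg_geometry$name
)

#' Names of the standard quantification target regions
#'
#' The five composite target regions quantified by the pipeline, ordered as
#' conventionally reported.
#' @return Character vector of region names.
#' @export
target_regions <- function() {
  c("striatum", "putamen", "caudate",
    "pre_commissural_putamen", "post_commissural_putamen")
}

paint_ellipsoid <- function(labels, ax, centre, radii, code) {
  ix <- which(abs(ax[[1]] - centre[1]) <= radii[1])
  iy <- which(abs(ax[[2]] - centre[2]) <= radii[2])
  iz <- which(abs(ax[[3]] - centre[3]) <= radii[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(labels)
  dx2 <- ((ax[[1]][ix] - centre[1]) / radii[1])^2
  dy2 <- ((ax[[2]][iy] - centre[2]) / radii[2])^2
  dz2 <- ((ax[[3]][iz] - centre[3]) / radii[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  sub <- labels[ix, iy, iz, drop = FALSE]
  sub[inside & sub == 0L] <- code
  labels[ix, iy, iz] <- sub
  labels
}

#' Build the synthetic 23-region atlas
#'
#' Constructs a deterministic geometric stand-in for a striatal brain atlas on
#' a regular grid: 18 ellipsoidal basal-ganglia subregions (9 per hemisphere:
#' pre/post caudate, pre-dorsal/pre-ventral/post-dorsal/post-ventral putamen,
#' accumbens, globus pallidus, ventral pallidum) plus 5 tissue classes
#' (cerebral white matter as the reference region, grey matter, CSF, skull,
#' soft tissue) as nested ellipsoidal shells.  Regions are painted in a fixed
#' order and later paint never overwrites earlier labels, so base labels are
#' disjoint by construction.
#'
#' @param shape Voxel counts per axis (default the canonical 91 x 109 x 91).
#' @param voxel_size_mm Voxel size in mm per axis (default 2 mm isotropic).
#' @return An object of class `cm_atlas`: integer label array (`0` =
#'   background), `region_table` (code, name, side, class), `composites`
#'   (composite name to child region names), voxel size and a content hash.
#' @examples
#' atlas <- build_synthetic_atlas(shape = c(46, 55, 46), voxel_size_mm = 4)
#' nrow(atlas$region_table)
#' @export
build_synthetic_atlas <- function(shape = c(91, 109, 91),
                                  voxel_size_mm = c(2, 2, 2)) {
  shape <- as.integer(rep_len(shape, 3))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3)
  half_extent <- shape * voxel_size_mm / 2
  need <- c(max(.tissue_geometry$rx), max(.tissue_geometry$ry),
            max(.tissue_geometry$rz)) + voxel_size_mm
  if (any(half_extent < need))
    stop("grid too small to place all atlas regions: need half-extents of ",
         "at least ", paste(round(need, 1), collapse = " x "), " mm",
         call. = FALSE)

  ax <- lapply(1:3, function(a) axis_coords_mm(shape[a], voxel_size_mm[a]))
  labels <- array(0L, shape)

  region_table <- data.frame(code = integer(), name = character(),
                             side = character(), class = character(),
                             stringsAsFactors = FALSE)
  code <- 0L
  for (side in c("left", "right")) {
    sgn <- if (side == "left") -1 else 1
    for (r in seq_len(nrow(.bg_geometry))) {
      code <- code + 1L
      g <- .bg_geometry[r, ]
      labels <- paint_ellipsoid(labels, ax, c(sgn * g$cx, g$cy, g$cz),
                                c(g$rx, g$ry, g$rz), code)
      region_table <- rbind(region_table,
                            data.frame(code = code, name = g$name,
                                       side = side, class = "target-subregion",
                                       stringsAsFactors = FALSE))
    }
  }
  for (r in seq_len(nrow(.tissue_geometry))) {
    code <- code + 1L
    g <- .tissue_geometry[r, ]
    labels <- paint_ellipsoid(labels, ax, c(0, 0, 0), c(g$rx, g$ry, g$rz),
                              code)
    region_table <- rbind(region_table,
                          data.frame(code = code, name = g$name,
                                     side = "none", class = g$class,
                                     stringsAsFactors = FALSE))
  }

  counts <- tabulate(labels, nbins = code)
  if (any(counts == 0L))
    stop("grid too coarse: region(s) ",
         paste(region_table$name[counts == 0L], collapse = ", "),
         " contain no voxels", call. = FALSE)

  atlas <- structure(
    list(labels = labels, voxel_size_mm = voxel_size_mm,
         region_table = region_table, composites = .composite_children,
         hash = atlas_hash(labels, voxel_size_mm)),
    class = "cm_atlas")
  atlas
}

# Cheap deterministic content fingerprint for provenance/caching.
atlas_hash <- function(labels, voxel_size_mm) {
  idx <- which(labels > 0L)
  sprintf("atlas-%dx%dx%d-%s-%.0f-%.0f",
          dim(labels)[1], dim(labels)[2], dim(labels)[3],
          paste(format(voxel_size_mm, trim = TRUE), collapse = "x"),
          sum(as.numeric(labels[idx])),
          sum(as.numeric(idx) %% 1e7))
}

#' @export
print.cm_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<cm_atlas> %d base regions on %d x %d x %d grid at %s mm\n",
              nrow(x$region_table), d[1], d[2], d[3],
              paste(format(x$voxel_size_mm, trim = TRUE), collapse = " x ")))
  cat("  composites:", paste(names(x$composites), collapse = ", "), "\n")
  invisible(x)
}

# Resolve a (region, side) request to base label codes.
region_codes <- function(atlas, region, side = "bilateral") {
  side <- match.arg(side, c("bilateral", "left", "right", "none"))
  rt <- atlas$region_table
  if (region %in% names(atlas$composites)) {
    rows <- rt[rt$name %in% atlas$composites[[region]], , drop = FALSE]
  } else if (region %in% rt$name) {
    rows <- rt[rt$name == region, , drop = FALSE]
  } else {
    stop("unknown region: '", region, "'", call. = FALSE)
  }
  if (side %in% c("left", "right")) {
    rows <- rows[rows$side == side, , drop = FALSE]
    if (!nrow(rows))
      stop("region '", region, "' has no '", side, "' instance", call. = FALSE)
  }
  rows$code
}

#' Binary mask for a region
#'
#' Looks up a base region or composite (optionally per side) and returns its
#' voxel mask.  A bilateral request is the union of both sides; unlateralized
#' tissue classes are returned for any side policy that includes them.
#'
#' @param atlas A `cm_atlas`.
#' @param region Region or composite name.
#' @param side One of "bilateral", "left", "right" (or "none").
#' @return A binary `cm_volume`.
#' @export
region_mask <- function(atlas, region, side = "bilateral") {
  stopifnot(inherits(atlas, "cm_atlas"))
  codes <- region_codes(atlas, region, side)
  m <- array(0, dim(atlas$labels))
  m[atlas$labels %in% codes] <- 1
  new_volume(m, atlas$voxel_size_mm)
}

# Per-code voxel counts (named by code).
atlas_voxel_counts <- function(atlas) {
  n <- nrow(atlas$region_table)
  counts <- tabulate(atlas$labels, nbins = n)
  names(counts) <- as.character(seq_len(n))
  counts
}

#' Export an atlas as a NIfTI label image plus a JSON region table
#'
#' @param atlas A `cm_atlas`.
#' @param prefix Output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_atlas <- function(atlas, prefix) {
  stopifnot(inherits(atlas, "cm_atlas"))
  img <- RNifti::asNifti(
    atlas$labels,
    reference = list(pixdim = c(-1, atlas$voxel_size_mm, 0, 0, 0, 0)),
    datatype = "int16")
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  meta <- list(voxel_size_mm = atlas$voxel_size_mm,
               region_table = atlas$region_table,
               composites = atlas$composites,
               hash = atlas$hash)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(prefix)
}

#' Read an atlas written by [write_atlas()]
#' @param prefix Path prefix used at write time.
#' @return A `cm_atlas`.
#' @export
read_atlas <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  labels <- array(as.integer(img), dim(img))
  structure(
    list(labels = labels,
         voxel_size_mm = as.numeric(meta$voxel_size_mm),
         region_table = as.data.frame(meta$region_table,
                                      stringsAsFactors = FALSE),
         composites = lapply(meta$composites, as.character),
         hash = meta$hash),
    class = "cm_atlas")
}
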