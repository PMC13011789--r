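# Specific binding ratio quantification from normalized volumes, and
# assembly of long-format SBR tables.

# Per-code sums and counts of a volume over the atlas labels; any composite
# mean is then a ratio of summed sums and counts.
code_sums_counts <- function(v, atlas) {
  n <- nrow(atlas$region_table)
  lab <- as.vector(atlas$labels)
  nz <- lab > 0L
  sums <- numeric(n)
  agg <- rowsum(as.vector(v$values)[nz], lab[nz])
  sums[as.integer(rownames(agg))] <- agg[, 1]
  counts <- tabulate(atlas$labels, nbins = n)
  list(sums = sums, counts = counts)
}

region_mean_from_sc <- function(sc, codes) {
  n <- sum(sc$counts[codes])
  if (n == 0) stop("region mask is empty", call. = FALSE)
  sum(sc$sums[codes]) / n
}

#' Compute a regional specific binding ratio
#'
#' `SBR = mean(target) / mean(reference) - 1`, with unweighted voxel means
#' over the masks at the volume's native resolution.  The ratio is invariant
#' to global intensity scaling of the volume.
#'
#' @param v A `cm_volume` in canonical space.
#' @param atlas A `cm_atlas`.
#' @param region Target region (base or composite name).
#' @param side "left", "right" or "bilateral" (combined mask, not the average
#'   of per-side ratios).
#' @param reference Reference region name (default cerebral white matter).
#' @return A single numeric SBR value.
#' @examples
#' \dontrun{compute_sbr(vol, atlas, "putamen", side = "left")}
#' @export
compute_sbr <- function(v, atlas, region, side = "bilateral",
                        reference = "cerebral_white_matter") {
  stopifnot(is_volume(v), inherits(atlas, "cm_atlas"))
  sc <- code_sums_counts(v, atlas)
  tar <- region_mean_from_sc(sc, region_codes(atlas, region, side))
  ref <- region_mean_from_sc(sc, region_codes(atlas, reference, "bilateral"))
  if (ref <= 0)
    stop("reference-region mean is not positive; SBR undefined",
         call. = FALSE)
  tar / ref - 1
}

#' Model-based regional SBR estimates for one volume
#'
#' Fits the paint-and-smooth forward model to the volume
#' ([fit_template_model()]) and forms SBR values from the fitted regional
#' values: the composite value is the voxel-count-weighted mean of its
#' children's fitted values, divided by the fitted reference value, minus 1.
#' Because the fit inverts the known point-spread, these estimates are free of
#' the spill-over bias that affects mask means of smoothed images.
#'
#' @param v A `cm_volume` in canonical space.
#' @param atlas A `cm_atlas`.
#' @param regions Regions to report (default [target_regions()]).
#' @param sides Sides to report.
#' @param reference Reference region name.
#' @param fwhm_mm Optional fixed kernel width passed to the model fit.
#' @param transform Optional registration `cm_affine`: when given, `v` is the
#'   *unresampled* scan and the model is fitted in its own space (see
#'   [fit_template_model()]).
#' @return A data frame with columns `region`, `side`, `sbr`, plus the fit as
#'   attribute `"fit"`.
#' @export
fit_regional_sbr <- function(v, atlas, regions = target_regions(),
                             sides = c("left", "right", "bilateral"),
                             reference = "cerebral_white_matter",
                             fwhm_mm = NULL, transform = NULL) {
  fit <- fit_template_model(v, atlas, fwhm_mm = fwhm_mm,
                            transform = transform)
  counts <- atlas_voxel_counts(atlas)
  vals <- fit$values
  ref_codes <- as.character(region_codes(atlas, reference, "bilateral"))
  ref_val <- sum(vals[ref_codes] * counts[ref_codes]) /
    sum(counts[ref_codes])
  if (ref_val <= 0)
    stop("fitted reference value is not positive; SBR undefined",
         call. = FALSE)
  out <- expand.grid(region = regions, side = sides,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$sbr <- mapply(function(r, s) {
    codes <- as.character(region_codes(atlas, r, s))
    sum(vals[codes] * counts[codes]) / sum(counts[codes]) / ref_val - 1
  }, out$region, out$side)
  attr(out, "fit") <- fit
  out
}

#' Assemble a long-format SBR table from normalized volumes
#'
#' One record per (subject, tracer, session, region, side); the bilateral
#' record uses the combined left+right mask.  Duplicate keys are an error.
#'
#' @param volumes A list of `cm_volume` objects in canonical space.
#' @param meta A data frame with one row per volume and columns `subject`,
#'   `tracer`, `session_years`, `age`, `sex`.
#' @param atlas A `cm_atlas`.
#' @param regions Regions to quantify (default [target_regions()]).
#' @param sides Sides policy (default left, right and bilateral).
#' @param method "mask" for Eq.-style mask-mean SBR, "model" for the
#'   model-based estimator of [fit_regional_sbr()].
#' @param reference Reference region name.
#' @param fwhm_mm Fixed kernel width for the model-based method (optional).
#' @return An SBR table data frame with columns `subject`, `tracer`,
#'   `session_years`, `age`, `sex`, `region`, `side`, `value`.
#' @export
build_sbr_table <- function(volumes, meta, atlas,
                            regions = target_regions(),
                            sides = c("left", "right", "bilateral"),
                            method = c("mask", "model"),
                            reference = "cerebral_white_matter",
                            fwhm_mm = NULL) {
  method <- match.arg(method)
  stopifnot(length(volumes) == nrow(meta))
  need <- c("subject", "tracer", "session_years", "age", "sex")
  if (!all(need %in% names(meta)))
    stop("`meta` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  recs <- vector("list", length(volumes))
  for (i in seq_along(volumes)) {
    if (method == "mask") {
      grid <- expand.grid(region = regions, side = sides,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      grid$sbr <- mapply(function(r, s)
        compute_sbr(volumes[[i]], atlas, r, s, reference),
        grid$region, grid$side)
    } else {
      grid <- fit_regional_sbr(volumes[[i]], atlas, regions, sides,
                               reference, fwhm_mm)
    }
    recs[[i]] <- data.frame(meta[i, need, drop = FALSE],
                            region = grid$region, side = grid$side,
                            value = grid$sbr, row.names = NULL,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  key <- with(out, paste(subject, tracer, session_years, region, side))
  if (anyDuplicated(key))
    stop("duplicate (subject, tracer, session, region, side) records",
         call. = FALSE)
  attr(out, "atlas_hash") <- atlas$hash
  out
}
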