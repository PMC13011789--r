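# Readers and writers: NIfTI volumes, delimited SBR/CM tables, and JSON
# calibration artifacts.  Stored values keep full precision; rounding happens
# only at presentation.

.table_columns <- c("subject", "tracer", "session_years", "age", "sex",
                    "region", "side", "value")

#' Read a 3-D volume from a NIfTI file
#'
#' 4-D images are accepted read-only with an explicit frame selection.
#'
#' @param path Path to a NIfTI-1 file.
#' @param frame Frame index for 4-D input (required when 4-D).
#' @return A `cm_volume`.
#' @export
read_volume <- function(path, frame = NULL) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("not a readable NIfTI image: ", path, " (",
                         conditionMessage(e), ")", call. = FALSE))
  d <- dim(img)
  pix <- RNifti::pixdim(img)
  if (length(d) == 4L) {
    if (is.null(frame))
      stop("4-D input requires a `frame` selection", call. = FALSE)
    if (frame < 1 || frame > d[4])
      stop("frame ", frame, " out of range 1..", d[4], call. = FALSE)
    arr <- array(img[, , , frame], d[1:3])
  } else if (length(d) == 3L) {
    arr <- array(as.numeric(img), d)
  } else {
    stop("expected a 3-D (or 4-D with frame selection) image; got ",
         length(d), "-D", call. = FALSE)
  }
  new_volume(arr, pix[1:3])
}

#' Write a volume to a NIfTI file
#' @param v A `cm_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  img <- RNifti::asNifti(
    v$values, reference = list(pixdim = c(-1, v$voxel_size_mm, 0, 0, 0, 0)),
    datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a long-format SBR/CM table from delimited text
#'
#' Expects a header with columns `subject, tracer, session_years, age, sex,
#' region, side, value`.  Sex must be coded strictly numeric 0 (female) or 1
#' (male); duplicate (subject, tracer, session, region, side) keys are
#' rejected naming the offending row.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame.
#' @export
read_sbr_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty table file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(d)) stop("table has no data rows: ", path, call. = FALSE)
  missing <- setdiff(.table_columns, names(d))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("session_years", "age", "sex", "value")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) | is.na(d[[col]]))
    if (length(bad))
      stop("non-numeric `", col, "` at data row ", bad[1],
           if (col == "sex")
             " (sex must be coded 0 = female, 1 = male, not e.g. \"F\"/\"M\")"
           else "", call. = FALSE)
    d[[col]] <- v
  }
  if (!all(d$sex %in% c(0, 1))) {
    bad <- which(!(d$sex %in% c(0, 1)))[1]
    stop("invalid sex coding at data row ", bad,
         ": must be 0 (female) or 1 (male)", call. = FALSE)
  }
  key <- with(d, paste(subject, tracer, session_years, region, side))
  if (anyDuplicated(key))
    stop("duplicate key at data row ", which(duplicated(key))[1],
         call. = FALSE)
  d[, .table_columns]
}

#' Write a long-format SBR/CM table as CSV
#' @param tab A table with the standard columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sbr_table <- function(tab, path) {
  check_sbr_table(tab)
  out <- tab[, intersect(.table_columns, names(tab))]
  # 17 significant digits so doubles survive the text round trip bit-exactly
  for (col in c("session_years", "age", "sex", "value"))
    if (col %in% names(out)) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a calibration file
#'
#' Bundles level-1 anchors, tracer mappings, an age/sex model and pipeline
#' calibrations into a versioned JSON artifact that round-trips at full float
#' precision.
#'
#' @param path Output path.
#' @param anchors A `cm_anchors` (optional).
#' @param mappings A list of `cm_mapping` objects (optional).
#' @param agesex A `cm_agesex` (optional).
#' @param pipeline A `cm_pipeline_calibration` (optional).
#' @param provenance A list of free-form provenance fields (seed, config
#'   hash, ...).
#' @return `path`, invisibly.
#' @export
write_calibration <- function(path, anchors = NULL, mappings = NULL,
                              agesex = NULL, pipeline = NULL,
                              provenance = list()) {
  obj <- list(schema_version = 1L,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              provenance = provenance)
  if (!is.null(anchors)) {
    stopifnot(inherits(anchors, "cm_anchors"))
    obj$anchors <- list(tracer = attr(anchors, "tracer"),
                        side = attr(anchors, "side"),
                        table = as.data.frame(anchors))
  }
  if (!is.null(mappings)) {
    if (inherits(mappings, "cm_mapping")) mappings <- list(mappings)
    obj$mappings <- lapply(mappings, function(m) {
      stopifnot(inherits(m, "cm_mapping"))
      list(tracer = m$tracer, upstream = m$upstream, level = m$level,
           reference_tracer = m$reference_tracer, table = m$table)
    })
    # name the entries so the JSON array stays an object of objects
    names(obj$mappings) <- vapply(mappings, `[[`, character(1), "tracer")
  }
  if (!is.null(agesex)) {
    stopifnot(inherits(agesex, "cm_agesex"))
    obj$agesex <- list(anchor_age = attr(agesex, "anchor_age"),
                       anchor_sex = attr(agesex, "anchor_sex"),
                       table = as.data.frame(agesex))
  }
  if (!is.null(pipeline)) {
    stopifnot(inherits(pipeline, "cm_pipeline_calibration"))
    obj$pipeline <- list(table = as.data.frame(pipeline))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' Read a calibration file written by [write_calibration()]
#' @param path Path to the JSON artifact.
#' @return A list with any of `anchors`, `mappings`, `agesex`, `pipeline`
#'   (reconstructed as their classes) plus `provenance`.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(schema_version = obj$schema_version,
              provenance = obj$provenance)
  if (!is.null(obj$anchors)) {
    out$anchors <- structure(
      as.data.frame(obj$anchors$table, stringsAsFactors = FALSE),
      class = c("cm_anchors", "data.frame"),
      tracer = obj$anchors$tracer, side = obj$anchors$side)
  }
  if (!is.null(obj$mappings)) {
    out$mappings <- lapply(obj$mappings, function(m) {
      new_mapping(as.data.frame(m$table, stringsAsFactors = FALSE),
                  m$tracer, m$upstream, as.integer(m$level),
                  m$reference_tracer)
    })
  }
  if (!is.null(obj$agesex)) {
    out$agesex <- structure(
      as.data.frame(obj$agesex$table, stringsAsFactors = FALSE),
      class = c("cm_agesex", "data.frame"),
      anchor_age = obj$agesex$anchor_age,
      anchor_sex = obj$agesex$anchor_sex)
  }
  if (!is.null(obj$pipeline)) {
    out$pipeline <- structure(
      as.data.frame(obj$pipeline$table, stringsAsFactors = FALSE),
      class = c("cm_pipeline_calibration", "data.frame"))
  }
  out
}
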