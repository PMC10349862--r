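# Reading and writing ADC maps and annotation artifacts.
#
# ADC values are stored in "paper units", i.e. the magnitudes printed on
# clinical ADC maps (10^-6 mm^2/s physically); no unit conversion happens
# anywhere in the pipeline. Coordinates are 0-based (row, col) with pixel
# centers at integer coordinates; row 0 is the top of the image.

#' Construct an ADC map object
#'
#' Container for a single 2-D slice of an apparent diffusion coefficient map,
#' together with its geometry and an optional exclusion mask (e.g. ventricles,
#' bone, calcifications, which carry extreme ADC values and must not be
#' crossed by a line of interest).
#'
#' @param values Numeric matrix of ADC values (paper units); finite, >= 0.
#' @param pixel_spacing_mm Length-2 positive numeric, (row, col) spacing in mm.
#' @param slice_thickness_mm Positive scalar, slice thickness in mm.
#' @param exclusion_mask Optional logical matrix, same shape as `values`;
#'   `TRUE` marks excluded pixels.
#' @param source_id Free-text identifier of the source image.
#' @return An object of class `adc_map`.
#' @export
adc_map <- function(values, pixel_spacing_mm = c(0.8, 0.8),
                    slice_thickness_mm = 5, exclusion_mask = NULL,
                    source_id = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (any(!is.finite(values))) stopf("ADC values must be finite")
  if (any(values < 0)) stopf("ADC values must be >= 0")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    stopf("'pixel_spacing_mm' must be 2 positive values (row, col)")
  check_scalar(slice_thickness_mm, "slice_thickness_mm", positive = TRUE)
  if (!is.null(exclusion_mask)) {
    if (!is.logical(exclusion_mask) || !identical(dim(exclusion_mask), dim(values)))
      stopf("'exclusion_mask' must be a logical matrix with the shape of 'values'")
  }
  structure(list(values = values, pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 exclusion_mask = exclusion_mask,
                 source_id = as.character(source_id)),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("ADC map: %d x %d pixels, spacing %.3g x %.3g mm, slice %.3g mm\n",
              nrow(x$values), ncol(x$values),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm))
  cat(sprintf("  values in [%.1f, %.1f]%s\n", min(x$values), max(x$values),
              if (!is.null(x$exclusion_mask))
                sprintf(", %d excluded px", sum(x$exclusion_mask)) else ""))
  invisible(x)
}

#' Voxel volume of an ADC map
#'
#' In-plane pixel area times slice thickness; e.g. 0.8 x 0.8 mm pixels at 5 mm
#' slice thickness give 3.2 mm^3 per voxel.
#'
#' @param map An `adc_map`.
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(map) {
  stopifnot(inherits(map, "adc_map"))
  prod(map$pixel_spacing_mm) * map$slice_thickness_mm
}

#' Read an ADC map
#'
#' Supported formats: `nifti` (via the RNifti library; `.nii` or `.nii.gz`)
#' and `text` (whitespace-delimited raster with optional `#`-comment header
#' lines carrying the geometry, see [write_adc_map()]). Single-file DICOM /
#' DICOM series input is not supported by this build and raises an error.
#'
#' @param path File path.
#' @param format One of `"nifti"`, `"text"`, `"dicom"`; default guessed from
#'   the file extension.
#' @param slice For 3-D NIfTI volumes, the 1-based slice index to extract;
#'   a 3-D volume without `slice` is a dimensionality error.
#' @param default_spacing_mm Fallback in-plane spacing when the header carries
#'   none (a warning is emitted); default 0.8 mm.
#' @param default_thickness_mm Fallback slice thickness; default 5 mm.
#' @return An `adc_map`.
#' @export
read_adc_map <- function(path, format = NULL, slice = NULL,
                         default_spacing_mm = 0.8, default_thickness_mm = 5) {
  if (!file.exists(path)) stopf("cannot read ADC map: '%s' does not exist", path)
  format <- format %||% guess_format(path)
  switch(format,
    nifti = read_adc_nifti(path, slice, default_spacing_mm, default_thickness_mm),
    text = read_adc_text(path, default_spacing_mm, default_thickness_mm),
    dicom = stopf("DICOM input is not supported; convert the series to NIfTI"),
    stopf("unknown ADC map format '%s'", format))
}

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.(dcm|dicom)$", path, ignore.case = TRUE)) "dicom"
  else "text"
}

read_adc_nifti <- function(path, slice, default_spacing_mm, default_thickness_mm) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 1L) arr <- arr[, , 1L]
    else if (is.null(slice))
      stopf("3-D volume (%d slices): supply 'slice' to select one",
            dim(arr)[3])
    else arr <- arr[, , slice]
  }
  if (length(dim(arr)) != 2L) stopf("expected a 2-D slice, got %d dims",
                                    length(dim(arr)))
  spacing <- hdr$pixdim[2:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    warning(sprintf("no pixel spacing in NIfTI header; using default %.3g mm",
                    default_spacing_mm))
    spacing <- rep(default_spacing_mm, 2L)
  }
  # through-plane spacing: pixdim[4] when present, else the z row of the
  # sform (single-slice files keep it there), else the default
  thickness <- hdr$pixdim[4]
  if (!is.finite(thickness) || thickness <= 0)
    thickness <- sqrt(sum(hdr$srow_z[1:3]^2))
  if (!is.finite(thickness) || thickness <= 0)
    thickness <- default_thickness_mm
  adc_map(as.matrix(arr), spacing, thickness, source_id = path)
}

read_adc_text <- function(path, default_spacing_mm, default_thickness_mm) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parse_hdr <- function(key) {
    m <- grep(paste0("^\\s*#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    as.numeric(strsplit(trimws(sub(".*:", "", m[1])), "\\s+")[[1]])
  }
  spacing <- parse_hdr("pixel_spacing_mm")
  thickness <- parse_hdr("slice_thickness_mm")
  if (is.null(spacing)) {
    warning(sprintf("no pixel spacing in raster header; using default %.3g mm",
                    default_spacing_mm))
    spacing <- rep(default_spacing_mm, 2L)
  }
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  ncols <- unique(vapply(vals, length, 1L))
  if (length(ncols) != 1L) stopf("ragged raster rows in '%s'", path)
  mat <- do.call(rbind, vals)
  adc_map(mat, spacing, thickness %||% default_thickness_mm, source_id = path)
}

#' Write an ADC map
#'
#' @param map An `adc_map`.
#' @param path Output path.
#' @param format `"nifti"` or `"text"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_adc_map <- function(map, path, format = NULL) {
  stopifnot(inherits(map, "adc_map"))
  format <- format %||% guess_format(path)
  if (format == "nifti") {
    # single-slice volume; in-plane spacing in pixdim, slice thickness in
    # the z row of the sform (which survives the singleton third dimension)
    arr <- array(map$values, dim = c(dim(map$values), 1L))
    sp <- map$pixel_spacing_mm; th <- map$slice_thickness_mm
    hdr <- RNifti::niftiHeader(list(
      dim = c(3L, dim(arr), 1L, 1L, 1L, 1L),
      pixdim = c(-1, sp[1], sp[2], th, 0, 0, 0, 0),
      sform_code = 2L,
      srow_x = c(sp[1], 0, 0, 0), srow_y = c(0, sp[2], 0, 0),
      srow_z = c(0, 0, th, 0)))
    img <- RNifti::asNifti(arr, reference = hdr)
    RNifti::writeNifti(img, path)
  } else if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# pixel_spacing_mm: %.10g %.10g",
                         map$pixel_spacing_mm[1], map$pixel_spacing_mm[2]),
                 sprintf("# slice_thickness_mm: %.10g", map$slice_thickness_mm)),
               con)
    utils::write.table(format(map$values, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else stopf("unsupported output format '%s'", format)
  invisible(path)
}

#' Read / write line-of-interest annotations (JSON)
#'
#' The JSON schema is an array of objects
#' `{subject_id, loi_id, point_A: [row, col], point_F: [row, col]}` in 0-based
#' continuous pixel coordinates; A is the peripheral endpoint, F the lesion
#' center. Whether the endpoints lie inside a given image is checked at
#' sampling time, not at load time.
#'
#' @param path JSON file path.
#' @return For the reader, a list of [loi()] objects.
#' @export
read_loi_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    for (k in c("subject_id", "loi_id", "point_A", "point_F"))
      if (is.null(r[[k]])) stopf("LOI record missing key '%s'", k)
    loi(point_A = as.numeric(r$point_A), point_F = as.numeric(r$point_F),
        subject_id = r$subject_id, loi_id = r$loi_id)
  })
}

#' @rdname read_loi_json
#' @param lois List of [loi()] objects.
#' @export
write_loi_json <- function(lois, path) {
  recs <- lapply(lois, function(l)
    list(subject_id = l$subject_id, loi_id = l$loi_id,
         point_A = l$point_A, point_F = l$point_F))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write profile landmark annotations (JSON)
#'
#' JSON object keyed by `loi_id`, each entry carrying the integer indices
#' `a..f` (1-based indices into the sampled profile) and optionally `method`.
#' Ordering violations (e.g. `b <= a`) are a validation error at load time.
#'
#' @param path JSON file path.
#' @return Named list of [profile_landmarks()] objects, keyed by `loi_id`.
#' @export
read_landmarks_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(names(recs), function(id) {
    r <- recs[[id]]
    for (k in c("a", "b", "c", "d", "e", "f"))
      if (is.null(r[[k]])) stopf("landmarks for '%s' missing key '%s'", id, k)
    lm <- try(profile_landmarks(r$a, r$b, r$c, r$d, r$e, r$f,
                                method = r$method %||% "manual"),
              silent = TRUE)
    if (inherits(lm, "try-error"))
      stopf("invalid landmarks for loi_id '%s': %s", id,
            conditionMessage(attr(lm, "condition")))
    lm
  })
  names(out) <- names(recs)
  out
}

#' @rdname read_landmarks_json
#' @param landmarks Named list of [profile_landmarks()], keyed by `loi_id`.
#' @export
write_landmarks_json <- function(landmarks, path) {
  recs <- lapply(landmarks, function(lm)
    list(a = lm$a, b = lm$b, c = lm$c, d = lm$d, e = lm$e, f = lm$f,
         method = lm$method))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

FEATURE_COLUMNS <- c("grad_E_rise", "mean_E", "std_E", "median_E",
                     "grad_E_fall", "grad_T_rise", "mean_T", "std_T",
                     "median_T")

#' Read / write a feature table (CSV)
#'
#' Column contract: `subject_id, loi_id, label` followed by the nine feature
#' columns `grad_E_rise, mean_E, std_E, median_E, grad_E_fall, grad_T_rise,
#' mean_T, std_T, median_T` (the seven-predictor subset simply leaves
#' `mean_E`/`mean_T` as `NA`).
#'
#' @param path CSV file path.
#' @return For the reader, a data frame with the contract columns.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "loi_id", "label", FEATURE_COLUMNS)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("feature CSV missing column(s): %s", paste(missing, collapse = ", "))
  df[need]
}

#' @rdname read_features_csv
#' @param df Data frame of labeled samples (as from [generate_cohort()]).
#' @export
write_features_csv <- function(df, path) {
  need <- c("subject_id", "loi_id", "label", FEATURE_COLUMNS)
  for (col in setdiff(need, names(df))) df[[col]] <- NA_real_
  utils::write.csv(df[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
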