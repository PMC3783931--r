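#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file into a [volume_image()]. Voxel spacing is taken from
#' the header. The left-right axis is resolved from the header orientation
#' (qform/sform); when the file carries no orientation, an explicit
#' `lr_axis` must be supplied rather than guessed.
#'
#' @param path path to a `.nii`/`.nii.gz` file with exactly 3 spatial
#'   dimensions.
#' @param lr_axis optional explicit left-right axis (1-3), used only when
#'   the header has no orientation information.
#' @param lr_dir direction convention accompanying an explicit `lr_axis`:
#'   `+1` if increasing index runs toward patient left.
#' @return A `volume_image`.
#' @export
read_volume <- function(path, lr_axis = NULL, lr_dir = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-dimensional volume, got ", length(d),
         " dimensions in ", path)
  sp <- abs(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in header of ", path)
  lr <- .lr_from_header(img)
  if (is.na(lr$axis)) {
    if (is.null(lr_axis))
      stop("no orientation information in ", path,
           "; supply 'lr_axis' explicitly")
    lr <- list(axis = as.integer(lr_axis), dir = as.integer(lr_dir))
  }
  volume_image(array(as.numeric(img), dim = d), sp, lr$axis, lr$dir)
}

# resolve the left-right axis from a NIfTI header orientation string
.lr_from_header <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code == 0 && hdr$sform_code == 0)
    return(list(axis = NA_integer_, dir = NA_integer_))
  ort <- strsplit(RNifti::orientation(img), "")[[1]]
  ax <- which(ort %in% c("L", "R"))
  if (length(ax) != 1L) return(list(axis = NA_integer_, dir = NA_integer_))
  list(axis = as.integer(ax), dir = if (ort[ax] == "L") 1L else -1L)
}

#' Write a volume to NIfTI
#'
#' Masks are stored as uint8, everything else as float64 so that values
#' round-trip exactly. An sform encoding the volume's left-right convention
#' is written when `lr_axis` is known.
#'
#' @param vol a `volume_image`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  dat <- vol$data
  mask <- is_mask_volume(vol)
  storage.mode(dat) <- "double"
  img <- RNifti::asNifti(dat)
  if (!is.na(vol$lr_axis)) {
    aff <- matrix(0, 4, 4)
    aff[4, 4] <- 1
    world <- c(vol$lr_axis, setdiff(1:3, vol$lr_axis)) # x <- LR axis
    sgn <- c(if (isTRUE(vol$lr_dir == 1L)) -1 else 1, 1, 1)
    for (k in 1:3) aff[k, world[k]] <- sgn[k] * vol$spacing[world[k]]
    aff[1:3, 4] <- -aff[1:3, 1:3] %*% (dim(dat) / 2)
    RNifti::qform(img) <- structure(aff, code = 2L)
  }
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = if (mask) "uint8" else "double")
  invisible(path)
}

#' Read a 4D dynamic susceptibility contrast series
#'
#' TR and TE are taken from the arguments, never from the header: timing
#' fields in exported DSC headers are unreliable. A differing header TR
#' triggers a warning, not an error.
#'
#' @param path path to a 4D NIfTI file (time last).
#' @param tr repetition time in s.
#' @param te echo time in s.
#' @param n_baseline number of pre-bolus time points.
#' @param lr_axis,lr_dir fallback left-right convention when the header has
#'   no orientation, as in [read_volume()].
#' @return A [dsc_series()].
#' @export
read_dsc <- function(path, tr, te, n_baseline, lr_axis = NULL, lr_dir = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4-dimensional series, got ", length(d),
         " dimensions in ", path)
  pd <- abs(RNifti::pixdim(img))
  sp <- pd[1:3]
  if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0 &&
      abs(pd[4] - tr) > 1e-6)
    warning(sprintf(
      "header TR (%.4g s) differs from supplied TR (%.4g s); using %.4g",
      pd[4], tr, tr))
  lr <- .lr_from_header(img)
  if (is.na(lr$axis) && !is.null(lr_axis))
    lr <- list(axis = as.integer(lr_axis), dir = as.integer(lr_dir))
  dsc_series(array(as.numeric(img), dim = d), sp, tr, te, n_baseline,
             lr$axis, lr$dir)
}

#' Write a DSC series to NIfTI
#'
#' @param dsc a `dsc_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dsc <- function(dsc, path) {
  stopifnot(inherits(dsc, "dsc_series"))
  dat <- dsc$data
  storage.mode(dat) <- "double"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- c(dsc$spacing, dsc$tr)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# clinical record column contract -------------------------------------------

.clinical_mandatory <- c("treated", "sbp", "dbp")
.clinical_columns <- c("id", "nihss_acute", "nihss_24h", "sbp", "dbp", "inr",
                       "anticoagulant", "hemorrhage", "onset_to_treatment",
                       "treated", "mrs_3m", "nihss_3m")
.clinical_flags <- c("anticoagulant", "hemorrhage", "treated")

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(ifelse(is.na(x), NA, x != 0))
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "yes", "t")] <- TRUE
  out[x %in% c("0", "false", "no", "f")] <- FALSE
  out
}

#' Read per-patient clinical records
#'
#' Accepts CSV or JSON (an array of objects); the two encodings of the same
#' cohort yield identical record tables. Recognized columns: `id`,
#' `nihss_acute`, `nihss_24h` (0-42), `sbp`, `dbp` (mmHg), `inr`,
#' `anticoagulant`, `hemorrhage`, `onset_to_treatment` (hours), `treated`,
#' `mrs_3m` (0-6), `nihss_3m`. Missing optional fields become `NA`
#' ("unknown"), never silent zeros; the mandatory fields `treated`, `sbp`
#' and `dbp` must be present and non-missing in every row.
#'
#' @param path CSV or JSON file.
#' @return A `data.frame` with one row per patient and the canonical
#'   column set.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) stop("no patient records in ", path)
  missing_cols <- setdiff(.clinical_mandatory, names(df))
  if (length(missing_cols))
    stop("missing mandatory clinical field(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(.clinical_columns, names(df))) df[[col]] <- NA
  for (col in .clinical_flags) df[[col]] <- .as_flag(df[[col]])
  num_cols <- setdiff(.clinical_columns, c(.clinical_flags, "id"))
  for (col in num_cols) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  if (all(is.na(df$id))) df$id <- sprintf("P%03d", seq_len(nrow(df)))
  df$id <- as.character(df$id)
  for (col in .clinical_mandatory) {
    bad <- which(is.na(df[[col]]))
    if (length(bad))
      stop("mandatory field '", col, "' is missing in row(s) ",
           paste(bad, collapse = ", "))
  }
  .validate_clinical(df)
  df[, .clinical_columns]
}

.validate_clinical <- function(df) {
  chk <- function(col, lo, hi) {
    x <- df[[col]]
    bad <- which(!is.na(x) & (x < lo | x > hi))
    if (length(bad))
      stop("'", col, "' outside [", lo, ", ", hi, "] in row(s) ",
           paste(bad, collapse = ", "))
  }
  chk("nihss_acute", 0, 42); chk("nihss_24h", 0, 42); chk("nihss_3m", 0, 42)
  chk("mrs_3m", 0, 6)
  chk("sbp", 1e-9, Inf); chk("dbp", 1e-9, Inf); chk("inr", 1e-9, Inf)
  invisible(df)
}

#' Write clinical records or a cohort table to CSV
#'
#' @param df data frame of records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
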