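#' CT volume container
#'
#' A 3-D grid of Hounsfield units with explicit spacing and a fixed axis
#' convention: axis 1 is craniocaudal (slice 1 most caudal, z increasing
#' caudal to cranial), axis 2 anteroposterior, axis 3 left-right. The z
#' position of 0-based slice `k` is `k * spacing_mm[1]`; this conversion is
#' the single source of truth used by every module.
#'
#' @param voxels 3-D numeric/integer array of HU values (clamped to
#'   \[-1024, 3071\] on construction).
#' @param spacing_mm numeric (z, y, x) voxel spacing, strictly positive.
#' @param origin_mm numeric (z, y, x) origin, default zeros.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3-D array")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop("spacing must be 3 strictly positive values")
  if (any(voxels < HU_RANGE[1]) || any(voxels > HU_RANGE[2])) {
    message("clamping HU values outside [", HU_RANGE[1], ", ", HU_RANGE[2],
            "]")
    voxels[] <- pmin(pmax(voxels, HU_RANGE[1]), HU_RANGE[2])
  }
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (z, y, x), spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 4), collapse = " x ")))
  cat(sprintf("  HU range [%d, %d]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Convert between slice index and z position
#'
#' 0-based slice `k` sits at `z = k * spacing_z` mm (caudal to cranial);
#' the inverse rounds half-up toward cranial.
#'
#' @param index 0-based slice index (vectorized).
#' @param z_mm z position in mm (vectorized).
#' @param spacing_z_mm slice spacing in mm.
#' @return the converted value(s).
#' @export
slice_index_to_z <- function(index, spacing_z_mm) index * spacing_z_mm

#' @rdname slice_index_to_z
#' @export
z_to_slice_index <- function(z_mm, spacing_z_mm)
  as.integer(round_half_up(z_mm / spacing_z_mm))

#' Per-pixel tissue label map for one axial slice
#'
#' Integer codes: 0 background, 1 other in-body tissue, 2 skeletal muscle
#' (SM), 3 visceral fat (VAT), 4 subcutaneous fat (SAT).
#'
#' @param labels integer matrix.
#' @param spacing_mm numeric (y, x) pixel spacing in mm.
#' @return object of class `tissue_label_map`.
#' @export
tissue_label_map <- function(labels, spacing_mm) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% TISSUE_CODES))
    stop("labels contain codes outside ", paste(TISSUE_CODES, collapse = ","))
  if (length(spacing_mm) != 2 || any(spacing_mm <= 0))
    stop("spacing must be 2 positive values")
  structure(list(labels = labels, spacing_mm = as.numeric(spacing_mm),
                 codes = TISSUE_CODES), class = "tissue_label_map")
}

#' @export
print.tissue_label_map <- function(x, ...) {
  cat(sprintf("<tissue_label_map> %d x %d px at %s mm\n", nrow(x$labels),
              ncol(x$labels), paste(signif(x$spacing_mm, 4), collapse = " x ")))
  tab <- table(factor(x$labels, levels = TISSUE_CODES,
                      labels = names(TISSUE_CODES)))
  print(tab)
  invisible(x)
}

#' Save a CT volume or label map as NIfTI
#'
#' Volumes are written as int16 (lossless for integer HU; non-integer
#' values are rounded, and values outside \[-1024, 3071\] are clamped with
#' a message). The array is stored in x, y, z order with pixdim from the
#' volume spacing, so files are readable by standard NIfTI tools.
#'
#' @param volume a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  v <- round_half_up(volume$voxels)
  if (any(v != volume$voxels))
    message("rounding non-integer HU values for int16 storage")
  arr <- aperm(v, c(3, 2, 1))  # to x, y, z
  attr(arr, "pixdim") <- rev(volume$spacing_mm)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  invisible(path)
}

#' Load a CT volume
#'
#' Reads a NIfTI file or an uncompressed DICOM series directory into a
#' [ct_volume()]. DICOM stored values are rescaled to HU via the rescale
#' slope/intercept and slices are sorted caudal to cranial by their z
#' position regardless of file order; a mixed series (more than one series
#' UID) is an error. NIfTI is the internal interchange format; DICOM is
#' import-only.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"auto"` (directory implies DICOM), `"nifti"` or
#'   `"dicom"`.
#' @return a [ct_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file or directory", call. = FALSE)
  if (format == "auto") format <- if (dir.exists(path)) "dicom" else "nifti"
  if (format == "dicom") return(load_dicom_series(path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  arr <- aperm(as.array(img), c(3, 2, 1))
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  ct_volume(arr, rev(pd[1:3]))
}

#' Save / load a tissue label map as NIfTI
#'
#' @param labmap a [tissue_label_map()].
#' @param path `.nii`/`.nii.gz` path.
#' @return `save_label_map`: `path` invisibly; `load_label_map`: a
#'   [tissue_label_map()].
#' @export
save_label_map <- function(labmap, path) {
  stopifnot(inherits(labmap, "tissue_label_map"))
  arr <- t(labmap$labels)  # to x, y
  attr(arr, "pixdim") <- rev(labmap$spacing_mm)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  invisible(path)
}

#' @rdname save_label_map
#' @export
load_label_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 2) stop("label map file is not 2-D")
  pd <- RNifti::pixdim(img)
  tissue_label_map(t(arr), rev(pd[1:2]))
}

#' Load an annotation table
#'
#' Reads per-scan L3 annotations from CSV or Excel (`.xlsx`, the format
#' radiologists typically record slice picks in). Required columns: `id`,
#' `l3_slice_index` (0-based), `spacing_z_mm`. Optional: `l3_z_mm`
#' (recomputed as `l3_slice_index * spacing_z_mm` when absent) and
#' `height_m`. Duplicate ids and negative indices are rejected.
#'
#' @param path `.csv` or `.xlsx` file.
#' @return data.frame with one typed row per scan.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  df <- if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package", call. = FALSE)
    as.data.frame(readxl::read_excel(path))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("id", "l3_slice_index", "spacing_z_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate scan id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  df$l3_slice_index <- as.integer(df$l3_slice_index)
  df$spacing_z_mm <- as.numeric(df$spacing_z_mm)
  if (any(df$l3_slice_index < 0)) stop("negative slice index", call. = FALSE)
  if (any(df$spacing_z_mm <= 0)) stop("non-positive slice spacing",
                                      call. = FALSE)
  if (is.null(df$l3_z_mm) || all(is.na(df$l3_z_mm)))
    df$l3_z_mm <- slice_index_to_z(df$l3_slice_index, df$spacing_z_mm)
  df$l3_z_mm <- as.numeric(df$l3_z_mm)
  if (is.null(df$height_m)) df$height_m <- NA_real_
  df[c("id", "l3_slice_index", "l3_z_mm", "spacing_z_mm", "height_m")]
}

#' Write an annotation table as CSV
#'
#' @param annotations data.frame in the [load_annotations()] schema.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}
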