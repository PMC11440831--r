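# Binary morphology wrappers (2-D matrix or 3-D array), shared by the
# body-mask and pre-crop steps.
bin_dilate <- function(m, radii) {
  d <- dim(m)
  if (length(d) == 2) { d <- c(d, 1L); radii <- c(radii, 0L) }
  out <- cpp_dilate_box(as.logical(m), d[1], d[2], d[3],
                        radii[1], radii[2], radii[3])
  array(out, dim = dim(m))
}
bin_erode <- function(m, radii) !bin_dilate(!m, radii)
bin_close <- function(m, radii) bin_erode(bin_dilate(m, radii), radii)
bin_open <- function(m, radii) bin_dilate(bin_erode(m, radii), radii)

label_components <- function(m) {
  d <- dim(m)
  if (length(d) == 2) d <- c(d, 1L)
  array(cpp_label3d(as.logical(m), d[1], d[2], d[3]), dim = dim(m))
}

largest_component <- function(m) {
  lab <- label_components(m)
  if (max(lab) == 0) return(NULL)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

# Lantuejoul morphological skeleton of a 2-D binary matrix (box SE,
# radius 1): S = union over k of erode^k(A) minus its opening.
skeleton2d <- function(m) {
  s <- matrix(FALSE, nrow(m), ncol(m))
  e <- m
  while (any(e)) {
    s <- s | (e & !bin_open(e, c(1L, 1L)))
    e <- bin_erode(e, c(1L, 1L))
  }
  s
}

#' Preprocessing configuration
#'
#' Parameters of the L3-localization preprocessing chain. The full-scale
#' profile mirrors clinical CT: coronal projections rescaled to 1 mm per
#' row, padded to 1064 x 512 and then to 1088 x 512 at network entry. The
#' desk profile is a reduced-size preset for CPU-scale experiments on
#' phantoms (2 mm per row, 208 x 64, no extra network pad).
#'
#' @param row_mm target craniocaudal mm per projection row.
#' @param col_mm optional target left-right mm per projection column;
#'   `NULL` (the full-scale behaviour) keeps the native column sampling
#'   and only pads.
#' @param target_rows,target_cols standardized projection shape.
#' @param net_rows rows after the additional network-entry padding
#'   (>= `target_rows`).
#' @param body_threshold_hu HU threshold of the body mask.
#' @param se_mm structuring-element radius (mm) for closing/dilation.
#' @param lung_threshold_hu HU below which voxels count as lung-like air.
#' @param bone_threshold_hu HU above which voxels count as bone.
#' @param crop_margin_mm margin kept beyond each centroid when cropping.
#' @param precrop_min_dist_mm minimum lung-pelvis centroid distance (mm)
#'   before pre-cropping is applied (200 mm = 20 cm).
#' @param pad_value_hu background/pad HU value.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(row_mm = 1, col_mm = NULL,
                              target_rows = 1064,
                              target_cols = 512, net_rows = 1088,
                              body_threshold_hu = -200, se_mm = 5,
                              lung_threshold_hu = -500,
                              bone_threshold_hu = 150,
                              crop_margin_mm = 20,
                              precrop_min_dist_mm = 200,
                              pad_value_hu = -1000) {
  stopifnot(row_mm > 0, target_rows > 0, target_cols > 0,
            net_rows >= target_rows)
  structure(list(row_mm = row_mm, col_mm = col_mm,
                 target_rows = target_rows,
                 target_cols = target_cols, net_rows = net_rows,
                 body_threshold_hu = body_threshold_hu, se_mm = se_mm,
                 lung_threshold_hu = lung_threshold_hu,
                 bone_threshold_hu = bone_threshold_hu,
                 crop_margin_mm = crop_margin_mm,
                 precrop_min_dist_mm = precrop_min_dist_mm,
                 pad_value_hu = pad_value_hu), class = "preprocess_config")
}

#' @rdname preprocess_config
#' @param name `"full"` (paper-scale) or `"desk"` (reduced, CPU-scale).
#' @export
preprocess_preset <- function(name = c("full", "desk")) {
  name <- match.arg(name)
  if (name == "full") preprocess_config()
  else preprocess_config(row_mm = 3, col_mm = 12, target_rows = 144,
                         target_cols = 32, net_rows = 144)
}

#' Whole-body segmentation mask
#'
#' Thresholds the volume, keeps the largest 6-connected component (which
#' drops the scanner table, arms and other detached structures), then
#' applies morphological closing followed by dilation with a box element of
#' `se_mm` radius. Voxels outside this mask are zeroed (set to background)
#' before projection.
#'
#' @param volume a [ct_volume()].
#' @param config a [preprocess_config()].
#' @return logical 3-D array of the volume's shape.
#' @export
body_mask <- function(volume, config = preprocess_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  bin <- volume$voxels > config$body_threshold_hu
  comp <- largest_component(bin)
  if (is.null(comp))
    stop("degenerate input: no voxels above the body threshold (",
         config$body_threshold_hu, " HU)", call. = FALSE)
  radii <- as.integer(round(config$se_mm / volume$spacing_mm))
  bin_dilate(bin_close(comp, radii), radii)
}

#' Coronal maximum-intensity projection
#'
#' Sets voxels outside the mask to the background value and takes the
#' maximum along the anteroposterior axis, producing a 2-D coronal image
#' whose rows index craniocaudal position (row 1 = most caudal slice) and
#' whose columns index left-right.
#'
#' @param volume a [ct_volume()].
#' @param mask optional logical array from [body_mask()]; `NULL` projects
#'   the full volume.
#' @param config a [preprocess_config()].
#' @param crop_offset_mm z offset of `volume` relative to the original
#'   scan, as returned by [precrop()].
#' @param original_n_slices slice count of the original (un-cropped) scan.
#' @return list with `image` (n_slices x n_cols matrix), `spacing_z_mm`,
#'   `spacing_x_mm`, `crop_offset_mm`, `original_n_slices`.
#' @export
coronal_max_projection <- function(volume, mask = NULL,
                                   config = preprocess_config(),
                                   crop_offset_mm = 0,
                                   original_n_slices = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  v <- volume$voxels
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(v)))
    v[!mask] <- config$pad_value_hu
  }
  img <- apply(v, c(1, 3), max)
  if (is.null(original_n_slices))
    original_n_slices <- dim(v)[1] +
      as.integer(round(crop_offset_mm / volume$spacing_mm[1]))
  list(image = img, spacing_z_mm = volume$spacing_mm[1],
       spacing_x_mm = volume$spacing_mm[3], crop_offset_mm = crop_offset_mm,
       original_n_slices = as.integer(original_n_slices))
}

# Centroid (z, mm) of enclosed air components: air-like voxels whose
# connected component does not touch the lateral/AP borders of the grid
# (room air does, lungs do not).
find_lung_centroid <- function(volume, config) {
  air <- volume$voxels < config$lung_threshold_hu
  lab <- label_components(air)
  if (max(lab) == 0) return(NULL)
  border <- unique(c(lab[, 1, ], lab[, dim(lab)[2], ],
                     lab[, , 1], lab[, , dim(lab)[3]]))
  counts <- tabulate(lab[lab > 0], nbins = max(lab))
  counts[setdiff(border, 0)] <- 0L
  if (all(counts == 0)) return(NULL)
  best <- which.max(counts)
  if (counts[best] < 20) return(NULL)
  idx <- which(lab == best, arr.ind = TRUE)
  mean(idx[, 1] - 1) * volume$spacing_mm[1]
}

# Pelvic centroid (z, mm): per-slice morphological skeleton of the bone
# mask in the caudal half; slices whose skeleton mass is at least half the
# maximum dominate (the pelvic ring is much larger than vertebral
# cross-sections), and their weighted mean z is returned.
find_pelvis_centroid <- function(volume, config) {
  nz <- dim(volume$voxels)[1]
  sz <- volume$spacing_mm[1]
  half <- seq_len(max(1L, floor(nz / 2)))
  counts <- numeric(length(half))
  for (k in half) {
    bone <- volume$voxels[k, , ] > config$bone_threshold_hu
    if (any(bone)) counts[k] <- sum(skeleton2d(bone))
  }
  if (all(counts == 0)) return(NULL)
  keep <- counts >= 0.5 * max(counts)
  sum((half[keep] - 1) * sz * counts[keep]) / sum(counts[keep])
}

#' Centroid-based craniocaudal pre-crop
#'
#' Locates the lung centroid (largest enclosed air component below the lung
#' HU threshold) and the pelvic centroid (morphological skeleton of the
#' bone mask in the caudal half), and crops the volume craniocaudally to
#' \[pelvic centroid - margin, lung centroid + margin\] -- but only when
#' the centroids are more than `precrop_min_dist_mm` (20 cm) apart.
#' Otherwise, or when either landmark cannot be found (with a warning), the
#' volume is returned unchanged with offset 0.
#'
#' @param volume a [ct_volume()].
#' @param config a [preprocess_config()].
#' @return list with `volume`, `crop_offset_mm` (z of the first kept slice
#'   in the original frame), `cropped` flag, `lung_z_mm`, `pelvis_z_mm`,
#'   `original_n_slices`.
#' @export
precrop <- function(volume, config = preprocess_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  nz <- dim(volume$voxels)[1]
  sz <- volume$spacing_mm[1]
  no_crop <- function(lung = NA_real_, pelvis = NA_real_)
    list(volume = volume, crop_offset_mm = 0, cropped = FALSE,
         lung_z_mm = lung, pelvis_z_mm = pelvis, original_n_slices = nz)
  lung_z <- find_lung_centroid(volume, config)
  pelvis_z <- find_pelvis_centroid(volume, config)
  if (is.null(lung_z) || is.null(pelvis_z)) {
    warning("precrop: lung or pelvic landmark not found; skipping pre-crop",
            call. = FALSE)
    return(no_crop(if (is.null(lung_z)) NA_real_ else lung_z,
                   if (is.null(pelvis_z)) NA_real_ else pelvis_z))
  }
  if (abs(lung_z - pelvis_z) <= config$precrop_min_dist_mm)
    return(no_crop(lung_z, pelvis_z))
  lo <- min(pelvis_z, lung_z) - config$crop_margin_mm
  hi <- max(pelvis_z, lung_z) + config$crop_margin_mm
  i0 <- max(0L, as.integer(ceiling(lo / sz)))
  i1 <- min(nz - 1L, as.integer(floor(hi / sz)))
  list(volume = ct_volume(volume$voxels[(i0 + 1):(i1 + 1), , , drop = FALSE],
                          volume$spacing_mm),
       crop_offset_mm = i0 * sz, cropped = TRUE,
       lung_z_mm = lung_z, pelvis_z_mm = pelvis_z, original_n_slices = nz)
}

#' Standardize a coronal projection
#'
#' Rescales rows so that one row spans `row_mm` of craniocaudal extent
#' (bilinear interpolation), then pads symmetrically with the background
#' value to `target_rows` x `target_cols`. A projection larger than the
#' target is center-cropped with a warning (the fixed network input must be
#' honored). The returned provenance suffices to map any row back to an
#' original slice index.
#'
#' @param projection result of [coronal_max_projection()].
#' @param config a [preprocess_config()].
#' @return object of class `coronal_projection`: list with `image`
#'   (`target_rows` x `target_cols`) and `provenance` (`row_mm`,
#'   `row_scale` = spacing_z / row_mm, `spacing_z_mm`, `crop_offset_mm`,
#'   `pad_top_rows` (negative when center-cropped), `pad_left_cols`,
#'   `original_n_slices`, `n_rows_scaled`).
#' @export
standardize <- function(projection, config = preprocess_config()) {
  img <- projection$image
  sz <- projection$spacing_z_mm
  sx <- projection$spacing_x_mm
  n_in <- nrow(img)
  n_scaled <- max(1L, as.integer(round(n_in * sz / config$row_mm)))
  col_mm <- if (is.null(config$col_mm)) sx else config$col_mm
  c_scaled <- max(1L, as.integer(round(ncol(img) * sx / col_mm)))
  if (n_scaled != n_in || sz != config$row_mm || c_scaled != ncol(img)) {
    map_r <- matrix(pmin((seq_len(n_scaled) - 1) * config$row_mm / sz,
                         n_in - 1), n_scaled, c_scaled)
    map_c <- matrix(pmin((seq_len(c_scaled) - 1) * col_mm / sx,
                         ncol(img) - 1), n_scaled, c_scaled, byrow = TRUE)
    img <- cpp_warp_bilinear(img, map_r, map_c, config$pad_value_hu)
  }
  if (n_scaled > config$target_rows || ncol(img) > config$target_cols)
    warning("projection larger than ", config$target_rows, " x ",
            config$target_cols, "; center-cropping", call. = FALSE)
  pc <- pad_crop_matrix(img, config$target_rows, config$target_cols,
                        config$pad_value_hu)
  structure(list(
    image = pc$m,
    provenance = list(row_mm = config$row_mm, row_scale = sz / config$row_mm,
                      spacing_z_mm = sz,
                      crop_offset_mm = projection$crop_offset_mm,
                      pad_top_rows = pc$off_r, pad_left_cols = pc$off_c,
                      original_n_slices = projection$original_n_slices,
                      n_rows_scaled = n_scaled)),
    class = "coronal_projection")
}

#' @describeIn standardize Additional symmetric row padding applied at
#'   network entry (1064 to 1088 rows in the full-scale profile); updates
#'   the provenance accordingly.
#' @export
pad_for_network <- function(projection, config = preprocess_config()) {
  stopifnot(inherits(projection, "coronal_projection"))
  extra <- config$net_rows - nrow(projection$image)
  if (extra == 0) return(projection)
  pc <- pad_crop_matrix(projection$image, config$net_rows,
                        ncol(projection$image), config$pad_value_hu)
  projection$image <- pc$m
  projection$provenance$pad_top_rows <-
    projection$provenance$pad_top_rows + pc$off_r
  projection
}

#' Map projection rows to original slice indices and back
#'
#' `row_to_z_mm` returns the z position (mm, original scan frame) of a
#' 0-based projection row; `row_to_slice_index` rounds it half-up to a
#' 0-based slice index; `slice_index_to_row` is the inverse mapping. All
#' are vectorized and exact inverses on valid rows whenever
#' `row_mm <= spacing_z`.
#'
#' @param row 0-based projection row(s).
#' @param index 0-based slice index or indices.
#' @param provenance provenance list of a [standardize()]d projection.
#' @return numeric z (mm), integer slice index, or integer row.
#' @export
row_to_z_mm <- function(row, provenance)
  provenance$crop_offset_mm + (row - provenance$pad_top_rows) *
    provenance$row_mm

#' @rdname row_to_z_mm
#' @export
row_to_slice_index <- function(row, provenance)
  z_to_slice_index(row_to_z_mm(row, provenance), provenance$spacing_z_mm)

#' @rdname row_to_z_mm
#' @export
slice_index_to_row <- function(index, provenance)
  as.integer(round_half_up(
    (index * provenance$spacing_z_mm - provenance$crop_offset_mm) /
      provenance$row_mm) + provenance$pad_top_rows)

#' Build the L3 target band for training
#'
#' Marks a horizontal band of `thickness_mm` (default 10 mm, i.e. 10 rows
#' at 1 mm/row) centered on the annotated L3 position, full image width:
#' the 1-pixel L3 line extended to 1 cm to soften class imbalance. A band
#' crossing the image border is clipped with a warning.
#'
#' @param l3_z_mm annotated L3 z position (mm, original scan frame).
#' @param provenance provenance of the [standardize()]d projection the
#'   target must align with.
#' @param shape target (rows, cols); defaults to the standardized shape
#'   implied by the provenance plus network padding must be supplied by the
#'   caller.
#' @param thickness_mm band thickness in mm.
#' @return binary matrix of dimension `shape` with exactly one contiguous
#'   band.
#' @export
make_l3_target <- function(l3_z_mm, provenance, shape,
                           thickness_mm = 10) {
  rc <- as.integer(round_half_up(
    (l3_z_mm - provenance$crop_offset_mm) / provenance$row_mm) +
      provenance$pad_top_rows)
  t_rows <- max(1L, as.integer(round(thickness_mm / provenance$row_mm)))
  lo <- rc - (as.integer(ceiling(t_rows / 2)) - 1L)
  hi <- rc + as.integer(floor(t_rows / 2))
  if (lo < 0 || hi > shape[1] - 1)
    warning("L3 band clipped at the image border", call. = FALSE)
  lo <- max(0L, lo); hi <- min(shape[1] - 1L, hi)
  if (hi < lo) stop("L3 band lies entirely outside the image", call. = FALSE)
  m <- matrix(0, shape[1], shape[2])
  m[(lo + 1):(hi + 1), ] <- 1
  m
}

#' Run the full L3 preprocessing chain on one volume
#'
#' body mask, optional centroid pre-crop, masked coronal maximum-intensity
#' projection, standardization and network padding.
#'
#' @param volume a [ct_volume()].
#' @param config a [preprocess_config()].
#' @param do_precrop apply the 20 cm centroid rule (default TRUE).
#' @return a [standardize()]d, network-padded `coronal_projection` with an
#'   extra `precrop` element describing the crop.
#' @export
prepare_projection <- function(volume, config = preprocess_config(),
                               do_precrop = TRUE) {
  pc <- if (do_precrop) precrop(volume, config) else
    list(volume = volume, crop_offset_mm = 0, cropped = FALSE,
         original_n_slices = dim(volume$voxels)[1])
  mask <- body_mask(pc$volume, config)
  raw <- coronal_max_projection(pc$volume, mask, config,
                                crop_offset_mm = pc$crop_offset_mm,
                                original_n_slices = pc$original_n_slices)
  proj <- pad_for_network(standardize(raw, config), config)
  proj$precrop <- pc[c("crop_offset_mm", "cropped", "lung_z_mm",
                       "pelvis_z_mm")]
  proj
}
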