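#' Post-processing configuration
#'
#' @param gaussian_sigma_rows sigma (rows, ~mm) of the Gaussian used to
#'   smooth the 1-D probability signal before peak selection.
#' @param hu_window inclusive HU window outside which pixels are forced to
#'   background after segmentation (the reference rule: HU > 150 or
#'   < -500 are ignored).
#' @param strict_per_class apply per-tissue windows instead of the single
#'   global window: muscle \[-29, 150\], fat \[-500, -30\]. Off by default
#'   to keep the literal global-window behaviour.
#' @return object of class `postprocess_config`.
#' @export
postprocess_config <- function(gaussian_sigma_rows = 5,
                               hu_window = c(-500, 150),
                               strict_per_class = FALSE) {
  stopifnot(gaussian_sigma_rows > 0, length(hu_window) == 2,
            hu_window[1] < hu_window[2])
  structure(list(gaussian_sigma_rows = gaussian_sigma_rows,
                 hu_window = hu_window,
                 strict_per_class = isTRUE(strict_per_class)),
            class = "postprocess_config")
}

#' Collapse an L3 probability map to a 1-D craniocaudal signal
#'
#' Each projection row receives the mean L3-class probability across its
#' columns, yielding one value per craniocaudal position.
#'
#' @param prob_map L3-class probability matrix (rows x cols), or the full
#'   H x W x 2 probability array from the L3 model (channel 2 is used).
#' @return numeric vector, one value per row.
#' @export
project_probability_signal <- function(prob_map) {
  if (length(dim(prob_map)) == 3) prob_map <- prob_map[, , 2]
  rowMeans(prob_map)
}

#' Locate the L3 slice from the probability signal
#'
#' Smooths the signal with a Gaussian filter, enumerates local maxima and
#' selects the global maximum (ties broken toward the lowest row), then
#' maps the peak row back to an original-volume slice index through the
#' projection provenance (undo padding, divide by the row scale, add the
#' crop offset, round half-up).
#'
#' @param signal numeric vector from [project_probability_signal()].
#' @param provenance provenance of the projection the signal came from.
#' @param config a [postprocess_config()].
#' @return object of class `l3_prediction`: `slice_index` (0-based,
#'   original frame), `z_mm`, `peak_row` (0-based), `confidence` (smoothed
#'   peak height), `signal`, `smoothed`.
#' @export
locate_l3 <- function(signal, provenance,
                      config = postprocess_config()) {
  if (length(signal) < 2) stop("signal too short", call. = FALSE)
  s <- gauss_smooth(signal, config$gaussian_sigma_rows)
  if (max(s) - min(s) < 1e-12)
    stop("no peak: the probability signal is constant", call. = FALSE)
  n <- length(s)
  is_max <- s > c(-Inf, s[-n]) & s >= c(s[-1], -Inf)
  peaks <- which(is_max)
  peak_row <- peaks[which.max(s[peaks])] - 1L  # 0-based; ties -> lowest row
  idx <- row_to_slice_index(peak_row, provenance)
  idx <- min(max(idx, 0L), provenance$original_n_slices - 1L)
  structure(list(slice_index = idx,
                 z_mm = slice_index_to_z(idx, provenance$spacing_z_mm),
                 peak_row = peak_row, confidence = s[peak_row + 1],
                 signal = signal, smoothed = s), class = "l3_prediction")
}

#' @export
print.l3_prediction <- function(x, ...) {
  cat(sprintf("<l3_prediction> slice %d (z = %.1f mm), confidence %.3f\n",
              x$slice_index, x$z_mm, x$confidence))
  invisible(x)
}

#' Force pixels outside the HU window to background
#'
#' The reference post-filter: pixels with HU above 150 or below -500 are
#' ignored (set to background) whatever the network predicted. With
#' `strict_per_class` the tissue-specific windows are applied instead.
#' Idempotent by construction.
#'
#' @param labels integer label matrix.
#' @param hu HU matrix of the same shape.
#' @param config a [postprocess_config()].
#' @return filtered label matrix.
#' @export
apply_hu_filter <- function(labels, hu, config = postprocess_config()) {
  stopifnot(all(dim(labels) == dim(hu)))
  labels[hu < config$hu_window[1] | hu > config$hu_window[2]] <-
    TISSUE_CODES[["background"]]
  if (config$strict_per_class) {
    labels[labels == TISSUE_CODES[["SM"]] &
             (hu < HU_WINDOW_MUSCLE[1] | hu > HU_WINDOW_MUSCLE[2])] <-
      TISSUE_CODES[["background"]]
    fat <- labels %in% c(TISSUE_CODES[["VAT"]], TISSUE_CODES[["SAT"]])
    labels[fat & (hu < HU_WINDOW_FAT[1] | hu > HU_WINDOW_FAT[2])] <-
      TISSUE_CODES[["background"]]
  }
  labels
}

#' Segment an axial slice into tissue classes
#'
#' Pads (or center-crops) the slice to the model input shape, normalizes
#' intensities, takes the per-pixel argmax of the class probabilities
#' (ties toward the lowest class code), maps back to the original slice
#' shape and applies the HU-window post-filter.
#'
#' @param slice_hu HU matrix of the axial slice.
#' @param model the body-composition `unet_model`.
#' @param spacing_mm (y, x) pixel spacing of the slice.
#' @param config a [postprocess_config()].
#' @return a [tissue_label_map()] with the same shape as `slice_hu`.
#' @export
segment_slice <- function(slice_hu, model, spacing_mm,
                          config = postprocess_config()) {
  stopifnot(inherits(model, "unet_model"))
  shape <- model$config$input_shape
  pc <- pad_crop_matrix(slice_hu, shape[1], shape[2], -1000)
  probs <- unet_predict(model, normalize_hu(pc$m))
  lab_pad <- argmax_channels(probs)
  # invert the pad/crop back to the slice frame
  lab <- matrix(TISSUE_CODES[["background"]], nrow(slice_hu), ncol(slice_hu))
  src_r <- seq_len(nrow(slice_hu)) + pc$off_r
  src_c <- seq_len(ncol(slice_hu)) + pc$off_c
  keep_r <- src_r >= 1 & src_r <= shape[1]
  keep_c <- src_c >= 1 & src_c <= shape[2]
  lab[keep_r, keep_c] <- lab_pad[src_r[keep_r], src_c[keep_c]]
  lab <- apply_hu_filter(lab, slice_hu, config)
  tissue_label_map(lab, spacing_mm)
}

#' Run the full detection + segmentation pipeline on one volume
#'
#' Chains pre-crop, body masking, coronal projection, standardization, the
#' L3 network, signal post-processing, axial-slice extraction, the
#' body-composition network with HU filtering, and the sarcopenia report.
#'
#' @param volume a [ct_volume()].
#' @param l3_model trained L3-detection `unet_model` (2 classes).
#' @param body_model trained body-composition `unet_model` (5 classes).
#' @param pre_config a [preprocess_config()] whose target shape matches
#'   `l3_model`.
#' @param post_config a [postprocess_config()].
#' @param height_m optional patient height (m) for SMI/SMG.
#' @return list with `prediction` ([locate_l3()] result), `labels`
#'   ([tissue_label_map()] of the selected slice), `report`
#'   ([build_report()] result), `projection`.
#' @export
detect_and_segment <- function(volume, l3_model, body_model,
                               pre_config = preprocess_preset("desk"),
                               post_config = postprocess_config(),
                               height_m = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  proj <- stage("preprocess", prepare_projection(volume, pre_config))
  if (!all(dim(proj$image) == l3_model$config$input_shape))
    stop("[preprocess] projection shape ",
         paste(dim(proj$image), collapse = " x "),
         " does not match the L3 model input ",
         paste(l3_model$config$input_shape, collapse = " x "),
         call. = FALSE)
  probs <- stage("l3_model", unet_predict(l3_model,
                                          normalize_hu(proj$image)))
  pred <- stage("locate_l3", locate_l3(project_probability_signal(probs),
                                       proj$provenance, post_config))
  slice_hu <- volume$voxels[pred$slice_index + 1, , ]
  labels <- stage("segment", segment_slice(slice_hu, body_model,
                                           volume$spacing_mm[2:3],
                                           post_config))
  report <- stage("report", build_report(slice_hu, labels,
                                         height_m = height_m))
  list(prediction = pred, labels = labels, report = report,
       projection = proj)
}
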