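#' DICE overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks; 1 for
#' identical masks, 0 for disjoint ones. Two empty masks have DICE 1
#' (perfect agreement on absence), which stabilizes per-class summaries on
#' slices where a rare class is absent.
#'
#' @param a,b binary/logical arrays of identical shape.
#' @return numeric in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  a <- a != 0; b <- b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Agreement statistics between predicted and true values
#'
#' MAE = mean |p - t|; MAPE = 100 * mean(|p - t| / |t|); R^2 = 1 -
#' SS_res / SS_tot.
#'
#' @param predicted,truth numeric vectors of equal length >= 2.
#' @return named vector `c(mae, mape, r2)`.
#' @export
agreement_stats <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch",
                                               call. = FALSE)
  if (length(truth) < 2) stop("need at least 2 paired values", call. = FALSE)
  if (any(truth == 0)) stop("MAPE undefined: truth contains zero",
                            call. = FALSE)
  if (var(truth) == 0) stop("R^2 undefined: truth has zero variance",
                            call. = FALSE)
  mae <- mean(abs(predicted - truth))
  mape <- 100 * mean(abs(predicted - truth) / abs(truth))
  r2 <- 1 - sum((predicted - truth)^2) / sum((truth - mean(truth))^2)
  c(mae = mae, mape = mape, r2 = r2)
}

#' Cross-sectional area of a tissue class
#'
#' Pixel count times pixel area, in cm^2.
#'
#' @param labmap a [tissue_label_map()].
#' @param class class code (0-4) or name (`"background"`, `"other"`,
#'   `"SM"`, `"VAT"`, `"SAT"`).
#' @return area in cm^2.
#' @export
area_cm2 <- function(labmap, class) {
  stopifnot(inherits(labmap, "tissue_label_map"))
  if (is.character(class)) {
    if (!class %in% names(TISSUE_CODES))
      stop("unknown tissue class '", class, "'", call. = FALSE)
    class <- TISSUE_CODES[[class]]
  }
  if (!class %in% TISSUE_CODES)
    stop("unknown tissue class code ", class, call. = FALSE)
  sum(labmap$labels == class) * prod(labmap$spacing_mm) / 100
}

#' Skeletal muscle density (SMD)
#'
#' Mean HU over skeletal-muscle pixels, assessed inside the muscle window
#' \[-29, 150\] HU (pixels outside it are excluded even if labelled
#' muscle, making the windowing idempotent with the inference-time HU
#' filter).
#'
#' @param slice_hu HU matrix of the slice.
#' @param sm_mask logical/binary matrix marking skeletal-muscle pixels.
#' @return mean attenuation in HU.
#' @export
smd <- function(slice_hu, sm_mask) {
  stopifnot(all(dim(slice_hu) == dim(sm_mask)))
  vals <- slice_hu[sm_mask != 0 & slice_hu >= HU_WINDOW_MUSCLE[1] &
                     slice_hu <= HU_WINDOW_MUSCLE[2]]
  if (length(vals) == 0)
    stop("SMD undefined: no muscle pixels inside [-29, 150] HU",
         call. = FALSE)
  mean(vals)
}

#' Skeletal muscle index (SMI)
#'
#' Muscle cross-sectional area normalized by height squared (cm^2/m^2).
#'
#' @param area_sm_cm2 muscle area at L3 in cm^2.
#' @param height_m patient height in metres (> 0).
#' @return SMI in cm^2/m^2.
#' @export
smi <- function(area_sm_cm2, height_m) {
  if (is.null(height_m) || is.na(height_m) || height_m <= 0)
    stop("SMI requires a positive patient height", call. = FALSE)
  area_sm_cm2 / height_m^2
}

#' Skeletal muscle gauge (SMG)
#'
#' Composite of muscle quantity and quality, SMI x SMD, in
#' HU x cm^2/m^2.
#'
#' @param smi_value SMI in cm^2/m^2.
#' @param smd_value SMD in HU.
#' @return SMG in HU x cm^2/m^2.
#' @export
smg <- function(smi_value, smd_value) {
  if (any(is.na(c(smi_value, smd_value))))
    stop("SMG requires both SMI and SMD", call. = FALSE)
  smi_value * smd_value
}

#' Lean body mass (LBM)
#'
#' `LBM (kg) = 0.3 x muscle cross-sectional area at L3 (cm^2) + 6.06`.
#'
#' @param area_sm_cm2 muscle area at L3 in cm^2 (>= 0).
#' @return LBM in kg.
#' @export
lbm <- function(area_sm_cm2) {
  if (any(area_sm_cm2 < 0)) stop("negative muscle area", call. = FALSE)
  0.3 * area_sm_cm2 + 6.06
}

#' Fraction of correctly identified L3 slices
#'
#' A prediction counts as correct when its z position is within
#' `tolerance_mm` of the annotation (default 20 mm, half the ~40 mm
#' vertebral-body height; 0 demands the exact slice).
#'
#' @param pred_z_mm,true_z_mm numeric vectors of z positions (mm).
#' @param tolerance_mm tolerance in mm.
#' @param ids optional scan ids for both vectors; must match exactly.
#' @return fraction in \[0, 1\].
#' @export
correct_slice_rate <- function(pred_z_mm, true_z_mm, tolerance_mm = 20,
                               ids = NULL) {
  if (!is.null(ids)) {
    if (anyDuplicated(ids) || length(ids) != length(pred_z_mm))
      stop("ids must be unique and match the predictions", call. = FALSE)
  }
  if (length(pred_z_mm) != length(true_z_mm))
    stop("unmatched predictions and annotations", call. = FALSE)
  mean(abs(pred_z_mm - true_z_mm) <= tolerance_mm)
}

#' Sarcopenia report for one L3 slice
#'
#' Computes the tissue areas, SMD, LBM and -- when a height is available --
#' SMI and SMG from a segmented slice. SMG defaults to SMI x SMD (the
#' units HU x cm^2/m^2 imply the index); `smg_mode = "area"` uses
#' area x SMD instead.
#'
#' @param slice_hu HU matrix of the L3 slice.
#' @param labels a [tissue_label_map()] for that slice.
#' @param height_m optional patient height (m).
#' @param smg_mode `"smi"` (default) or `"area"`.
#' @return object of class `sarcopenia_report`: `area_sm_cm2`,
#'   `area_vat_cm2`, `area_sat_cm2`, `smd_hu`, `smi_cm2_m2` (NA without
#'   height), `smg_hu_cm2_m2`, `lbm_kg`, `height_m`.
#' @export
build_report <- function(slice_hu, labels, height_m = NULL,
                         smg_mode = c("smi", "area")) {
  smg_mode <- match.arg(smg_mode)
  stopifnot(inherits(labels, "tissue_label_map"),
            all(dim(slice_hu) == dim(labels$labels)))
  a_sm <- area_cm2(labels, "SM")
  a_vat <- area_cm2(labels, "VAT")
  a_sat <- area_cm2(labels, "SAT")
  smd_v <- smd(slice_hu, labels$labels == TISSUE_CODES[["SM"]])
  has_h <- !is.null(height_m) && !is.na(height_m) && height_m > 0
  smi_v <- if (has_h) smi(a_sm, height_m) else NA_real_
  smg_v <- if (smg_mode == "area") smg(a_sm, smd_v) else
    if (has_h) smg(smi_v, smd_v) else NA_real_
  structure(list(area_sm_cm2 = a_sm, area_vat_cm2 = a_vat,
                 area_sat_cm2 = a_sat, smd_hu = smd_v, smi_cm2_m2 = smi_v,
                 smg_hu_cm2_m2 = smg_v, lbm_kg = lbm(a_sm),
                 height_m = if (has_h) height_m else NA_real_),
            class = "sarcopenia_report")
}

#' @export
print.sarcopenia_report <- function(x, ...) {
  cat("<sarcopenia_report>\n")
  cat(sprintf("  SM  area %8.2f cm^2    SMD %6.1f HU\n", x$area_sm_cm2,
              x$smd_hu))
  cat(sprintf("  VAT area %8.2f cm^2    SAT area %8.2f cm^2\n",
              x$area_vat_cm2, x$area_sat_cm2))
  cat(sprintf("  LBM %6.2f kg", x$lbm_kg))
  if (!is.na(x$smi_cm2_m2))
    cat(sprintf("    SMI %6.2f cm^2/m^2    SMG %7.1f HU.cm^2/m^2",
                x$smi_cm2_m2, x$smg_hu_cm2_m2))
  cat("\n")
  invisible(x)
}

#' Evaluate a cohort of predictions against ground truth
#'
#' Mirrors the standard result layout: L3 localization (MAE in mm and the
#' correct-slice rate), per-class DICE (median and interquartile range)
#' and, for each derived quantity (tissue areas, SMD, SMI, LBM, SMG),
#' MAE / MAPE / R^2 between predicted and true values. R^2 and MAPE are NA
#' when undefined (fewer than 2 complete pairs, zero truth variance, or a
#' zero truth value).
#'
#' @param items list of per-scan lists with elements `pred_z_mm`,
#'   `true_z_mm`, `pred_labels` and `true_labels` ([tissue_label_map()]s of
#'   identical shape), `slice_hu`, and optionally `height_m`.
#' @param tolerance_mm correct-slice tolerance (mm).
#' @param smg_mode passed to [build_report()].
#' @return object of class `evaluation_summary`: `l3` (list), `dice`
#'   (data.frame class/median/q1/q3), `agreement` (data.frame
#'   quantity/mae/mape/r2/n).
#' @export
evaluate_cohort <- function(items, tolerance_mm = 20,
                            smg_mode = c("smi", "area")) {
  smg_mode <- match.arg(smg_mode)
  if (length(items) == 0) stop("empty cohort", call. = FALSE)
  pred_z <- vapply(items, `[[`, 0, "pred_z_mm")
  true_z <- vapply(items, `[[`, 0, "true_z_mm")
  l3 <- list(mae_mm = mean(abs(pred_z - true_z)),
             correct_rate = correct_slice_rate(pred_z, true_z,
                                               tolerance_mm),
             tolerance_mm = tolerance_mm)

  classes <- names(TISSUE_CODES)
  dice_rows <- lapply(classes, function(cl) {
    d <- vapply(items, function(it)
      dice_coefficient(it$pred_labels$labels == TISSUE_CODES[[cl]],
                       it$true_labels$labels == TISSUE_CODES[[cl]]), 0)
    data.frame(class = cl, median = median(d),
               q1 = unname(quantile(d, 0.25)),
               q3 = unname(quantile(d, 0.75)))
  })

  report_pair <- function(it) {
    h <- if (is.null(it$height_m)) NA_real_ else it$height_m
    list(pred = build_report(it$slice_hu, it$pred_labels, h, smg_mode),
         true = build_report(it$slice_hu, it$true_labels, h, smg_mode))
  }
  pairs <- lapply(items, function(it)
    tryCatch(report_pair(it), error = function(e) NULL))
  ok <- !vapply(pairs, is.null, TRUE)
  quantities <- c(area_sm_cm2 = "SM area (cm^2)",
                  area_vat_cm2 = "VAT area (cm^2)",
                  area_sat_cm2 = "SAT area (cm^2)", smd_hu = "SMD (HU)",
                  smi_cm2_m2 = "SMI (cm^2/m^2)", lbm_kg = "LBM (kg)",
                  smg_hu_cm2_m2 = "SMG (HU.cm^2/m^2)")
  agree_rows <- lapply(names(quantities), function(f) {
    p <- vapply(pairs[ok], function(x) x$pred[[f]], 0)
    t <- vapply(pairs[ok], function(x) x$true[[f]], 0)
    keep <- !is.na(p) & !is.na(t)
    p <- p[keep]; t <- t[keep]
    row <- data.frame(quantity = quantities[[f]], mae = NA_real_,
                      mape = NA_real_, r2 = NA_real_, n = length(p))
    if (length(p) >= 1) row$mae <- mean(abs(p - t))
    if (length(p) >= 1 && all(t != 0))
      row$mape <- 100 * mean(abs(p - t) / abs(t))
    if (length(p) >= 2 && var(t) > 0)
      row$r2 <- 1 - sum((p - t)^2) / sum((t - mean(t))^2)
    row
  })
  structure(list(l3 = l3, dice = do.call(rbind, dice_rows),
                 agreement = do.call(rbind, agree_rows),
                 n = length(items), n_reported = sum(ok)),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf(
    "<evaluation_summary> %d scans (%d with tissue reports)\n", x$n,
    x$n_reported))
  cat(sprintf("  L3: MAE %.2f mm, correct-slice rate %.1f%% (tol %g mm)\n",
              x$l3$mae_mm, 100 * x$l3$correct_rate, x$l3$tolerance_mm))
  cat("  DICE by class:\n")
  print(x$dice, row.names = FALSE)
  cat("  Agreement:\n")
  print(x$agreement, row.names = FALSE)
  invisible(x)
}
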