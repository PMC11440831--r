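#' Scaled-down L3-localization experiment on synthetic phantoms
#'
#' End-to-end rehearsal of the L3 pipeline at desk scale: generate a
#' jittered phantom cohort (slice thickness drawn from \{1, 2.5, 5\} mm,
#' 10% implant and 20% arms fractions by default), preprocess every volume
#' to a standardized coronal projection, train the reduced L3 U-net
#' (depth 3, base 16, 15 epochs, Adam 1e-4, batch 8) on the training
#' split, and measure localization error on the held-out phantoms.
#'
#' @param n cohort size.
#' @param seed master seed; cohort, split, initialization and shuffling
#'   seeds are derived from it.
#' @param n_holdout phantoms held out for evaluation.
#' @param epochs training epochs.
#' @param base_spec base [phantom_spec()].
#' @param variability jitter ranges ([cohort_variability()]).
#' @param verbose print training progress.
#' @return list with `mae_mm`, `correct_rate` (20 mm tolerance, as a
#'   fraction), `errors_mm` (per held-out phantom), `n_test`, `n_train`,
#'   `history`, `model`.
#' @export
run_l3_experiment <- function(n = 200, seed = 42, n_holdout = 40,
                              epochs = 15, base_spec = phantom_spec(),
                              variability = cohort_variability(),
                              verbose = FALSE) {
  pre_cfg <- preprocess_preset("desk")
  specs <- cohort_specs(n, base_spec, variability, seed = seed)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(specs[[i]])
    proj <- prepare_projection(ph$volume, pre_cfg)
    target <- make_l3_target(ph$truth$l3_z_mm, proj$provenance,
                             dim(proj$image))
    samples[[i]] <- list(x = normalize_hu(proj$image),
                         y = to_onehot(target, 2L),
                         provenance = proj$provenance,
                         true_z_mm = ph$truth$l3_z_mm)
  }
  hold <- with_seed(seed + 1L, sample.int(n, n_holdout))
  ucfg <- unet_config(depth = 3L, base_filters = 16L,
                      input_shape = dim(samples[[1]]$x), n_classes = 2L,
                      seed = seed + 2L)
  tcfg <- train_config(learning_rate = 1e-4, batch_size = 8L,
                       max_epochs = epochs, patience = epochs,
                       seed = seed + 3L)
  fit <- train_model(build_unet(ucfg), samples[-hold], samples[hold],
                     tcfg, verbose = verbose)
  pred_z <- numeric(n_holdout)
  true_z <- numeric(n_holdout)
  for (j in seq_along(hold)) {
    s <- samples[[hold[j]]]
    probs <- unet_predict(fit$model, s$x)
    pred <- locate_l3(project_probability_signal(probs), s$provenance)
    pred_z[j] <- pred$z_mm
    true_z[j] <- s$true_z_mm
  }
  list(mae_mm = mean(abs(pred_z - true_z)),
       correct_rate = correct_slice_rate(pred_z, true_z, 20),
       errors_mm = abs(pred_z - true_z), n_test = n_holdout,
       n_train = n - n_holdout, history = fit$history, model = fit$model)
}

#' Scaled-down body-composition segmentation experiment
#'
#' Generates phantom L3 axial slices with ground-truth tissue maps, trains
#' the reduced body-composition U-net (depth 3, base 16, 15 epochs) and
#' reports per-class DICE on held-out slices after HU-window
#' post-filtering.
#'
#' @inheritParams run_l3_experiment
#' @return list with `dice` (per held-out slice x class matrix),
#'   `median_dice` (named vector over classes), `n_test`, `n_train`,
#'   `history`, `model`.
#' @export
run_bodycomp_experiment <- function(n = 200, seed = 7, n_holdout = 40,
                                    epochs = 15,
                                    base_spec = phantom_spec(),
                                    variability = cohort_variability(),
                                    verbose = FALSE) {
  specs <- cohort_specs(n, base_spec, variability, seed = seed)
  slices <- lapply(specs, generate_l3_sample)
  samples <- lapply(slices, function(s)
    list(x = normalize_hu(s$hu), y = to_onehot(s$labels$labels, 5L)))
  hold <- with_seed(seed + 1L, sample.int(n, n_holdout))
  ucfg <- unet_config(depth = 3L, base_filters = 16L,
                      input_shape = dim(samples[[1]]$x), n_classes = 5L,
                      seed = seed + 2L)
  tcfg <- train_config(learning_rate = 1e-4, batch_size = 8L,
                       max_epochs = epochs, patience = epochs,
                       seed = seed + 3L)
  fit <- train_model(build_unet(ucfg), samples[-hold], samples[hold],
                     tcfg, verbose = verbose)
  post <- postprocess_config()
  classes <- names(TISSUE_CODES)
  dice <- matrix(NA_real_, length(hold), length(classes),
                 dimnames = list(NULL, classes))
  for (j in seq_along(hold)) {
    s <- slices[[hold[j]]]
    labmap <- segment_slice(s$hu, fit$model, s$labels$spacing_mm, post)
    for (cl in classes)
      dice[j, cl] <- dice_coefficient(
        labmap$labels == TISSUE_CODES[[cl]],
        s$labels$labels == TISSUE_CODES[[cl]])
  }
  list(dice = dice, median_dice = apply(dice, 2, median),
       n_test = length(hold), n_train = n - length(hold),
       history = fit$history, model = fit$model)
}
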