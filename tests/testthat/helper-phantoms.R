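# Small phantom specs shared across tests. Kept deliberately coarse so a
# full volume generates in well under a second.

# Default-geometry phantom at test scale (64 slices x 32 x 32, 5 mm
# slices): long enough that the L3 level is abdominal (below the lungs).
small_spec <- function(seed = 1L, ...) {
  phantom_spec(shape_vox = c(64L, 32L, 32L), spacing_mm = c(5, 8, 8),
               body_halfaxes_mm = c(ap = 90, lr = 110), seed = seed, ...)
}

# Short-volume phantom whose lung and pelvic centroids are < 20 cm apart,
# so the pre-crop rule must leave it untouched.
short_spec <- function(seed = 1L, ...) {
  phantom_spec(shape_vox = c(50L, 32L, 32L), spacing_mm = c(4, 8, 8),
               body_halfaxes_mm = c(ap = 90, lr = 110),
               column_base_mm = 60, seed = seed, ...)
}

# Noise-free spec: deterministic tissue draw (sd 0 everywhere).
flat_spec <- function(seed = 1L, ...) {
  phantom_spec(shape_vox = c(64L, 32L, 32L), spacing_mm = c(5, 8, 8),
               body_halfaxes_mm = c(ap = 90, lr = 110),
               tissue_hu = list(air = c(-1000, 0), lung = c(-800, 0),
                                muscle = c(45, 0), VAT = c(-90, 0),
                                SAT = c(-105, 0), bone = c(400, 0),
                                implant = c(1500, 0)),
               seed = seed, ...)
}

# A small trained model pair (L3 + body composition), fitted once per test
# session on a handful of phantoms and cached. Deliberately overfit
# (high learning rate, training phantoms reused for validation): these
# models exist to exercise the inference chain, not to measure accuracy.
trained_models <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    n <- 10
    specs <- cohort_specs(n, phantom_spec(),
                          variability = list(column_base_mm = c(-20, 20)),
                          seed = 99L)
    pre <- preprocess_preset("desk")
    l3_samples <- lapply(specs, function(sp) {
      ph <- generate_phantom(sp)
      proj <- prepare_projection(ph$volume, pre)
      list(x = normalize_hu(proj$image),
           y = to_onehot(make_l3_target(ph$truth$l3_z_mm, proj$provenance,
                                        dim(proj$image)), 2L))
    })
    bc_samples <- lapply(specs, function(sp) {
      s <- generate_l3_sample(sp)
      list(x = normalize_hu(s$hu), y = to_onehot(s$labels$labels, 5L))
    })
    tc <- train_config(learning_rate = 2e-3, batch_size = 8L,
                       max_epochs = 8L, patience = 8L, seed = 1L)
    l3_fit <- train_model(build_unet(unet_preset("l3_desk")),
                          l3_samples, l3_samples, tc)
    bc_fit <- train_model(build_unet(unet_preset("bodycomp_desk")),
                          bc_samples, bc_samples, tc)
    cache <<- list(l3 = l3_fit$model, body = bc_fit$model, specs = specs,
                   pre = pre)
    cache
  }
})
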