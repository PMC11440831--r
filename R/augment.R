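#' Geometric augmentation configuration
#'
#' Ranges for the training-time augmentation: rotation, isotropic scaling,
#' translation and elastic deformation, applied identically to the image
#' and its target, plus random insertion of artificial arm sections
#' (soft-tissue-density ellipses painted lateral to the body) emulating
#' arms left in the field of view.
#'
#' @param rotate_deg rotation range (degrees).
#' @param scale isotropic scale-factor range (must be > 0).
#' @param translate_px translation range (pixels, both axes).
#' @param elastic_alpha displacement amplitude (pixels); 0 disables the
#'   elastic field.
#' @param elastic_sigma Gaussian smoothing sigma (pixels) of the elastic
#'   displacement field.
#' @param arm_prob probability of inserting an artificial arm pair.
#' @param arm_hu_range HU range of inserted arm tissue (soft tissue).
#' @return object of class `augment_config`.
#' @export
augment_config <- function(rotate_deg = c(-7, 7), scale = c(0.95, 1.05),
                           translate_px = c(-10, 10), elastic_alpha = 0,
                           elastic_sigma = 8, arm_prob = 0,
                           arm_hu_range = c(20, 70)) {
  if (any(scale <= 0)) stop("degenerate scale range (must be > 0)",
                            call. = FALSE)
  if (elastic_sigma <= 0) stop("elastic_sigma must be > 0", call. = FALSE)
  if (arm_prob < 0 || arm_prob > 1) stop("arm_prob must be in [0, 1]",
                                         call. = FALSE)
  stopifnot(length(rotate_deg) == 2, length(scale) == 2,
            length(translate_px) == 2)
  structure(list(rotate_deg = rotate_deg, scale = scale,
                 translate_px = translate_px, elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma, arm_prob = arm_prob,
                 arm_hu_range = arm_hu_range), class = "augment_config")
}

# Smooth a matrix with a separable Gaussian (replicate-padded edges).
smooth_field <- function(m, sigma) {
  m <- apply(m, 2, gauss_smooth, sigma = sigma)
  t(apply(m, 1, gauss_smooth, sigma = sigma))
}

# Sample one transform and build the inverse coordinate maps (source row /
# col per output pixel, 0-based).
sample_maps <- function(nr, nc, config) {
  theta <- runif(1, config$rotate_deg[1], config$rotate_deg[2]) * pi / 180
  s <- runif(1, config$scale[1], config$scale[2])
  tr <- runif(1, config$translate_px[1], config$translate_px[2])
  tc <- runif(1, config$translate_px[1], config$translate_px[2])
  cr <- (nr - 1) / 2; cc <- (nc - 1) / 2
  R <- matrix(seq_len(nr) - 1 - cr - tr, nr, nc)
  C <- matrix(seq_len(nc) - 1 - cc - tc, nr, nc, byrow = TRUE)
  map_r <- (cos(theta) * R - sin(theta) * C) / s + cr
  map_c <- (sin(theta) * R + cos(theta) * C) / s + cc
  if (config$elastic_alpha > 0) {
    dr <- smooth_field(matrix(runif(nr * nc, -1, 1), nr, nc),
                       config$elastic_sigma)
    dc <- smooth_field(matrix(runif(nr * nc, -1, 1), nr, nc),
                       config$elastic_sigma)
    map_r <- map_r + config$elastic_alpha * dr / max(abs(dr))
    map_c <- map_c + config$elastic_alpha * dc / max(abs(dc))
  }
  list(map_r = map_r, map_c = map_c)
}

# Paint an artificial arm pair lateral to the body on an HU image.
insert_arms <- function(img, config, body_threshold = -200) {
  nr <- nrow(img); nc <- ncol(img)
  body <- largest_component(img > body_threshold)
  if (is.null(body)) return(img)
  cols_in_body <- which(apply(body, 2, any))
  for (side in c("left", "right")) {
    a <- runif(1, 4, 9)                      # lateral semi-axis (px)
    b <- runif(1, 0.12 * nr, 0.35 * nr)      # longitudinal semi-axis (px)
    theta <- runif(1, -15, 15) * pi / 180
    ci <- runif(1, 0.3 * nr, 0.7 * nr)
    cj <- if (side == "left") max(1, min(cols_in_body) - 3 - a) else
      min(nc, max(cols_in_body) + 3 + a)
    R <- matrix(seq_len(nr) - ci, nr, nc)
    C <- matrix(seq_len(nc) - cj, nr, nc, byrow = TRUE)
    u <- cos(theta) * R - sin(theta) * C
    v <- sin(theta) * R + cos(theta) * C
    inside <- (u / b)^2 + (v / a)^2 <= 1
    paint <- inside & !body
    img[paint] <- runif(sum(paint), config$arm_hu_range[1],
                        config$arm_hu_range[2])
  }
  img
}

#' Augment a batch of image/target pairs
#'
#' Applies one randomly sampled geometric transform (rotation, scale,
#' translation, optional elastic deformation) per pair -- bilinear
#' resampling for the image, nearest-neighbour for the target so label
#' codes survive -- and optionally paints artificial arm sections outside
#' the body mask. Deterministic given `seed`; with all ranges zero and
#' `arm_prob` 0 the batch is returned unchanged.
#'
#' @param images list of HU matrices.
#' @param targets list of matching target matrices (binary masks or label
#'   maps).
#' @param config an [augment_config()].
#' @param seed integer seed.
#' @param fill_hu background fill for resampled images.
#' @return list with `images` and `targets`, same lengths as the input.
#' @export
augment_batch <- function(images, targets, config = augment_config(),
                          seed = 1L, fill_hu = -1000) {
  stopifnot(inherits(config, "augment_config"),
            length(images) == length(targets))
  with_seed(seed, {
    out_i <- vector("list", length(images))
    out_t <- vector("list", length(targets))
    for (k in seq_along(images)) {
      img <- images[[k]]; tgt <- targets[[k]]
      stopifnot(all(dim(img) == dim(tgt)))
      identity_tf <- all(config$rotate_deg == 0) &&
        all(config$scale == 1) && all(config$translate_px == 0) &&
        config$elastic_alpha == 0
      if (!identity_tf) {
        maps <- sample_maps(nrow(img), ncol(img), config)
        img <- cpp_warp_bilinear(img, maps$map_r, maps$map_c, fill_hu)
        tgt <- cpp_warp_nearest(tgt, maps$map_r, maps$map_c, 0)
      }
      if (config$arm_prob > 0 && runif(1) < config$arm_prob)
        img <- insert_arms(img, config)
      out_i[[k]] <- img; out_t[[k]] <- tgt
    }
    list(images = out_i, targets = out_t)
  })
}
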