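#' U-net architecture configuration
#'
#' A standard U-net: `depth` encoder levels of two 3 x 3 convolutions +
#' ReLU followed by 2 x 2 max pooling, a two-convolution bottleneck, and a
#' symmetric decoder (2 x upsampling, a channel-halving convolution, skip
#' concatenation, two convolutions), closed by a 1 x 1 convolution and a
#' per-pixel softmax. Filters double at each level down and halve back up:
#' level k carries `base_filters * 2^(k-1)` channels.
#'
#' @param depth number of down/up-sampling levels.
#' @param base_filters filters in the first encoder level (64 for the
#'   full-scale L3 task, 32 for full-scale body composition; 16 in the
#'   reduced desk presets).
#' @param input_shape (rows, cols); each must be divisible by `2^depth`.
#' @param n_classes output classes (2 for L3-band detection, 5 for tissue
#'   classes).
#' @param kernel convolution kernel size (odd).
#' @param seed seed for the random weight initialization.
#' @return object of class `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_filters = 64L,
                        input_shape = c(1088L, 512L), n_classes = 2L,
                        kernel = 3L, seed = 1L) {
  if (kernel %% 2 != 1) stop("kernel size must be odd", call. = FALSE)
  if (any(input_shape %% 2^depth != 0))
    stop("input dimensions (", paste(input_shape, collapse = " x "),
         ") must be divisible by 2^depth = ", 2^depth, call. = FALSE)
  if (n_classes < 2) stop("need at least 2 classes", call. = FALSE)
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 kernel = as.integer(kernel), seed = as.integer(seed)),
            class = "unet_config")
}

#' @rdname unet_config
#' @param name preset name. `l3_full` / `bodycomp_full` mirror the
#'   reference design (depth 4, base 64 on 1088 x 512 / base 32 on
#'   512 x 512); `l3_desk` / `bodycomp_desk` are reduced profiles (depth 3,
#'   base 16 on 208 x 32 / 64 x 64) sized for CPU experiments.
#' @export
unet_preset <- function(name = c("l3_desk", "bodycomp_desk", "l3_full",
                                 "bodycomp_full"), seed = 1L) {
  switch(match.arg(name),
    l3_full = unet_config(4L, 64L, c(1088L, 512L), 2L, seed = seed),
    bodycomp_full = unet_config(4L, 32L, c(512L, 512L), 5L, seed = seed),
    l3_desk = unet_config(3L, 16L, c(144L, 32L), 2L, seed = seed),
    bodycomp_desk = unet_config(3L, 16L, c(64L, 64L), 5L, seed = seed))
}

#' Encoder filter progression of a configuration
#'
#' @param config a [unet_config()].
#' @return integer vector of length `depth + 1`: filters per encoder level
#'   and at the bottleneck.
#' @export
unet_filter_sequence <- function(config)
  as.integer(config$base_filters * 2^(0:config$depth))

new_conv <- function(cin, cout, k, norm = TRUE) {
  # gamma/beta are the learnable scale/shift of the per-channel instance
  # normalization that follows every hidden convolution
  list(w = matrix(rnorm(k * k * cin * cout) * sqrt(2 / (k * k * cin)),
                  k * k * cin, cout),
       b = numeric(cout), k = as.integer(k), norm = norm,
       g = if (norm) rep(1, cout), be = if (norm) numeric(cout))
}

#' Build a U-net model with randomly initialized weights
#'
#' @param config a [unet_config()].
#' @return object of class `unet_model` holding the configuration and the
#'   parameter list; weights are He-initialized from `config$seed`.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  d <- config$depth; k <- config$kernel
  f <- unet_filter_sequence(config)  # f[1..d] levels, f[d+1] bottleneck
  with_seed(config$seed, {
    p <- list()
    for (lev in seq_len(d)) {
      cin <- if (lev == 1) 1L else f[lev - 1]
      p[[paste0("enc", lev, "_c1")]] <- new_conv(cin, f[lev], k)
      p[[paste0("enc", lev, "_c2")]] <- new_conv(f[lev], f[lev], k)
    }
    p[["bot_c1"]] <- new_conv(f[d], f[d + 1], k)
    p[["bot_c2"]] <- new_conv(f[d + 1], f[d + 1], k)
    for (lev in d:1) {
      cin <- if (lev == d) f[d + 1] else f[lev + 1]
      p[[paste0("dec", lev, "_up")]] <- new_conv(cin, f[lev], k)
      p[[paste0("dec", lev, "_c1")]] <- new_conv(2L * f[lev], f[lev], k)
      p[[paste0("dec", lev, "_c2")]] <- new_conv(f[lev], f[lev], k)
    }
    p[["out"]] <- new_conv(f[1], config$n_classes, 1L, norm = FALSE)
    structure(list(config = config, params = p, opt = NULL),
              class = "unet_model")
  })
}

#' @export
print.unet_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, function(p) length(p$w) + length(p$b), 0))
  cat(sprintf(
    "<unet_model> depth %d, filters %s, input %d x %d, %d classes (%s parameters)\n",
    cfg$depth, paste(unet_filter_sequence(cfg), collapse = "-"),
    cfg$input_shape[1], cfg$input_shape[2], cfg$n_classes,
    format(n_par, big.mark = ",")))
  invisible(x)
}

softmax_channels <- function(z) {
  K <- dim(z)[3]
  m <- z[, , 1]
  for (c in 2:K) m <- pmax(m, z[, , c])
  e <- exp(z - array(m, dim(z)))
  s <- e[, , 1]
  for (c in 2:K) s <- s + e[, , c]
  e / array(s, dim(z))
}

as_input_cube <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

IN_EPS <- 1e-5

# Forward pass; with cache = TRUE also returns everything the backward
# pass needs (per-conv inputs, normalization statistics, ReLU masks, pool
# indices).
unet_forward <- function(model, x, cache = FALSE) {
  P <- model$params
  d <- model$config$depth
  cin <- list(); mask <- list(); pidx <- list(); pdim <- list()
  xhat <- list(); inv_sd <- list()
  conv_relu <- function(a, name, relu = TRUE) {
    p <- P[[name]]
    if (cache) cin[[name]] <<- a
    y <- cpp_conv2d(a, p$w, p$b, p$k)
    if (p$norm) {
      dm <- dim(y); hw <- dm[1] * dm[2]; C <- dm[3]
      m <- matrix(y, hw, C)
      mu <- .colMeans(m, hw, C)
      m <- m - rep(mu, each = hw)
      isd <- 1 / sqrt(.colMeans(m * m, hw, C) + IN_EPS)
      m <- m * rep(isd, each = hw)
      if (cache) { xhat[[name]] <<- m; inv_sd[[name]] <<- isd }
      y <- array(m * rep(p$g, each = hw) + rep(p$be, each = hw), dm)
    }
    if (relu) {
      y[y < 0] <- 0
      if (cache) mask[[name]] <<- y > 0
    }
    y
  }
  a <- as_input_cube(x)
  skips <- vector("list", d)
  for (lev in seq_len(d)) {
    a <- conv_relu(a, paste0("enc", lev, "_c1"))
    a <- conv_relu(a, paste0("enc", lev, "_c2"))
    skips[[lev]] <- a
    mp <- cpp_maxpool2(a)
    if (cache) { pidx[[lev]] <- mp$idx; pdim[[lev]] <- dim(a)[1:2] }
    a <- mp$y
  }
  a <- conv_relu(a, "bot_c1")
  a <- conv_relu(a, "bot_c2")
  for (lev in d:1) {
    a <- cpp_upsample2(a)
    a <- conv_relu(a, paste0("dec", lev, "_up"))
    a <- array(c(a, skips[[lev]]),
               c(dim(a)[1:2], dim(a)[3] + dim(skips[[lev]])[3]))
    a <- conv_relu(a, paste0("dec", lev, "_c1"))
    a <- conv_relu(a, paste0("dec", lev, "_c2"))
  }
  logits <- conv_relu(a, "out", relu = FALSE)
  probs <- softmax_channels(logits)
  if (!cache) return(probs)
  list(probs = probs, cin = cin, mask = mask, pidx = pidx, pdim = pdim,
       xhat = xhat, inv_sd = inv_sd)
}

#' Predict class-probability maps
#'
#' @param model a trained [build_unet()] model.
#' @param x input image (matrix) or H x W x C array matching the model's
#'   input shape.
#' @return H x W x `n_classes` array of per-pixel class probabilities
#'   (each pixel sums to 1).
#' @export
unet_predict <- function(model, x) unet_forward(model, x, cache = FALSE)

# Backward pass: gradient of the loss w.r.t. every parameter given
# dL/dprobs. Returns a list of gradients parallel to model$params.
unet_backward <- function(model, fw, dprobs) {
  P <- model$params
  d <- model$config$depth
  probs <- fw$probs
  K <- dim(probs)[3]
  inner <- dprobs[, , 1] * probs[, , 1]
  for (c in 2:K) inner <- inner + dprobs[, , c] * probs[, , c]
  dz <- probs * (dprobs - array(inner, dim(probs)))

  g <- list()
  conv_back <- function(dy, name, relu = TRUE) {
    p <- P[[name]]
    if (relu) dy <- dy * fw$mask[[name]]
    extra <- NULL
    if (p$norm) {
      dm <- dim(dy); hw <- dm[1] * dm[2]; C <- dm[3]
      dym <- matrix(dy, hw, C)
      xh <- fw$xhat[[name]]
      dg <- .colSums(dym * xh, hw, C)
      dbe <- .colSums(dym, hw, C)
      dxh <- dym * rep(p$g, each = hw)
      s1 <- .colSums(dxh, hw, C)
      s2 <- .colSums(dxh * xh, hw, C)
      dz <- (dxh - rep(s1 / hw, each = hw) -
               xh * rep(s2 / hw, each = hw)) *
        rep(fw$inv_sd[[name]], each = hw)
      dy <- array(dz, dm)
      extra <- list(g = dg, be = dbe)
    }
    r <- cpp_conv2d_grad(fw$cin[[name]], p$w, dy, p$k)
    g[[name]] <<- c(list(w = r$dw, b = r$db), extra)
    r$dx
  }
  dy <- conv_back(dz, "out", relu = FALSE)
  dskips <- vector("list", d)
  for (lev in seq_len(d)) {
    dy <- conv_back(dy, paste0("dec", lev, "_c2"))
    dy <- conv_back(dy, paste0("dec", lev, "_c1"))
    f <- dim(fw$cin[[paste0("dec", lev, "_c1")]])[3] %/% 2  # up-branch channels
    dskips[[lev]] <- dy[, , (f + 1):(2 * f), drop = FALSE]
    dy <- dy[, , 1:f, drop = FALSE]
    dy <- conv_back(dy, paste0("dec", lev, "_up"))
    dy <- cpp_upsample2_grad(dy)
  }
  dy <- conv_back(dy, "bot_c2")
  dy <- conv_back(dy, "bot_c1")
  for (lev in d:1) {
    dy <- cpp_maxpool2_grad(dy, fw$pidx[[lev]], fw$pdim[[lev]][1],
                            fw$pdim[[lev]][2])
    dy <- dy + dskips[[lev]]
    dy <- conv_back(dy, paste0("enc", lev, "_c2"))
    dy <- conv_back(dy, paste0("enc", lev, "_c1"))
  }
  g
}

#' Soft dice loss
#'
#' `1 - (2 * sum(p * g) + s) / (sum(p) + sum(g) + s)` with smoothing
#' constant `s`; 0 for perfect binary agreement, up to 1 for disjoint
#' maps, and 0 when both maps are empty (the smoothing convention). For a
#' multi-class probability array (classes along the third dimension versus
#' a one-hot target) the loss is the unweighted mean over foreground
#' classes (all classes but the first, background, channel).
#'
#' @param pred probability matrix, or H x W x K array.
#' @param target binary matrix, or one-hot H x W x K array.
#' @param smooth smoothing constant (default 1).
#' @param foreground class channels averaged over in the multi-class case;
#'   defaults to all but channel 1.
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(pred, target, smooth = 1, foreground = NULL) {
  stopifnot(all(dim(pred) == dim(target)))
  one <- function(p, g)
    1 - (2 * sum(p * g) + smooth) / (sum(p) + sum(g) + smooth)
  if (length(dim(pred)) == 2) return(one(pred, target))
  K <- dim(pred)[3]
  if (is.null(foreground)) foreground <- 2:K
  mean(vapply(foreground, function(c) one(pred[, , c], target[, , c]), 0))
}

# Gradient of dice_loss w.r.t. the probability array (zero on channels
# outside `foreground`).
dice_loss_grad <- function(pred, target, smooth = 1, foreground = NULL) {
  if (length(dim(pred)) == 2) {
    pred <- array(pred, c(dim(pred), 1L)); target <- array(target, dim(pred))
    foreground <- 1L
  }
  K <- dim(pred)[3]
  if (is.null(foreground)) foreground <- 2:K
  g <- array(0, dim(pred))
  for (c in foreground) {
    p <- pred[, , c]; t <- target[, , c]
    num <- 2 * sum(p * t) + smooth
    den <- sum(p) + sum(t) + smooth
    g[, , c] <- -(2 * t * den - num) / den^2 / length(foreground)
  }
  g
}

#' One-hot encode an integer label matrix
#'
#' @param labels matrix of class codes `0 .. n_classes - 1`.
#' @param n_classes number of classes.
#' @return H x W x `n_classes` binary array.
#' @export
to_onehot <- function(labels, n_classes) {
  y <- array(0, c(dim(labels), n_classes))
  for (c in seq_len(n_classes)) y[, , c] <- (labels == c - 1) * 1
  y
}

# Per-pixel argmax (ties resolved toward the lowest class code).
argmax_channels <- function(probs) {
  K <- dim(probs)[3]
  lab <- matrix(0L, dim(probs)[1], dim(probs)[2])
  best <- probs[, , 1]
  for (c in 2:K) {
    upd <- probs[, , c] > best
    lab[upd] <- c - 1L
    best[upd] <- probs[, , c][upd]
  }
  lab
}

# Mean hard dice over foreground classes of one prediction.
hard_dice <- function(probs, y_onehot, foreground = NULL) {
  K <- dim(probs)[3]
  if (is.null(foreground)) foreground <- 2:K
  lab <- argmax_channels(probs)
  truth <- argmax_channels(y_onehot)
  mean(vapply(foreground, function(c)
    dice_coefficient(lab == c - 1, truth == c - 1), 0))
}
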