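#' Training configuration
#'
#' Adam optimization under the dice loss with per-epoch validation. The
#' defaults follow the reference recipe: learning rate 1e-4, batch size 8,
#' up to 100 epochs with early stopping on the validation loss; the
#' checkpoint returned is the epoch with the best validation DICE.
#' Early-stopping semantics: training stops once the validation loss has
#' failed to improve by more than `min_delta` for `patience` consecutive
#' epochs, so with a strictly worsening loss exactly `1 + patience` epochs
#' run.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size images per optimization step.
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience in epochs (>= 1).
#' @param min_delta minimum validation-loss improvement that resets the
#'   patience counter.
#' @param grad_clip_norm rescale each batch gradient so its global L2 norm
#'   does not exceed this value; guards the dice loss against its known
#'   all-background collapse mode. `Inf` disables clipping.
#' @param seed seed for shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 8L,
                         max_epochs = 100L, patience = 10L,
                         min_delta = 1e-4, grad_clip_norm = 1,
                         seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, min_delta >= 0, grad_clip_norm > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 grad_clip_norm = grad_clip_norm,
                 seed = as.integer(seed)), class = "train_config")
}

PARAM_PARTS <- c("w", "b", "g", "be")

param_parts <- function(p) intersect(PARAM_PARTS, names(p)[!vapply(p, is.null, TRUE)])

adam_init <- function(params) {
  zero <- function(p) lapply(p[param_parts(p)], function(x) x * 0)
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

adam_step <- function(model, grads, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(model$opt)) model$opt <- adam_init(model$params)
  o <- model$opt
  o$t <- o$t + 1L
  c1 <- 1 - b1^o$t; c2 <- 1 - b2^o$t
  for (nm in names(grads)) {
    for (part in names(grads[[nm]])) {
      g <- grads[[nm]][[part]]
      o$m[[nm]][[part]] <- b1 * o$m[[nm]][[part]] + (1 - b1) * g
      o$v[[nm]][[part]] <- b2 * o$v[[nm]][[part]] + (1 - b2) * g^2
      model$params[[nm]][[part]] <- model$params[[nm]][[part]] -
        lr * (o$m[[nm]][[part]] / c1) /
          (sqrt(o$v[[nm]][[part]] / c2) + eps)
    }
  }
  model$opt <- o
  model
}

# Mean dice loss and mean hard foreground dice over a sample list.
evaluate_samples <- function(model, samples, smooth = 1) {
  losses <- numeric(length(samples))
  dices <- numeric(length(samples))
  for (i in seq_along(samples)) {
    probs <- unet_forward(model, samples[[i]]$x)
    losses[i] <- dice_loss(probs, samples[[i]]$y, smooth = smooth)
    dices[i] <- hard_dice(probs, samples[[i]]$y)
  }
  c(loss = mean(losses), dice = mean(dices))
}

#' Train a U-net under the dice loss
#'
#' Mini-batch Adam with per-epoch validation. The history records one row
#' per epoch (train loss, validation loss, validation DICE); the returned
#' model carries the weights of the epoch with the highest validation
#' DICE. Fully deterministic given the model's initialization seed and
#' `config$seed`.
#'
#' @param model a [build_unet()] model.
#' @param train,val non-empty lists of samples, each a list with `x`
#'   (input matrix/array) and `y` (one-hot target array).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint), `history` (data.frame),
#'   `best_epoch`.
#' @export
train_model <- function(model, train, val, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  if (length(train) == 0 || length(val) == 0)
    stop("training and validation sets must be non-empty", call. = FALSE)
  n <- length(train)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_dice = numeric())
  best_dice <- -Inf; best_params <- model$params; best_epoch <- 0L
  best_loss <- Inf; wait <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        grads <- NULL
        bloss <- 0
        for (i in idx) {
          fw <- unet_forward(model, train[[i]]$x, cache = TRUE)
          bloss <- bloss + dice_loss(fw$probs, train[[i]]$y)
          dp <- dice_loss_grad(fw$probs, train[[i]]$y)
          g <- unet_backward(model, fw, dp)
          if (is.null(grads)) grads <- g
          else for (nm in names(g))
            for (part in names(g[[nm]]))
              grads[[nm]][[part]] <- grads[[nm]][[part]] + g[[nm]][[part]]
        }
        for (nm in names(grads))
          for (part in names(grads[[nm]]))
            grads[[nm]][[part]] <- grads[[nm]][[part]] / length(idx)
        if (is.finite(config$grad_clip_norm)) {
          gnorm <- sqrt(sum(vapply(grads, function(g)
            sum(vapply(g, function(x) sum(x^2), 0)), 0)))
          if (gnorm > config$grad_clip_norm) {
            scale <- config$grad_clip_norm / gnorm
            for (nm in names(grads))
              for (part in names(grads[[nm]]))
                grads[[nm]][[part]] <- grads[[nm]][[part]] * scale
          }
        }
        bloss <- bloss / length(idx)
        if (!is.finite(bloss))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        ep_loss <- ep_loss + bloss * length(idx)
        model <- adam_step(model, grads, config$learning_rate)
      }
      ev <- evaluate_samples(model, val)
      if (!is.finite(ev["loss"]))
        stop("training diverged (non-finite validation loss) at epoch ",
             epoch, call. = FALSE)
      hist[epoch, ] <- list(epoch, ep_loss / n, unname(ev["loss"]),
                            unname(ev["dice"]))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  dice %.4f",
                        epoch, ep_loss / n, ev["loss"], ev["dice"]))
      if (ev["dice"] > best_dice) {
        best_dice <- ev["dice"]; best_params <- model$params
        best_epoch <- epoch
      }
      if (ev["loss"] < best_loss - config$min_delta) {
        best_loss <- ev["loss"]; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$params <- best_params
  list(model = model, history = hist, best_epoch = best_epoch)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the architecture configuration and weights, so a
#' loaded model is ready for [unet_predict()].
#'
#' @param model a `unet_model`.
#' @param path checkpoint path (`.rds`).
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  model$opt <- NULL
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model")) stop("not a unet_model checkpoint")
  model
}

#' k-fold cross-validation harness
#'
#' Seeded random partition of the samples into `k` folds; each sample is
#' validated exactly once. Per-fold metrics come from `eval_fn` (default:
#' mean validation dice loss and hard DICE), aggregated as mean and sd.
#'
#' @param samples list of training samples (`x`, `y`).
#' @param unet_cfg a [unet_config()].
#' @param train_cfg a [train_config()].
#' @param k number of folds (default 5).
#' @param eval_fn `function(trained_model, val_samples)` returning a named
#'   numeric vector.
#' @param seed partition seed.
#' @return list with `folds` (data.frame of per-fold metrics), `mean`,
#'   `sd`, and `assignments` (fold id per sample).
#' @export
run_kfold_cv <- function(samples, unet_cfg, train_cfg, k = 5L,
                         eval_fn = NULL, seed = 1L) {
  n <- length(samples)
  if (n < k) stop("need at least k = ", k, " samples", call. = FALSE)
  if (is.null(eval_fn))
    eval_fn <- function(model, val) evaluate_samples(model, val)
  assignments <- with_seed(seed,
    sample(rep(seq_len(k), length.out = n)))
  rows <- vector("list", k)
  for (fold in seq_len(k)) {
    val_idx <- which(assignments == fold)
    fit <- train_model(build_unet(unet_cfg), samples[-val_idx],
                       samples[val_idx], train_cfg)
    rows[[fold]] <- c(fold = fold, eval_fn(fit$model, samples[val_idx]))
  }
  folds <- as.data.frame(do.call(rbind, rows))
  metrics <- setdiff(names(folds), "fold")
  list(folds = folds, mean = colMeans(folds[metrics]),
       sd = apply(folds[metrics], 2, sd), assignments = assignments)
}
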