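##
## Training: class-weighted Dice loss, k-fold plans, the fine-tuning loop
## (Adam, fixed epoch count, no schedule) and softmax-averaged ensembling.
##

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with `beta1 = 0.9`,
#' `beta2 = 0.999`, `epsilon = 1e-8`, learning rate `1e-4`, 100 epochs,
#' batches of 4, equal class weights `(0.5, 0.5)` in the Dice loss, and
#' 10-fold cross-validation.
#'
#' @param lr learning rate.
#' @param beta1,beta2,epsilon Adam moment decays and stabiliser.
#' @param epochs number of passes over the (augmented) training pool.
#' @param batch_size images per gradient step.
#' @param class_weights `c(C0, C1)` weights of background and plaque in
#'   the Dice loss.
#' @param seed seed for weight init and data order.
#' @param folds `k` of the cross-validation.
#' @export
train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, epochs = 100L, batch_size = 4L,
                         class_weights = c(0.5, 0.5), seed = 1L,
                         folds = 10L) {
  if (lr <= 0) stop("lr must be > 0", call. = FALSE)
  if (any(class_weights < 0)) stop("class_weights must be >= 0", call. = FALSE)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 class_weights = class_weights, seed = as.integer(seed),
                 folds = as.integer(folds)),
            class = "train_config")
}

#' One-hot encoding of a binary label mask
#'
#' @param mask H x W binary matrix (1 = plaque).
#' @return array `(H, W, 2)`: channel 1 background, channel 2 plaque.
#' @export
label_to_onehot <- function(mask) {
  check_binary(mask, "label")
  out <- array(0, dim = c(dim(mask), 2L))
  out[, , 1] <- 1 - mask
  out[, , 2] <- mask
  out
}

## Loss and gradient with respect to the softmax probabilities.
## Per image e-th class term: C_e * (1 - 2*sum(L_e S_e)/(sum L_e + sum S_e)),
## summed over classes, averaged over the batch.  A smoothing epsilon keeps
## empty-class images finite.
dice_loss_grad <- function(pred, label, weights, eps = 1e-6) {
  pred <- as_nchw(pred); label <- as_nchw(label)
  C <- dim(pred)[3]; N <- dim(pred)[4]
  loss <- 0
  dpred <- pred * 0
  for (n in seq_len(N)) {
    for (e in seq_len(C)) {
      L <- label[, , e, n]; S <- pred[, , e, n]
      I <- sum(L * S)
      D <- sum(L) + sum(S) + eps
      loss <- loss + weights[e] * (1 - 2 * I / D) / N
      dpred[, , e, n] <- -weights[e] * 2 * (L * D - I) / D^2 / N
    }
  }
  list(loss = loss, dpred = dpred)
}

#' Class-weighted Dice loss
#'
#' `L = sum_e C_e * (1 - 2 sum(L_e S_e) / (sum L_e + sum S_e))` over the
#' background/plaque one-hot channels, pixels summed over the full frame;
#' 0 for a perfect prediction and `C0 + C1` in the worst case.  For a
#' batch the per-image losses are averaged.
#'
#' @param pred probability map `(H, W, 2)` or `(H, W, 2, N)`; per-pixel
#'   channel sums must be 1.
#' @param label_onehot one-hot label of the same shape.
#' @param weights `c(C0, C1)` class weights.
#' @param eps smoothing constant guarding empty-class denominators.
#' @export
dice_loss <- function(pred, label_onehot, weights = c(0.5, 0.5),
                      eps = 1e-6) {
  if (!identical(dim(as_nchw(pred)), dim(as_nchw(label_onehot))))
    stop("prediction and label shapes differ", call. = FALSE)
  dice_loss_grad(pred, label_onehot, weights, eps)$loss
}

#' Deterministic k-fold plan
#'
#' Shuffles `1..n` with the seed and deals the samples round-robin into
#' `k` folds, so fold sizes differ by at most one; with `n = 40`,
#' `k = 10` every fold holds exactly 4 test images.
#'
#' @param n number of samples (`>= k`).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return list with `fold_assignments` (length-`n` integer vector) and
#'   `k`.
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (n < k) stop("need n >= k", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  list(fold_assignments = fold, k = as.integer(k))
}

## One Adam step on a batch; returns the updated model and the loss.
train_step <- function(model, xb, yb, config) {
  r <- hrunet_tape(model, xb, training = TRUE)
  logits <- r$tp$val[[r$logits]]
  probs <- softmax_channels(logits)
  lg <- dice_loss_grad(probs, yb, config$class_weights)
  dz <- softmax_backward(probs, lg$dpred)
  grads <- tape_backward(r$tp, r$logits, dz)
  for (nm in names(r$tp$new_stats)) {
    model$units[[nm]]$rm <- r$tp$new_stats[[nm]]$rm
    model$units[[nm]]$rv <- r$tp$new_stats[[nm]]$rv
  }
  model <- adam_step(model, grads, config$lr, config$beta1, config$beta2,
                     config$epsilon)
  list(model = model, loss = lg$loss)
}

#' Train one model on an augmented training pool
#'
#' Runs `config$epochs` passes over `train_pairs` with the weighted Dice
#' loss and Adam; the pool is reshuffled each epoch from the run seed, so
#' identical seeds give bitwise-identical loss histories.
#'
#' @param train_pairs list of `list(image, label)` pairs, normally from
#'   [build_training_set()] (held-out test images must not be included).
#' @param config a [train_config()].
#' @param model_config a [model_config()], or an existing `hrunet` model
#'   to continue training.
#' @param verbose print per-epoch mean loss.
#' @return list with `model` and `history` (per-epoch mean loss, length
#'   `config$epochs`).
#' @export
train_fold <- function(train_pairs, config = train_config(),
                       model_config = model_config(), verbose = FALSE) {
  if (length(train_pairs) == 0L)
    stop("empty training set", call. = FALSE)
  if (inherits(model_config, "hrunet")) {
    model <- model_config
  } else {
    mc <- model_config
    mc$seed <- if (is.null(mc$seed)) config$seed else mc$seed
    model <- build_hrunet(mc)
  }
  d <- dim(train_pairs[[1]]$image)
  set.seed(config$seed + 1L)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(train_pairs))
    losses <- c()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      nb <- length(idx)
      xb <- array(0, dim = c(d[1], d[2], 1L, nb))
      yb <- array(0, dim = c(d[1], d[2], 2L, nb))
      for (j in seq_len(nb)) {
        xb[, , 1, j] <- train_pairs[[idx[j]]]$image
        yb[, , , j] <- label_to_onehot(train_pairs[[idx[j]]]$label)
      }
      st <- train_step(model, xb, yb, config)
      model <- st$model
      losses <- c(losses, st$loss)
    }
    history[ep] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %d/%d  dice-loss %.4f", ep, config$epochs,
                      history[ep]))
  }
  list(model = model, history = history)
}

#' Softmax-averaged ensemble prediction
#'
#' Per-pixel arithmetic mean of the softmax probability maps of `k`
#' trained models; the average stays normalised, and the hard mask is the
#' per-pixel arg-max (see [prob_to_mask()]).
#'
#' @param models nonempty list of `hrunet` models sharing the input
#'   contract.
#' @param image grayscale matrix (or batch array).
#' @return averaged probability map `(H, W, 2, N)`.
#' @export
ensemble_predict <- function(models, image) {
  if (length(models) == 0L)
    stop("need at least one model", call. = FALSE)
  acc <- predict_hrunet(models[[1]], image)
  for (m in models[-1]) acc <- acc + predict_hrunet(m, image)
  acc / length(models)
}
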