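# Small-scale fixtures and independent oracles used across the suite.

# Desk-scale phantom (32 x 64) for fast structural tests.
tiny_phantom_params <- function(seed = 1L, n_plaques = 1L) {
  phantom_params(height = 32L, width = 64L, lumen_half_thickness = 6L,
                 wall_thickness = 3L, plaque_axis_range = c(3L, 5L),
                 n_plaques = n_plaques, seed = seed)
}

# 64 x 64 phantom used by the learning smoke tests.
small_phantom_params <- function(seed = 1L) {
  phantom_params(height = 64L, width = 64L, lumen_half_thickness = 12L,
                 wall_thickness = 5L, plaque_axis_range = c(5L, 11L),
                 n_plaques = 2L, seed = seed)
}

tiny_model_config <- function(seed = 1L, ...) {
  model_config(in_height = 32L, in_width = 64L, seed = seed, ...)
}

random_mask <- function(h = 12L, w = 12L, p = 0.3) {
  matrix(stats::rbinom(h * w, 1L, p), h, w)
}

# Brute-force metric oracles: direct pixel loops, independent of the
# package implementations.
oracle_counts <- function(L, S) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(L))) for (j in seq_len(ncol(L))) {
    if (L[i, j] == 1 && S[i, j] == 1) tp <- tp + 1
    else if (L[i, j] == 0 && S[i, j] == 0) tn <- tn + 1
    else if (L[i, j] == 0 && S[i, j] == 1) fp <- fp + 1
    else fn <- fn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}
oracle_dice <- function(L, S) {
  k <- oracle_counts(L, S)
  if (sum(L) + sum(S) == 0) return(1)
  2 * k$tp / (2 * k$tp + k$fp + k$fn)
}
oracle_iou <- function(L, S) {
  k <- oracle_counts(L, S)
  if (k$tp + k$fp + k$fn == 0) return(1)
  k$tp / (k$tp + k$fp + k$fn)
}
oracle_acc <- function(L, S) {
  k <- oracle_counts(L, S)
  (k$tp + k$tn) / (k$tp + k$tn + k$fp + k$fn)
}
oracle_mhd <- function(A, B) {
  dmin <- function(p, Q) {
    best <- Inf
    for (q in seq_len(nrow(Q)))
      best <- min(best, sqrt(sum((p - Q[q, ])^2)))
    best
  }
  dab <- mean(vapply(seq_len(nrow(A)), function(i) dmin(A[i, ], B), 0))
  dba <- mean(vapply(seq_len(nrow(B)), function(i) dmin(B[i, ], A), 0))
  max(dab, dba)
}

# Direct evaluation of the weighted Dice loss from its definition.
oracle_dice_loss <- function(pred, label, weights = c(0.5, 0.5),
                             eps = 1e-6) {
  loss <- 0
  for (e in 1:2) {
    I <- sum(label[, , e] * pred[, , e])
    D <- sum(label[, , e]) + sum(pred[, , e]) + eps
    loss <- loss + weights[e] * (1 - 2 * I / D)
  }
  loss
}

# Naive dilated cross-correlation oracle for the conv kernels.
naive_conv <- function(x, w, stride, pad, dil) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; N <- dim(x)[4]
  K <- dim(w)[1]; Cout <- dim(w)[4]
  eff <- dil * (K - 1) + 1
  Ho <- (H + 2 * pad - eff) %/% stride + 1
  Wo <- (W + 2 * pad - eff) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (o in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    s <- 0
    for (c in 1:Cin) for (i in 1:K) for (j in 1:K) {
      hi <- (ho - 1) * stride - pad + dil * (i - 1) + 1
      wi <- (wo - 1) * stride - pad + dil * (j - 1) + 1
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        s <- s + x[hi, wi, c, n] * w[i, j, c, o]
    }
    out[ho, wo, o, n] <- s
  }
  out
}

# Central finite differences of sum(f(a) * dout) with respect to a.
numeric_grad <- function(f, a, eps = 1e-6) {
  g <- a * 0
  for (i in seq_along(a)) {
    a1 <- a; a1[i] <- a1[i] + eps
    a2 <- a; a2[i] <- a2[i] - eps
    g[i] <- (f(a1) - f(a2)) / (2 * eps)
  }
  g
}

# Nonzero extent of the response to a single-pixel impulse pushed through
# an actual dilated-conv cascade (all-ones kernels): a brute-force
# receptive-field measurement.
impulse_extent <- function(rates, kernel = 3L, size = 33L) {
  x <- array(0, c(size, size, 1L, 1L))
  x[(size + 1) %/% 2, (size + 1) %/% 2, 1, 1] <- 1
  w <- array(1, c(kernel, kernel, 1L, 1L))
  conv <- getFromNamespace("cpp_conv2d_fwd", "plaqueseg")
  for (r in rates)
    x <- conv(x, w, NULL, 1L, as.integer(r * (kernel - 1L) %/% 2L),
              as.integer(r))
  nz <- which(x[, , 1, 1] != 0, arr.ind = TRUE)
  max(nz[, 1]) - min(nz[, 1]) + 1L
}
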