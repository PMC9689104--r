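##
## Minimal reverse-mode engine over the C++ tensor kernels.
##
## Activations are numeric arrays (H, W, C, N).  A forward pass records
## op nodes on a tape; tape_backward() replays the tape in reverse and
## accumulates parameter gradients per named unit.  Trainable units are
## either "cbr" (conv -> batch norm -> optional ReLU) or "conv" (plain
## convolution with bias, used by the softmax head).
##

as_nchw <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array input", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

## He-normal initialisation; draws come from the current R RNG stream so a
## builder seed makes the whole network reproducible.
new_cbr <- function(K, cin, cout, stride = 1L, dil = 1L,
                    pad = dil * (K - 1L) %/% 2L, relu = TRUE) {
  w <- array(stats::rnorm(K * K * cin * cout, sd = sqrt(2 / (K * K * cin))),
             dim = c(K, K, cin, cout))
  list(kind = "cbr", w = w,
       gamma = rep(1, cout), beta = rep(0, cout),
       rm = rep(0, cout), rv = rep(1, cout),
       stride = as.integer(stride), pad = as.integer(pad),
       dil = as.integer(dil), relu = isTRUE(relu))
}

new_conv <- function(K, cin, cout, stride = 1L, dil = 1L,
                     pad = dil * (K - 1L) %/% 2L) {
  w <- array(stats::rnorm(K * K * cin * cout, sd = sqrt(2 / (K * K * cin))),
             dim = c(K, K, cin, cout))
  list(kind = "conv", w = w, b = rep(0, cout),
       stride = as.integer(stride), pad = as.integer(pad),
       dil = as.integer(dil))
}

tape_new <- function(model, training = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$model <- model
  tp$training <- isTRUE(training)
  tp$nodes <- list()
  tp$val <- list()
  tp$next_id <- 1L
  tp$new_stats <- list()
  tp
}

tp_push <- function(tp, op, inputs, out, unit = NULL, cache = NULL) {
  id <- tp$next_id
  tp$next_id <- id + 1L
  tp$val[[id]] <- out
  tp$nodes[[length(tp$nodes) + 1L]] <-
    list(op = op, id = id, inputs = inputs, unit = unit, cache = cache)
  id
}

tape_input <- function(tp, x) tp_push(tp, "input", integer(0), x)

tape_cbr <- function(tp, name, in_id) {
  force(in_id)
  u <- tp$model$units[[name]]
  x <- tp$val[[in_id]]
  z <- cpp_conv2d_fwd(x, u$w, NULL, u$stride, u$pad, u$dil)
  if (tp$training) {
    bn <- cpp_bn_fwd(z, u$gamma, u$beta, 1e-5)
    ## exponential running statistics for inference mode
    tp$new_stats[[name]] <- list(rm = 0.9 * u$rm + 0.1 * bn$mean,
                                 rv = 0.9 * u$rv + 0.1 * bn$var)
    y <- bn$y
    if (u$relu) y <- pmax(y, 0)
    tp_push(tp, "cbr", in_id, y, unit = name,
            cache = list(xhat = bn$xhat, var = bn$var))
  } else {
    y <- cpp_bn_infer(z, u$gamma, u$beta, u$rm, u$rv, 1e-5)
    if (u$relu) y <- pmax(y, 0)
    tp_push(tp, "cbr", in_id, y, unit = name)
  }
}

tape_conv <- function(tp, name, in_id) {
  force(in_id)
  u <- tp$model$units[[name]]
  x <- tp$val[[in_id]]
  y <- cpp_conv2d_fwd(x, u$w, u$b, u$stride, u$pad, u$dil)
  tp_push(tp, "conv", in_id, y, unit = name)
}

tape_maxpool <- function(tp, in_id, K = 3L, stride = 2L, pad = 1L) {
  force(in_id)
  x <- tp$val[[in_id]]
  r <- cpp_maxpool_fwd(x, K, stride, pad)
  tp_push(tp, "maxpool", in_id, r$y,
          cache = list(idx = r$idx, in_dim = dim(x)))
}

tape_upsample2 <- function(tp, in_id) {
  force(in_id)
  tp_push(tp, "upsample2", in_id, cpp_upsample2_fwd(tp$val[[in_id]]))
}

tape_add_relu <- function(tp, a_id, b_id) {
  force(a_id); force(b_id)
  y <- pmax(tp$val[[a_id]] + tp$val[[b_id]], 0)
  tp_push(tp, "add_relu", c(a_id, b_id), y)
}

tape_concat <- function(tp, a_id, b_id) {
  force(a_id); force(b_id)
  a <- tp$val[[a_id]]; b <- tp$val[[b_id]]
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  tp_push(tp, "concat", c(a_id, b_id), out, cache = list(ca = da[3]))
}

## Reverse pass: returns per-unit parameter gradients.
tape_backward <- function(tp, out_id, dout) {
  dval <- vector("list", tp$next_id - 1L)
  dval[[out_id]] <- dout
  grads <- list()
  model <- tp$model
  for (node in rev(tp$nodes)) {
    g <- dval[[node$id]]
    if (is.null(g)) next
    dval[node$id] <- list(NULL)   # free as we go
    switch(node$op,
      input = NULL,
      cbr = {
        u <- model$units[[node$unit]]
        cc <- node$cache
        ## ReLU gate recovered from the stored (post-ReLU) activation
        if (u$relu) g <- g * (tp$val[[node$id]] > 0)
        bb <- cpp_bn_bwd(g, cc$xhat, cc$var, u$gamma, 1e-5)
        x <- tp$val[[node$inputs[1]]]
        cb <- cpp_conv2d_bwd(x, u$w, bb$dx, u$stride, u$pad, u$dil, FALSE)
        grads[[node$unit]] <- list(w = cb$dw, gamma = bb$dgamma, beta = bb$dbeta)
        i <- node$inputs[1]
        dval[[i]] <- if (is.null(dval[[i]])) cb$dx else dval[[i]] + cb$dx
      },
      conv = {
        u <- model$units[[node$unit]]
        x <- tp$val[[node$inputs[1]]]
        cb <- cpp_conv2d_bwd(x, u$w, g, u$stride, u$pad, u$dil, TRUE)
        grads[[node$unit]] <- list(w = cb$dw, b = cb$db)
        i <- node$inputs[1]
        dval[[i]] <- if (is.null(dval[[i]])) cb$dx else dval[[i]] + cb$dx
      },
      maxpool = {
        dx <- cpp_maxpool_bwd(g, node$cache$idx, node$cache$in_dim)
        i <- node$inputs[1]
        dval[[i]] <- if (is.null(dval[[i]])) dx else dval[[i]] + dx
      },
      upsample2 = {
        dx <- cpp_upsample2_bwd(g)
        i <- node$inputs[1]
        dval[[i]] <- if (is.null(dval[[i]])) dx else dval[[i]] + dx
      },
      add_relu = {
        g <- g * (tp$val[[node$id]] > 0)
        for (i in node$inputs)
          dval[[i]] <- if (is.null(dval[[i]])) g else dval[[i]] + g
      },
      concat = {
        ca <- node$cache$ca
        ga <- g[, , seq_len(ca), , drop = FALSE]
        gb <- g[, , ca + seq_len(dim(g)[3] - ca), , drop = FALSE]
        i <- node$inputs[1]; j <- node$inputs[2]
        dval[[i]] <- if (is.null(dval[[i]])) ga else dval[[i]] + ga
        dval[[j]] <- if (is.null(dval[[j]])) gb else dval[[j]] + gb
      },
      stop("unknown op on tape: ", node$op))
  }
  grads
}

## Channel-wise softmax for (H, W, C, N) logits.
softmax_channels <- function(z) {
  C <- dim(z)[3]
  m <- z[, , 1, , drop = FALSE]
  for (c in seq_len(C)[-1]) m <- pmax(m, z[, , c, , drop = FALSE])
  e <- z
  for (c in seq_len(C)) e[, , c, ] <- exp(z[, , c, , drop = FALSE] - m)
  s <- e[, , 1, , drop = FALSE]
  for (c in seq_len(C)[-1]) s <- s + e[, , c, , drop = FALSE]
  for (c in seq_len(C)) e[, , c, ] <- e[, , c, , drop = FALSE] / s
  e
}

## d(loss)/d(logits) given d(loss)/d(probs) through the softmax Jacobian.
softmax_backward <- function(probs, dprobs) {
  C <- dim(probs)[3]
  dot <- probs[, , 1, , drop = FALSE] * dprobs[, , 1, , drop = FALSE]
  for (c in seq_len(C)[-1])
    dot <- dot + probs[, , c, , drop = FALSE] * dprobs[, , c, , drop = FALSE]
  dz <- probs
  for (c in seq_len(C))
    dz[, , c, ] <- probs[, , c, , drop = FALSE] *
      (dprobs[, , c, , drop = FALSE] - dot)
  dz
}

## Adam step over every trainable array in the model; state kept in
## model$opt, keyed by "unit.param".
adam_step <- function(model, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      epsilon = 1e-8) {
  if (is.null(model$opt)) model$opt <- list(t = 0L, m = list(), v = list())
  model$opt$t <- model$opt$t + 1L
  t <- model$opt$t
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (un in names(grads)) {
    for (pn in names(grads[[un]])) {
      key <- paste0(un, ".", pn)
      g <- grads[[un]][[pn]]
      if (is.null(model$opt$m[[key]])) {
        model$opt$m[[key]] <- g * 0
        model$opt$v[[key]] <- g * 0
      }
      ## m and v are updated in place inside the kernel
      model$units[[un]][[pn]] <- cpp_adam_update(
        model$units[[un]][[pn]], model$opt$m[[key]], model$opt$v[[key]],
        g, lr, beta1, beta2, epsilon, c1, c2)
    }
  }
  model
}
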