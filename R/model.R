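##
## HRU-Net: ResNet-50 encoder with per-block 1x1 channel reduction, hybrid
## atrous convolution (HAC) modules on the deep semantic layers, and a
## U-Net-style skip-concatenation decoder ending in a 2-class softmax.
##

#' Dilated (atrous) convolution response at a single position
#'
#' Evaluates the response of a `K x K` kernel with the given atrous rate
#' centred at `center = (m, n)` on a 2D feature grid: taps are spaced
#' `rate` pixels apart and out-of-grid taps read as zero.  With `rate = 1`
#' this is the
#' standard cross-correlation at `(m, n)`.
#'
#' @param grid numeric matrix (feature grid).
#' @param center integer vector `c(m, n)` (1-based row, column).
#' @param kernel odd-sized square numeric matrix.
#' @param rate atrous rate, integer `>= 1`.
#' @return the scalar convolution response.
#' @examples
#' g <- matrix(1, 5, 5)
#' atrous_conv_value(g, c(3, 3), matrix(1, 3, 3), rate = 2)  # 9
#' @export
atrous_conv_value <- function(grid, center, kernel, rate = 1L) {
  K <- nrow(kernel)
  if (K != ncol(kernel) || K %% 2L == 0L)
    stop("kernel must be square with odd size", call. = FALSE)
  if (rate < 1L) stop("atrous rate must be >= 1", call. = FALSE)
  m <- center[1]; n <- center[2]
  H <- nrow(grid); W <- ncol(grid)
  acc <- 0
  half <- (K + 1L) %/% 2L
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      hi <- m - rate * half + rate * i
      wj <- n - rate * half + rate * j
      if (hi >= 1 && hi <= H && wj >= 1 && wj <= W)
        acc <- acc + grid[hi, wj] * kernel[i, j]
    }
  }
  acc
}

#' Receptive field of a stride-1 convolution cascade
#'
#' For a stack of stride-1 convolutions with kernel sizes `kernels` and
#' dilation rates `rates`, the receptive field is
#' `RF = 1 + sum(rates * (kernels - 1))`.  The cascade of 3x3 kernels at
#' rates 1, 2, 3 used inside the HAC module therefore sees 13 x 13 pixels.
#'
#' @param kernels integer vector of kernel sizes.
#' @param rates integer vector of dilation rates (same length).
#' @return receptive field extent in pixels.
#' @examples
#' receptive_field(c(3, 3, 3), c(1, 2, 3))  # 13
#' @export
receptive_field <- function(kernels, rates) {
  if (length(kernels) == 0L || length(kernels) != length(rates))
    stop("kernels and rates must be nonempty and of equal length",
         call. = FALSE)
  if (any(rates < 1) || any(kernels < 1))
    stop("kernel sizes and rates must be >= 1", call. = FALSE)
  1 + sum(rates * (kernels - 1))
}

#' Specification of a hybrid atrous convolution (HAC) module
#'
#' A HAC block runs parallel 3x3 dilated convolutions at small rates
#' (default 1, 2, 3, 5) next to one cascaded rate-1 -> 2 -> 3 chain, and
#' fuses the branches back to the input channel count.
#'
#' @param parallel_rates dilation rates of the parallel branches.
#' @param cascade_rates ordered rates of the cascaded chain.
#' @param kernel odd kernel size shared by all branches.
#' @export
hac_spec <- function(parallel_rates = c(1L, 2L, 3L, 5L),
                     cascade_rates = c(1L, 2L, 3L),
                     kernel = 3L) {
  if (kernel %% 2L == 0L) stop("kernel size must be odd", call. = FALSE)
  if (length(parallel_rates) == 0L && length(cascade_rates) == 0L)
    stop("HAC needs at least one branch", call. = FALSE)
  if (any(c(parallel_rates, cascade_rates) < 1L))
    stop("atrous rates must be >= 1", call. = FALSE)
  structure(list(parallel_rates = as.integer(parallel_rates),
                 cascade_rates = as.integer(cascade_rates),
                 kernel = as.integer(kernel)),
            class = "hac_spec")
}

## Units of one HAC block, named <prefix>_par<i>, <prefix>_cas<i>,
## <prefix>_fuse.  Each branch is conv/BN/ReLU at the input width; fusion is
## channel concatenation followed by a 1x1 conv/BN/ReLU back to `channels`,
## so the block is channel- and resolution-preserving (drop-in anywhere).
make_hac_units <- function(spec, channels, prefix) {
  units <- list()
  K <- spec$kernel
  for (i in seq_along(spec$parallel_rates)) {
    r <- spec$parallel_rates[i]
    units[[sprintf("%s_par%d", prefix, i)]] <- new_cbr(K, channels, channels, dil = r)
  }
  for (i in seq_along(spec$cascade_rates)) {
    r <- spec$cascade_rates[i]
    units[[sprintf("%s_cas%d", prefix, i)]] <- new_cbr(K, channels, channels, dil = r)
  }
  nb <- length(spec$parallel_rates) + (length(spec$cascade_rates) > 0L)
  units[[sprintf("%s_fuse", prefix)]] <- new_cbr(1L, nb * channels, channels)
  units
}

tape_hac <- function(tp, prefix, spec, in_id) {
  branch_ids <- integer(0)
  for (i in seq_along(spec$parallel_rates))
    branch_ids <- c(branch_ids, tape_cbr(tp, sprintf("%s_par%d", prefix, i), in_id))
  if (length(spec$cascade_rates) > 0L) {
    cur <- in_id
    for (i in seq_along(spec$cascade_rates))
      cur <- tape_cbr(tp, sprintf("%s_cas%d", prefix, i), cur)
    branch_ids <- c(branch_ids, cur)
  }
  cat_id <- branch_ids[1]
  for (b in branch_ids[-1]) cat_id <- tape_concat(tp, cat_id, b)
  tape_cbr(tp, sprintf("%s_fuse", prefix), cat_id)
}

#' Build a standalone HAC feature-transform block
#'
#' @param spec a [hac_spec()].
#' @param channels input (= output) channel count.
#' @param seed optional RNG seed for weight initialisation.
#' @return an object applicable with [hac_apply()].
#' @export
build_hac <- function(spec = hac_spec(), channels, seed = NULL) {
  if (channels < 1L) stop("channels must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  structure(list(units = make_hac_units(spec, channels, "hac"),
                 spec = spec, channels = as.integer(channels)),
            class = "hac_block")
}

#' Apply a HAC block to a feature grid
#'
#' @param hac a block from [build_hac()].
#' @param x array `(H, W, C)` or `(H, W, C, N)` with `C == hac$channels`.
#' @param training use batch statistics (`TRUE`) or running statistics.
#' @export
hac_apply <- function(hac, x, training = FALSE) {
  x <- as_nchw(x)
  if (dim(x)[3] != hac$channels)
    stop("channel mismatch: block expects ", hac$channels, call. = FALSE)
  tp <- tape_new(list(units = hac$units), training = training)
  in_id <- tape_input(tp, x)
  out <- tape_hac(tp, "hac", hac$spec, in_id)
  tp$val[[out]]
}

## Ordered candidate sites for HAC insertion: the three deep semantic layers
## first (the default placement), then on down the skip hierarchy to the
## full-resolution decoder stage.
hac_sites <- c("res4", "res3", "res2", "res1", "conv_block", "final")

#' Model configuration for HRU-Net
#'
#' @param in_height,in_width input size in pixels; both divisible by 32.
#' @param n_classes number of softmax categories (2: background, plaque).
#' @param hac_placement character subset of
#'   `c("res4","res3","res2","res1","conv_block","final")`; the default
#'   places HAC modules on the three deep encoder layers.  `character(0)`
#'   yields the plain RU-Net baseline.
#' @param pretrained whether [load_pretrained_encoder()] weights are
#'   expected; with `FALSE` the encoder keeps its random initialisation.
#' @param reduced_channels named per-block widths after the 1x1 reductions.
#' @param hac a [hac_spec()].
#' @param seed RNG seed for weight initialisation.
#' @export
model_config <- function(in_height = 128L, in_width = 128L, n_classes = 2L,
                         hac_placement = c("res2", "res3", "res4"),
                         pretrained = FALSE,
                         reduced_channels = c(conv_block = 32L, res1 = 64L,
                                              res2 = 96L, res3 = 128L,
                                              res4 = 128L),
                         hac = hac_spec(), seed = NULL) {
  if (in_height %% 32L != 0L || in_width %% 32L != 0L)
    stop("input height and width must be divisible by 32", call. = FALSE)
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  hac_placement <- unique(as.character(hac_placement))
  bad <- setdiff(hac_placement, hac_sites)
  if (length(bad))
    stop("unknown HAC placement site(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  need <- c("conv_block", "res1", "res2", "res3", "res4")
  if (!all(need %in% names(reduced_channels)))
    stop("reduced_channels must name ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(list(in_height = as.integer(in_height),
                 in_width = as.integer(in_width),
                 n_classes = as.integer(n_classes),
                 hac_placement = hac_placement,
                 pretrained = isTRUE(pretrained),
                 reduced_channels = reduced_channels[need],
                 hac = hac, seed = seed),
            class = "hrunet_config")
}

#' HAC placement for an ablation count
#'
#' Maps a module count 0..6 to placement sites, filling from the deepest
#' semantic layer downwards (res4, res3, res2, res1, conv_block, final);
#' count 0 is the plain RU-Net baseline and count 3 the default network.
#'
#' @param n number of HAC modules, 0..6.
#' @export
hac_placement_for_count <- function(n) {
  if (n < 0L || n > length(hac_sites))
    stop("HAC count must be between 0 and ", length(hac_sites), call. = FALSE)
  hac_sites[seq_len(n)]
}

## ResNet-50 stage table: blocks, bottleneck mid width, output width.
resnet50_stages <- list(
  res1 = list(blocks = 3L, mid = 64L,  out = 256L,  stride = 1L),
  res2 = list(blocks = 4L, mid = 128L, out = 512L,  stride = 2L),
  res3 = list(blocks = 6L, mid = 256L, out = 1024L, stride = 2L),
  res4 = list(blocks = 3L, mid = 512L, out = 2048L, stride = 2L)
)

#' Build the HRU-Net segmentation model
#'
#' Constructs the full network: a ResNet-50 encoder (7x7/2 stem, bottleneck
#' stages of 3/4/6/3 blocks with 256/512/1024/2048 output channels), a 1x1
#' conv/BN/ReLU reduction on each block output (to 32/64/96/128/128
#' channels), HAC modules at `config$hac_placement`, and a decoder that
#' bilinearly upsamples stage by stage with skip concatenation, ending in a
#' 1x1 softmax head at full input resolution.
#'
#' @param config a [model_config()].
#' @return an object of class `hrunet`.
#' @export
build_hrunet <- function(config = model_config()) {
  stopifnot(inherits(config, "hrunet_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  units <- list()
  units$stem <- new_cbr(7L, 3L, 64L, stride = 2L, pad = 3L)

  cin <- 64L
  for (sn in names(resnet50_stages)) {
    st <- resnet50_stages[[sn]]
    for (b in seq_len(st$blocks)) {
      p <- sprintf("%s_b%d", sn, b)
      stride <- if (b == 1L) st$stride else 1L
      bin <- if (b == 1L) cin else st$out
      units[[paste0(p, "_c1")]] <- new_cbr(1L, bin, st$mid)
      units[[paste0(p, "_c2")]] <- new_cbr(3L, st$mid, st$mid, stride = stride)
      units[[paste0(p, "_c3")]] <- new_cbr(1L, st$mid, st$out, relu = FALSE)
      if (b == 1L)
        units[[paste0(p, "_down")]] <- new_cbr(1L, bin, st$out,
                                               stride = stride, relu = FALSE)
    }
    cin <- st$out
  }

  rc <- config$reduced_channels
  pre <- c(conv_block = 64L, res1 = 256L, res2 = 512L, res3 = 1024L,
           res4 = 2048L)
  for (nm in names(pre))
    units[[paste0("red_", nm)]] <- new_cbr(1L, pre[[nm]], rc[[nm]])

  hac_ch <- c(res4 = rc[["res4"]], res3 = rc[["res3"]], res2 = rc[["res2"]],
              res1 = rc[["res1"]], conv_block = rc[["conv_block"]],
              final = rc[["conv_block"]])
  for (p in config$hac_placement)
    units <- c(units, make_hac_units(config$hac, hac_ch[[p]],
                                     paste0("hac_", p)))

  ## decoder widths mirror the reduced encoder widths
  dec <- list(
    d4 = c(rc[["res4"]] + rc[["res3"]], rc[["res3"]]),
    d3 = c(rc[["res3"]] + rc[["res2"]], rc[["res2"]]),
    d2 = c(rc[["res2"]] + rc[["res1"]], rc[["res1"]]),
    d1 = c(rc[["res1"]] + rc[["conv_block"]], rc[["conv_block"]]),
    d0 = c(rc[["conv_block"]], rc[["conv_block"]])
  )
  for (dn in names(dec)) {
    units[[paste0(dn, "_c1")]] <- new_cbr(3L, dec[[dn]][1], dec[[dn]][2])
    units[[paste0(dn, "_c2")]] <- new_cbr(3L, dec[[dn]][2], dec[[dn]][2])
  }
  units$head <- new_conv(1L, rc[["conv_block"]], config$n_classes)
  ## keep the softmax head near-uniform at start
  units$head$w <- units$head$w * 0.1

  structure(list(units = units, config = config), class = "hrunet")
}

## Shared forward pass.  Returns the tape plus ids of the encoder pyramid
## (raw and reduced) and the logits, so training, prediction and
## introspection all use the same code path.
hrunet_tape <- function(model, x, training = FALSE) {
  x <- as_nchw(x)
  d <- dim(x)
  if (d[3] == 1L) {
    ## replicate grayscale to the 3 channels the pretrained stem expects
    x3 <- array(0, dim = c(d[1], d[2], 3L, d[4]))
    for (c in 1:3) x3[, , c, ] <- x
    x <- x3
  } else if (d[3] != 3L) {
    stop("input must have 1 or 3 channels", call. = FALSE)
  }
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input size must be divisible by 32", call. = FALSE)

  tp <- tape_new(model, training = training)
  in_id <- tape_input(tp, x)
  feats <- list()
  s <- tape_cbr(tp, "stem", in_id)
  feats$conv_block <- s
  cur <- tape_maxpool(tp, s)
  for (sn in names(resnet50_stages)) {
    st <- resnet50_stages[[sn]]
    for (b in seq_len(st$blocks)) {
      p <- sprintf("%s_b%d", sn, b)
      c1 <- tape_cbr(tp, paste0(p, "_c1"), cur)
      c2 <- tape_cbr(tp, paste0(p, "_c2"), c1)
      c3 <- tape_cbr(tp, paste0(p, "_c3"), c2)
      sc <- if (b == 1L) tape_cbr(tp, paste0(p, "_down"), cur) else cur
      cur <- tape_add_relu(tp, c3, sc)
    }
    feats[[sn]] <- cur
  }

  hp <- model$config$hac_placement
  red <- list()
  for (nm in names(feats)) {
    r <- tape_cbr(tp, paste0("red_", nm), feats[[nm]])
    if (nm %in% hp) r <- tape_hac(tp, paste0("hac_", nm), model$config$hac, r)
    red[[nm]] <- r
  }

  dec_skip <- c(d4 = "res3", d3 = "res2", d2 = "res1", d1 = "conv_block")
  cur <- red$res4
  for (dn in names(dec_skip)) {
    cur <- tape_upsample2(tp, cur)
    cur <- tape_concat(tp, cur, red[[dec_skip[[dn]]]])
    cur <- tape_cbr(tp, paste0(dn, "_c1"), cur)
    cur <- tape_cbr(tp, paste0(dn, "_c2"), cur)
  }
  cur <- tape_upsample2(tp, cur)
  cur <- tape_cbr(tp, "d0_c1", cur)
  cur <- tape_cbr(tp, "d0_c2", cur)
  if ("final" %in% hp) cur <- tape_hac(tp, "hac_final", model$config$hac, cur)
  logits <- tape_conv(tp, "head", cur)

  list(tp = tp, logits = logits, feats = feats, reduced = red)
}

#' Forward pass: per-pixel class probabilities
#'
#' @param model an `hrunet` model.
#' @param image matrix `(H, W)` grayscale in `[0, 1]`, or array
#'   `(H, W, 1)` / `(H, W, 1, N)` for a batch.
#' @return array `(H, W, n_classes, N)` of softmax probabilities (the
#'   probability map); drop the fourth dimension for a single image with
#'   `drop = TRUE` indexing if desired.
#' @export
predict_hrunet <- function(model, image) {
  r <- hrunet_tape(model, image, training = FALSE)
  softmax_channels(r$tp$val[[r$logits]])
}

#' Hard segmentation mask from a probability map
#'
#' @param probs array `(H, W, C)` or `(H, W, C, N)` of class probabilities.
#' @return binary matrix (or `(H, W, N)` array) with 1 = plaque (class 2
#'   wins the per-pixel arg-max).
#' @export
prob_to_mask <- function(probs) {
  probs <- as_nchw(probs)
  out <- (probs[, , 2, ] >= probs[, , 1, ]) * 1
  out
}

#' Encoder feature pyramid of an HRU-Net
#'
#' Runs the encoder on one image and returns the raw and reduced feature
#' grids of each stage, for architecture introspection.
#'
#' @inheritParams predict_hrunet
#' @return list with elements `raw` and `reduced`, each a named list of
#'   `(H, W, C, N)` arrays for conv_block, res1..res4.
#' @export
encoder_features <- function(model, image) {
  r <- hrunet_tape(model, image, training = FALSE)
  list(raw = lapply(r$feats, function(i) r$tp$val[[i]]),
       reduced = lapply(r$reduced, function(i) r$tp$val[[i]]))
}

encoder_unit_names <- function(model) {
  nm <- names(model$units)
  nm[grepl("^(stem$|res[1-4]_b)", nm)]
}

#' Load pretrained encoder weights
#'
#' Initialises the ResNet-50 encoder (stem and bottleneck stages) from a
#' named list of parameter sets, e.g. ImageNet-trained weights exported as
#' `list(stem = list(w = ..., gamma = ..., beta = ..., rm = ..., rv = ...),
#' res1_b1_c1 = list(...), ...)`, or a path to an `.rds` file holding that
#' list.  Shapes are checked for every block; all parameters stay trainable
#' (fine-tuning).  With `weights_source = NULL` the encoder keeps its random
#' initialisation, the documented offline fallback.
#'
#' @param model an `hrunet` model.
#' @param weights_source named list, path to an RDS file, or `NULL`.
#' @return the model with encoder parameters replaced.
#' @export
load_pretrained_encoder <- function(model, weights_source = NULL) {
  if (is.null(weights_source)) return(model)
  if (is.character(weights_source)) weights_source <- readRDS(weights_source)
  enc <- encoder_unit_names(model)
  mismatched <- character(0)
  for (nm in intersect(enc, names(weights_source))) {
    src <- weights_source[[nm]]
    for (pn in intersect(c("w", "gamma", "beta", "rm", "rv"), names(src))) {
      cur <- model$units[[nm]][[pn]]
      if (!identical(dim(cur), dim(src[[pn]])) ||
          length(cur) != length(src[[pn]])) {
        mismatched <- c(mismatched, paste0(nm, "$", pn))
      } else {
        model$units[[nm]][[pn]] <- src[[pn]]
      }
    }
  }
  if (length(mismatched))
    stop("shape-incompatible pretrained weights for: ",
         paste(mismatched, collapse = ", "), call. = FALSE)
  missing <- setdiff(enc, names(weights_source))
  if (length(missing) == length(enc))
    stop("weights_source matches no encoder block", call. = FALSE)
  model
}

#' Save / load a trained model
#'
#' Thin wrappers around R serialisation; the checkpoint holds the full
#' parameter set, running statistics and configuration.
#'
#' @param model an `hrunet` model.
#' @param path file path (`.rds`).
#' @export
save_model <- function(model, path) {
  model$opt <- NULL  # optimiser state is not part of a checkpoint
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
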