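test_that("single-position atrous convolution follows the dilated sum", {
  g1 <- matrix(1, 5, 5)
  k1 <- matrix(1, 3, 3)
  expect_equal(atrous_conv_value(g1, c(3, 3), k1, rate = 1), 9)
  expect_equal(atrous_conv_value(g1, c(3, 3), k1, rate = 2), 9)
  expect_equal(atrous_conv_value(g1 * 0, c(3, 3), k1, rate = 3), 0)
  # rate 2 at the corner: only taps landing on the grid contribute
  expect_equal(atrous_conv_value(g1, c(1, 1), k1, rate = 2), 4)
  expect_error(atrous_conv_value(g1, c(3, 3), matrix(1, 2, 2)), "odd")
  expect_error(atrous_conv_value(g1, c(3, 3), k1, rate = 0), "rate")

  # r = 1 equals brute-force standard cross-correlation on random grids
  set.seed(31)
  for (i in 1:5) {
    g <- matrix(rnorm(49), 7, 7)
    k <- matrix(rnorm(9), 3, 3)
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    want <- sum(g[(m - 1):(m + 1), (n - 1):(n + 1)] * k)
    expect_equal(atrous_conv_value(g, c(m, n), k, 1), want, tolerance = 1e-12)
  }
})

test_that("receptive field closed form matches impulse-response extent", {
  expect_equal(receptive_field(c(3, 3, 3), c(1, 2, 3)), 13)
  expect_equal(receptive_field(3, 1), 3)
  expect_equal(receptive_field(3, 2), 5)
  expect_error(receptive_field(integer(0), integer(0)), "nonempty")
  expect_error(receptive_field(c(3, 3), 1), "equal length")

  # brute force: nonzero output extent of an actual conv cascade applied
  # to a single-pixel impulse
  for (rates in list(1, c(1, 2), c(1, 2, 3))) {
    expect_equal(impulse_extent(rates), receptive_field(rep(3, length(rates)), rates))
  }
})

test_that("HAC block has 4 parallel + 1 cascaded branch and preserves shape", {
  spec <- hac_spec()
  expect_equal(spec$parallel_rates, c(1L, 2L, 3L, 5L))
  expect_equal(spec$cascade_rates, c(1L, 2L, 3L))
  expect_equal(receptive_field(rep(spec$kernel, 3), spec$cascade_rates), 13)

  hac <- build_hac(spec, channels = 6, seed = 2)
  nm <- names(hac$units)
  expect_length(grep("_par", nm), 4)
  expect_length(grep("_cas", nm), 3)   # one cascaded branch of 3 convs
  expect_true("hac_fuse" %in% nm)
  # fusion consumes 5 branches x 6 channels
  expect_identical(dim(hac$units$hac_fuse$w), c(1L, 1L, 30L, 6L))

  x <- array(rnorm(8 * 10 * 6), c(8, 10, 6))
  y <- hac_apply(hac, x, training = TRUE)
  expect_identical(dim(y), c(8L, 10L, 6L, 1L))
  expect_error(hac_apply(hac, array(0, c(8, 10, 5))), "channel mismatch")
  expect_error(hac_spec(parallel_rates = integer(0),
                        cascade_rates = integer(0)), "at least one branch")
  expect_error(hac_spec(kernel = 4), "odd")
})

test_that("encoder pyramid matches the reduction table", {
  m <- build_hrunet(tiny_model_config(seed = 1))
  img <- matrix(runif(32 * 64), 32, 64)
  ef <- encoder_features(m, img)
  raw_ch <- vapply(ef$raw, function(a) dim(a)[3], 0L)
  red_ch <- vapply(ef$reduced, function(a) dim(a)[3], 0L)
  expect_equal(unname(raw_ch), c(64L, 256L, 512L, 1024L, 2048L))
  expect_equal(unname(red_ch), c(32L, 64L, 96L, 128L, 128L))
  # spatial halving at each stage: H/2, H/4, ..., H/32
  hs <- vapply(ef$raw, function(a) dim(a)[1], 0L)
  expect_equal(unname(hs), 32L %/% c(2L, 4L, 8L, 16L, 32L))
  ws <- vapply(ef$raw, function(a) dim(a)[2], 0L)
  expect_equal(unname(ws), 64L %/% c(2L, 4L, 8L, 16L, 32L))
})

test_that("forward pass preserves resolution and normalises the softmax", {
  m <- build_hrunet(tiny_model_config(seed = 1))
  img <- matrix(runif(32 * 64), 32, 64)
  p <- predict_hrunet(m, img)
  expect_identical(dim(p), c(32L, 64L, 2L, 1L))
  expect_lt(max(abs(p[, , 1, ] + p[, , 2, ] - 1)), 1e-5)
  mask <- prob_to_mask(p)
  expect_true(all(mask %in% c(0, 1)))
  expect_error(build_hrunet(model_config(in_height = 100L, in_width = 64L)),
               "divisible by 32")
  expect_error(predict_hrunet(m, matrix(0, 33, 64)), "divisible by 32")
})

test_that("grayscale inputs replicate to three channels before the stem", {
  m <- build_hrunet(tiny_model_config(seed = 3))
  img <- matrix(runif(32 * 64), 32, 64)
  x3 <- array(0, c(32, 64, 3, 1))
  for (c in 1:3) x3[, , c, 1] <- img
  expect_equal(predict_hrunet(m, img), predict_hrunet(m, x3),
               tolerance = 1e-12)
})

test_that("HAC placements 0..6 all build and the extremes run forward", {
  img <- matrix(runif(32 * 64), 32, 64)
  for (cnt in 0:6) {
    pl <- hac_placement_for_count(cnt)
    expect_length(pl, cnt)
    cfg <- tiny_model_config(seed = 1, hac_placement = pl)
    m <- build_hrunet(cfg)
    expect_s3_class(m, "hrunet")
    if (cnt %in% c(0L, 6L)) {
      p <- predict_hrunet(m, img)   # RU-Net baseline and full sweep both run
      expect_identical(dim(p)[1:2], c(32L, 64L))
    }
  }
  expect_error(hac_placement_for_count(7), "between 0 and 6")
  expect_error(model_config(hac_placement = "res9"), "unknown HAC placement")
})

test_that("pretrained encoder loading checks shapes and keeps the architecture", {
  donor <- build_hrunet(tiny_model_config(seed = 10))
  recipient <- build_hrunet(tiny_model_config(seed = 20))
  enc <- getFromNamespace("encoder_unit_names", "plaqueseg")(donor)
  weights <- lapply(donor$units[enc], function(u)
    u[c("w", "gamma", "beta", "rm", "rv")])

  loaded <- load_pretrained_encoder(recipient, weights)
  img <- matrix(runif(32 * 64), 32, 64)
  expect_identical(dim(predict_hrunet(loaded, img)), c(32L, 64L, 2L, 1L))
  # encoder now matches the donor, decoder still the recipient's
  expect_identical(loaded$units$stem$w, donor$units$stem$w)
  expect_false(identical(loaded$units$d0_c1$w, donor$units$d0_c1$w))

  # absent source: documented random-init fallback
  expect_identical(load_pretrained_encoder(recipient, NULL), recipient)

  # shape-incompatible weights name the offending blocks
  bad <- weights
  bad$res1_b1_c1$w <- array(0, c(3, 3, 2, 2))
  expect_error(load_pretrained_encoder(recipient, bad), "res1_b1_c1")
})
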