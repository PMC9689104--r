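test_that("Dice loss limits: perfect prediction 0, hard complement 1", {
  lab <- label_to_onehot(random_mask(6, 6))
  expect_equal(dice_loss(lab, lab), 0, tolerance = 1e-5)
  comp <- lab[, , 2:1]
  expect_equal(dice_loss(comp, lab), 1, tolerance = 1e-5)
})

test_that("Dice loss reproduces the 2 x 2 worked example", {
  mask <- matrix(c(1, 1, 0, 0), 2, 2)
  lab <- label_to_onehot(mask)
  pred <- array(0, c(2, 2, 2))
  pred[, , 2] <- ifelse(mask == 1, 0.8, 0.2)
  pred[, , 1] <- 1 - pred[, , 2]
  # both class Dice terms are 0.8, so loss = 0.5 * 0.2 + 0.5 * 0.2
  expect_equal(dice_loss(pred, lab), 0.2, tolerance = 1e-4)
})

test_that("Dice loss agrees with its direct evaluation on random grids", {
  set.seed(41)
  for (i in 1:20) {
    mask <- random_mask(4, 4, 0.4)
    lab <- label_to_onehot(mask)
    p2 <- matrix(runif(16), 4, 4)
    pred <- array(0, c(4, 4, 2))
    pred[, , 2] <- p2; pred[, , 1] <- 1 - p2
    w <- runif(2)
    expect_equal(dice_loss(pred, lab, w), oracle_dice_loss(pred, lab, w),
                 tolerance = 1e-6)
  }
})

test_that("Dice loss gradient passes a finite-difference check", {
  set.seed(42)
  mask <- random_mask(3, 3, 0.4)
  lab <- array(label_to_onehot(mask), c(3, 3, 2, 1))
  p2 <- matrix(runif(9), 3, 3)
  pred <- array(0, c(3, 3, 2, 1))
  pred[, , 2, 1] <- p2; pred[, , 1, 1] <- 1 - p2
  dlg <- getFromNamespace("dice_loss_grad", "plaqueseg")
  g <- dlg(pred, lab, c(0.5, 0.5))$dpred
  num <- numeric_grad(function(a) dlg(a, lab, c(0.5, 0.5))$loss, pred)
  expect_lt(max(abs(num - g)), 1e-6)
})

test_that("fold plans partition evenly and deterministically", {
  plan <- make_folds(40, 10, seed = 3)
  expect_equal(as.integer(table(plan$fold_assignments)), rep(4L, 10))
  expect_identical(plan, make_folds(40, 10, seed = 3))
  expect_false(identical(plan$fold_assignments,
                         make_folds(40, 10, seed = 4)$fold_assignments))
  expect_equal(as.integer(table(make_folds(10, 10)$fold_assignments)), rep(1L, 10))
  # n not divisible by k: sizes differ by at most one
  sz <- table(make_folds(23, 5, seed = 1)$fold_assignments)
  expect_lte(diff(range(sz)), 1)
  expect_error(make_folds(5, 10), "n >= k")
})

test_that("optimiser defaults follow the fine-tuning protocol", {
  tc <- train_config()
  expect_equal(c(tc$lr, tc$beta1, tc$beta2, tc$epsilon),
               c(1e-4, 0.9, 0.999, 1e-8))
  expect_equal(tc$epochs, 100L)
  expect_equal(tc$batch_size, 4L)
  expect_equal(tc$class_weights, c(0.5, 0.5))
  expect_equal(tc$folds, 10L)
  expect_error(train_config(lr = 0), "lr")
  expect_error(train_config(folds = 1), "folds")
})

test_that("training honours the epoch count, decreases the loss and is reproducible", {
  d <- generate_dataset(2, tiny_phantom_params(seed = 6), seed = 6)
  pairs <- lapply(d, function(s) list(image = s$image, label = s$plaque_mask))
  tc <- train_config(lr = 1e-3, epochs = 4L, batch_size = 2L, seed = 7)
  mc <- tiny_model_config(seed = 7)
  f1 <- train_fold(pairs, tc, mc)
  expect_length(f1$history, 4)
  expect_lt(tail(f1$history, 1), f1$history[1])  # downward trend
  f2 <- train_fold(pairs, tc, mc)
  expect_identical(f1$history, f2$history)        # bitwise on CPU
  expect_error(train_fold(list(), tc, mc), "empty training set")
})

test_that("ensembling averages softmax maps and keeps them normalised", {
  m <- build_hrunet(tiny_model_config(seed = 8))
  img <- matrix(runif(32 * 64), 32, 64)
  single <- predict_hrunet(m, img)
  ens <- ensemble_predict(list(m, m, m), img)
  expect_equal(ens, single, tolerance = 1e-15)   # mean of equal terms
  expect_lt(max(abs(ens[, , 1, ] + ens[, , 2, ] - 1)), 1e-5)
  expect_identical(ensemble_predict(list(m), img), single)  # k = 1 identity
  # averaging two different models still normalises per pixel
  m2 <- build_hrunet(tiny_model_config(seed = 9))
  ens2 <- ensemble_predict(list(m, m2), img)
  expect_lt(max(abs(ens2[, , 1, ] + ens2[, , 2, ] - 1)), 1e-5)
  expect_error(ensemble_predict(list(), img), "at least one model")
})

test_that("model checkpoints round-trip through save/load", {
  m <- build_hrunet(tiny_model_config(seed = 5))
  img <- matrix(runif(32 * 64), 32, 64)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_equal(predict_hrunet(load_model(path), img), predict_hrunet(m, img),
               tolerance = 1e-15)
})
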