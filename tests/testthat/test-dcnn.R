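test_that("dense blocks grow channels by layers x growth; transitions halve", {
  cfg <- dcnn_config(input_side = 32)
  m <- build_model(cfg, seed = 1)
  pl <- m$plan
  C <- cfg$stem_channels
  H <- pl$stem_H
  for (b in seq_len(cfg$num_blocks)) {
    expect_equal(pl$blocks[[b]]$Cin, C)
    expect_equal(pl$blocks[[b]]$Cout, C + 96L)  # 3 layers x growth 32
    expect_equal(pl$blocks[[b]]$H, H)
    C <- pl$blocks[[b]]$Cout
    if (b < cfg$num_blocks) {
      C <- pl$blocks[[b]]$Ctrans
      expect_equal(C, (pl$blocks[[b]]$Cout) %/% 2L)
      H <- H %/% 2L  # 2x2 average pooling halves the side
    }
  }
  expect_equal(pl$final_C, C)
  expect_equal(pl$feat_dim, C * sum(cfg$spp_levels^2))
  expect_error(dcnn_config(spp_levels = integer(0)), "non-empty")
})

test_that("parameter count is invariant across init seeds", {
  expect_equal(n_params(build_model(dcnn_config(32), 1)),
               n_params(build_model(dcnn_config(32), 99)))
})

test_that("forward pass maps an image batch to one score per class", {
  m <- build_model(dcnn_config(input_side = 32), seed = 2)
  x <- array(runif(32 * 32 * 3 * 3, 0, 255), c(32, 32, 3, 3))
  p <- predict(m, x, type = "prob")
  expect_equal(dim(p), c(10L, 3L))
  expect_equal(colSums(p), rep(1, 3), tolerance = 1e-9)
})

test_that("paper-scale preprocessing resizes to a 255-pixel side", {
  cfg <- dcnn_config(paper_scale = TRUE)
  expect_equal(cfg$input_side, 255L)
  lib <- test_library(1)
  img <- render_array_image(lib, NULL)
  expect_equal(dim(preprocess_image(img)), c(255L, 255L, 3L))
})

test_that("split_dataset honors the 17:3 ratio and rounds toward train", {
  s20 <- split_dataset(20, seed = 1)
  expect_equal(sum(s20 == "train"), 17L)
  expect_equal(sum(s20 == "val"), 3L)
  s21 <- split_dataset(21, seed = 1)
  expect_equal(sum(s21 == "train"), 18L)
  expect_identical(split_dataset(40, seed = 5), split_dataset(40, seed = 5))
  expect_false(identical(split_dataset(40, seed = 5),
                         split_dataset(40, seed = 6)))
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  m <- tiny_dcnn(7)
  x <- array(runif(8 * 8 * 3 * 5, 0, 255), c(8, 8, 3, 5))
  y <- c(1, 2, 3, 1, 2)
  X <- ripenose:::input_to_cube(x)
  lossfn <- function(mm)
    ripenose:::softmax_ce(ripenose:::forward_dcnn(mm, X, TRUE)$logits, y)$loss
  fw <- ripenose:::forward_dcnn(m, X, TRUE)
  ce <- ripenose:::softmax_ce(fw$logits, y)
  g <- ripenose:::backward_dcnn(m, fw$cache, ce$dlogits)$grads
  eps <- 1e-5
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (k in sample(length(p), min(3L, length(p)))) {
      m2 <- m
      m2$params[[nm]][k] <- p[k] + eps; lp <- lossfn(m2)
      m2$params[[nm]][k] <- p[k] - eps; lm <- lossfn(m2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(g[[nm]][k], num, tolerance = 1e-3)
    }
  }
})

test_that("initial loss on balanced classes is ln(num_classes)", {
  m <- build_model(dcnn_config(32), seed = 3)
  x <- array(runif(32 * 32 * 3 * 40, 0, 255), c(32, 32, 3, 40))
  expect_equal(model_loss(m, list(x = x, y = rep(1:10, 4))), log(10),
               tolerance = 0.05)
})

test_that("training is seeded-deterministic, resumable, and guards labels", {
  m <- tiny_dcnn(1)
  set.seed(99)
  x <- array(runif(8 * 8 * 3 * 12, 0, 255), c(8, 8, 3, 12))
  y <- rep(1:3, 4)
  d <- list(x = x, y = y)
  # zero epochs: unchanged model, empty history
  m0 <- train_dcnn(m, d, epochs = 0L, seed = 1)
  expect_identical(m0$params, m$params)
  expect_equal(nrow(m0$history), 0L)
  # same seed twice: identical parameters and history
  m1 <- train_dcnn(m, d, epochs = 2L, batch_size = 4L, seed = 5)
  m2 <- train_dcnn(m, d, epochs = 2L, batch_size = 4L, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  # resumable: histories concatenate
  m3 <- train_dcnn(m1, d, epochs = 1L, batch_size = 4L, seed = 6)
  expect_equal(nrow(m3$history), 3L)
  expect_equal(m3$trained_epochs, 3L)
  # absent class errors with its name
  bad <- list(x = x, y = rep(1:2, 6), classes = c("a", "b", "c"))
  expect_error(train_dcnn(m, bad, epochs = 1L), "c")
})

test_that("the learning-rate schedule is non-increasing with scaled breaks", {
  lr <- lr_schedule(500)
  expect_equal(lr[1], 0.01)
  expect_equal(lr[300], 0.01)
  expect_equal(lr[301], 0.005)
  expect_equal(lr[450], 0.005)
  expect_equal(lr[451], 0.001)
  expect_true(all(diff(lr) <= 0))
  expect_true(all(diff(lr_schedule(30)) <= 0))
})

test_that("eval reports implement the F1 and accuracy algebra", {
  # perfect predictor
  r <- eval_report(rep(1:3, 5), rep(1:3, 5), 3)
  expect_equal(r$accuracy, 100)
  expect_equal(r$macro_f1, 1)
  # single-class degenerate predictor on balanced data
  r2 <- eval_report(rep(1:10, 2), rep(1L, 20), 10)
  expect_equal(r2$accuracy, 10)
  # rows sum to class supports
  expect_equal(unname(rowSums(r2$confusion)), rep(2L, 10))
})

test_that("grad_cam maps are input-sized, non-negative and finite", {
  m <- tiny_dcnn(2)
  x <- array(runif(8 * 8 * 3 * 9, 0, 255), c(8, 8, 3, 9))
  d <- list(x = x, y = rep(1:3, 3))
  expect_error(grad_cam(m, x[, , , 1], 1), "trained")
  mt <- train_dcnn(m, d, epochs = 1L, batch_size = 3L, seed = 2)
  cam <- grad_cam(mt, x[, , , 1], 2)
  expect_equal(dim(cam), c(8L, 8L))
  expect_true(all(cam >= 0))
  expect_true(all(is.finite(cam)))
  expect_equal(attr(cam, "target_class"), 2)
  # uniform-zero input stays finite
  cam0 <- grad_cam(mt, array(0, c(8, 8, 3)), 1)
  expect_true(all(is.finite(cam0)))
})
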