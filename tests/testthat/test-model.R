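test_that("the layer chain reproduces the printed feature-map shapes", {
  m <- build_model(cnn_config(10))
  obs <- forward_shapes(m, matrix(rnorm(64 * 160), 64))
  expect_equal(obs$conv1, c(60L, 156L, 6L))
  expect_equal(obs$pool1, c(30L, 78L, 6L))
  expect_equal(obs$conv2, c(26L, 74L, 6L))
  expect_equal(obs$pool2, c(13L, 37L, 6L))
  expect_equal(obs$flatten, 2886L)
  expect_equal(obs$dense, 10L)
  expect_error(cnn_config(1), ">= 2")
  # BN toggles exactly two normalization stages, one per conv layer
  pb <- eegarrange:::init_params(build_model(cnn_config(3, use_batchnorm = TRUE)))
  pn <- eegarrange:::init_params(build_model(cnn_config(3)))
  expect_setequal(setdiff(names(pb), names(pn)),
                  c("gamma1", "beta1", "gamma2", "beta2"))
})

test_that("batch_normalize matches hand-evaluated cases", {
  expect_equal(batch_normalize(c(1, 3), eps = 0), c(-1, 1))
  set.seed(1)
  x <- rnorm(5000, 7, 3)
  z <- batch_normalize(x)
  expect_equal(mean(z), 0, tolerance = 1e-8)
  expect_equal(mean(z^2), 1, tolerance = 1e-3)
  xh <- batch_normalize(x, eps = 0)
  expect_equal(batch_normalize(x, gamma = 2, beta = 3, eps = 0), 2 * xh + 3)
  expect_error(batch_normalize(5), "size >= 2")
  # stored statistics bypass batch statistics
  expect_equal(batch_normalize(c(10), mean = 10, variance = 4, eps = 0), 0)
})

test_that("analytic gradients agree with finite differences (incl. batch norm)", {
  cfg <- cnn_config(3, use_batchnorm = TRUE, bn_epsilon = 1e-3)
  model <- build_model(cfg, input_dim = c(16L, 24L))
  set.seed(4)
  params <- eegarrange:::init_params(model)
  x <- array(rnorm(16 * 24 * 1 * 5), c(16, 24, 1, 5))
  y <- c(1L, 2L, 3L, 1L, 2L)
  loss_fn <- function(p) {
    fw <- eegarrange:::cnn_forward(p, cfg, x, bn_mode = "batch")
    -mean(log(fw$probs[cbind(y, seq_along(y))]))
  }
  fw <- eegarrange:::cnn_forward(params, cfg, x, bn_mode = "batch", keep = TRUE)
  gr <- eegarrange:::cnn_backward(params, cfg, fw, y)
  eps <- 1e-5
  for (nm in c("W1", "b1", "W2", "Wd", "bd", "gamma1", "beta2")) {
    idx <- c(1L, length(params[[nm]]))
    for (i in idx) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("training fits a separable toy, is seed-reproducible, and lr=0 is a no-op", {
  sp <- tiny_m1_split()
  model <- build_model(cnn_config(2))
  cfg <- train_config(epochs = 10, batch_size = 8, seed = 3)
  tm <- train_model(model, sp, cfg)
  pred_tr <- predict(tm, sp$train)
  expect_gt(accuracy(pred_tr$.pred_class, segment_ids(sp$train)), 90)
  expect_equal(nrow(tm$history), 10)

  tm2 <- train_model(model, sp, cfg)
  expect_equal(tm$history$loss, tm2$history$loss, tolerance = 1e-6)
  expect_identical(tm$params, tm2$params)

  frozen <- train_model(model, sp, train_config(learning_rate = 0, epochs = 2,
                                                batch_size = 8, seed = 3))
  init_only <- train_model(model, sp, train_config(epochs = 0, batch_size = 8,
                                                   seed = 3))
  expect_identical(frozen$params, init_only$params)
})

test_that("training rejects mixed kinds and empty splits", {
  sp <- tiny_m1_split()
  sp$train[[1]] <- matrix_to_image(sp$train[[1]])
  expect_error(train_model(build_model(cnn_config(2)), sp, train_config(epochs = 1)),
               "mixed")
  sp2 <- tiny_m1_split()
  sp2$train <- list()
  expect_error(train_model(build_model(cnn_config(2)), sp2, train_config(epochs = 1)),
               "empty")
})

test_that("predictions are proper probabilities and respect the input contract", {
  sp <- tiny_m1_split()
  tm <- train_model(build_model(cnn_config(2)),
                    sp, train_config(epochs = 2, batch_size = 8, seed = 1))
  pr <- predict(tm, sp$test)
  probs <- as.matrix(pr[grep("^\\.prob_", names(pr))])
  expect_equal(rowSums(probs), rep(1, nrow(pr)), tolerance = 1e-6)
  expect_true(all(pr$.pred_class %in% tm$label_levels))

  expect_equal(nrow(predict(tm, list())), 0)

  wrong <- sp$test[[1]]
  wrong$values <- wrong$values[1:32, ]
  expect_error(predict(tm, list(wrong)), "shape|expected")
  img <- matrix_to_image(sp$test[[1]])
  expect_error(predict(tm, list(img)), "trained on")
})

test_that("batch-norm inference is invariant to prediction batch grouping", {
  sp <- tiny_m1_split()
  tm <- train_model(build_model(cnn_config(2, use_batchnorm = TRUE)),
                    sp, train_config(epochs = 3, batch_size = 8, seed = 2))
  together <- predict(tm, sp$test)
  onebyone <- dplyr::bind_rows(lapply(sp$test, function(s) predict(tm, list(s))))
  expect_equal(together, onebyone, tolerance = 1e-12)
})

test_that("image training differs from rescaled-matrix training only by rounding", {
  sp <- tiny_m1_split()
  # continuous per-segment min-max rescale to [0, 255], no quantization
  cont <- lapply(sp$train, function(ai) {
    v <- ai$values
    ai$values <- (v - min(v)) / (max(v) - min(v)) * 255
    ai$kind <- "I1"
    ai
  })
  quant <- lapply(sp$train, matrix_to_image)
  for (i in c(1, 5)) {
    expect_lte(max(abs(quant[[i]]$values - cont[[i]]$values)), 0.5)
  }
  sp_cont <- sp
  sp_cont$train <- cont
  sp_cont$validation <- list()
  tm <- train_model(build_model(cnn_config(2)), sp_cont,
                    train_config(epochs = 0, seed = 9))
  pq <- predict(tm, quant)
  pc <- predict(tm, cont)
  probs <- function(p) as.matrix(p[grep("^\\.prob_", names(p))])
  expect_lt(max(abs(probs(pq) - probs(pc))), 0.05)
})

test_that("tidiers and autoplot expose the training record", {
  sp <- tiny_m1_split()
  tm <- train_model(build_model(cnn_config(2)),
                    sp, train_config(epochs = 2, batch_size = 8, seed = 1))
  td <- tidy(tm)
  expect_named(td, c("epoch", "loss", "val_accuracy"))
  gl <- glance(tm)
  expect_equal(gl$epochs, 2)
  expect_equal(gl$n_parameters, 6836)
  expect_s3_class(autoplot(tm), "ggplot")
})
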