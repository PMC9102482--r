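zero_model <- function() {
  list(
    W1 = matrix(0, 4, 4), b1 = rep(0, 4),
    W2 = matrix(0, 4, 4), b2 = rep(0, 4)
  )
}

test_that("forward pass is a probability simplex map", {
  m <- zero_model()
  expect_equal(as.numeric(mlp_forward(m, rep(0, 4))), rep(0.25, 4))

  set.seed(41)
  m$W1 <- matrix(rnorm(16), 4)
  m$W2 <- matrix(rnorm(16), 4)
  m$b1 <- rnorm(4)
  m$b2 <- rnorm(4)
  x <- matrix(rnorm(200), ncol = 4)
  p <- mlp_forward(m, x)
  expect_equal(rowSums(p), rep(1, 50), tolerance = 1e-12)
  expect_true(all(p > 0))
  # extreme inputs stay finite (overflow-safe softmax)
  p2 <- mlp_forward(m, matrix(c(1e4, -1e4, 1e4, -1e4), 1))
  expect_true(all(is.finite(p2)))
  expect_equal(sum(p2), 1, tolerance = 1e-12)

  # hidden layer fully off: output is softmax of the output bias
  m2 <- zero_model()
  m2$W1 <- diag(4)
  m2$b1 <- rep(-100, 4)
  m2$b2 <- c(1, 0, 0, 0)
  expect_equal(
    as.numeric(mlp_forward(m2, rep(0.1, 4))),
    exp(m2$b2) / sum(exp(m2$b2)),
    tolerance = 1e-12
  )
  expect_error(mlp_forward(m2, rep(0, 3)), "dimension")
})

test_that("cross-entropy matches closed forms and is non-negative", {
  y <- one_hot(1, 4)
  expect_equal(cross_entropy(y, y), 0)
  expect_equal(cross_entropy(y, rep(0.25, 4)), log(4), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:20) {
    yy <- one_hot(sample(0:3, 1), 4)
    p <- stats::runif(4)
    p <- p / sum(p)
    expect_gte(cross_entropy(yy, p), 0)
  }
  expect_warning(
    l <- cross_entropy(one_hot(0, 4), c(0, 0.5, 0.25, 0.25)),
    "clipping"
  )
  expect_equal(l, -log(1e-12))
  expect_error(cross_entropy(one_hot(0, 4), rep(0.25, 3)), "shapes")
})

test_that("analytic gradients match central finite differences", {
  set.seed(43)
  params <- list(
    W1 = matrix(rnorm(16, sd = 0.5), 4), b1 = rnorm(4, sd = 0.2),
    W2 = matrix(rnorm(16, sd = 0.5), 4), b2 = rnorm(4, sd = 0.2)
  )
  x <- matrix(rnorm(32), ncol = 4)
  y <- one_hot(sample(0:3, 8, replace = TRUE), 4)
  g <- myohmi:::mlp_grad(params, x, y)
  h <- 1e-6
  for (nm in c("W1", "b1", "W2", "b2")) {
    ga <- g[[paste0("g", nm)]]
    gn <- ga * 0
    for (i in seq_along(params[[nm]])) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + h
      lp <- myohmi:::mlp_grad(pp, x, y)$loss
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h
      lm <- myohmi:::mlp_grad(pp, x, y)$loss
      gn[i] <- (lp - lm) / (2 * h)
    }
    denom <- pmax(abs(ga) + abs(gn), 1e-4)
    expect_lt(max(abs(ga - gn) / denom), 1e-6)
  }
})

test_that("training is seeded-deterministic and reduces the loss", {
  s <- fast_session(c("SMP", "SMP3", "SMP5", "NIM"), reps = 12, seed = 42)
  feats <- truth_features(s)
  cfg <- train_config(epochs = 200, seed = 42)
  f1 <- train_mlp(feats, cfg)
  f2 <- train_mlp(feats, cfg)
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$W2, f2$W2)
  expect_identical(f1$b2, f2$b2)
  h <- f1$history$train_loss
  expect_lt(h[length(h)], h[1])
})

test_that("the reduced synthetic benchmark classifies held-out bursts well", {
  fit <- benchmark_model()
  expect_gte(fit$test_accuracy, 0.95)
  # split sizes follow the configured fractions
  n <- length(fit$split$test) + length(fit$split$validation) +
    length(fit$split$train)
  expect_equal(length(fit$split$test), round(0.2 * n))
  expect_equal(length(fit$split$validation), round(0.1 * (n - round(0.2 * n))))
})

test_that("confusion stays between adjacent-duration classes", {
  fit <- benchmark_model()
  s <- fast_session(c("SMP", "SMP3", "SMP5", "NIM"), reps = 8, seed = 77)
  feats <- truth_features(s)
  pred <- predict_class(fit, feats)
  confused <- pred$class != feats$class
  # never confuse the 1 s and 5 s pulses
  expect_false(any(feats$class[confused] == "SMP" & pred$class[confused] == "SMP5"))
  expect_false(any(feats$class[confused] == "SMP5" & pred$class[confused] == "SMP"))
})

test_that("prediction emits the machine pulse word and breaks ties low", {
  fit <- benchmark_model()
  s <- fast_session("SMP3", seed = 55)
  pred <- predict_class(fit, truth_features(s))
  expect_equal(pred$class, "SMP3")
  expect_equal(pred$pulse, "0100")

  # an all-zero network gives uniform probabilities: lowest class index wins
  flat <- fit
  flat$W1[] <- 0
  flat$b1[] <- 0
  flat$W2[] <- 0
  flat$b2[] <- 0
  p0 <- predict_class(flat, truth_features(s))
  expect_equal(p0$class, "NIM") # label 0
  expect_error(predict_class(list(), truth_features(s)), "trained emg_mlp")
})

test_that("a class missing from the training data is an error", {
  s <- fast_session(c("SMP", "SMP3"), reps = 10, seed = 56)
  expect_error(
    train_mlp(truth_features(s), train_config(epochs = 10)),
    "absent"
  )
})

test_that("model serialization round-trips through JSON", {
  fit <- benchmark_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp(fit, path)
  back <- read_mlp(path)
  expect_equal(back$W1, fit$W1, tolerance = 1e-12)
  expect_equal(back$b2, fit$b2, tolerance = 1e-12)
  s <- fast_session("SMP5", seed = 57)
  f <- truth_features(s)
  expect_equal(predict_class(back, f)$class, predict_class(fit, f)$class)
})

test_that("tidiers expose weights and fit summary", {
  fit <- benchmark_model()
  td <- tidy(fit)
  expect_equal(nrow(td), 16 + 4 + 16 + 4)
  expect_true(all(c("layer", "parameter", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$epochs, 600)
  expect_true(gl$test_accuracy >= 0 && gl$test_accuracy <= 1)
})
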