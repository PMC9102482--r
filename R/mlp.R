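#' Fit a standardizing scaler
#'
#' Per-feature centering and scaling to unit population standard deviation
#' (divisor `n`, not `n - 1`), matching the normalization used before network
#' training so that all features share a comparable numeric range.
#'
#' @param x A numeric matrix or data frame of features (rows = examples).
#' @return A `feature_scaler` with `mean` and `std` vectors.
#' @export
#' @examples
#' sc <- fit_scaler(matrix(c(1, 2, 3, 4, 5, 6), ncol = 2))
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    rlang::abort("Scaler needs at least 2 rows.")
  }
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  bad <- which(sd_pop <= 0)
  if (length(bad) > 0) {
    nm <- colnames(x)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    rlang::abort(paste0(
      "Constant feature column(s): ", paste(nm, collapse = ", ")
    ))
  }
  structure(list(mean = mu, std = sd_pop), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `feature_scaler`.
#' @return `scale_features()` returns the standardized matrix.
#' @export
scale_features <- function(x, scaler) {
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$mean)) {
    rlang::abort("Feature count does not match the scaler.")
  }
  sweep(sweep(x, 2, scaler$mean), 2, scaler$std, "/")
}

#' One-hot encode an integer label
#'
#' @param label Integer label(s) in `[0, num_classes)`.
#' @param num_classes Number of classes (default 4).
#' @return A unit basis vector, or a matrix with one row per label.
#' @export
#' @examples
#' one_hot(2, 4)
one_hot <- function(label, num_classes = 4) {
  if (any(label < 0 | label >= num_classes | label != floor(label))) {
    rlang::abort("`label` must be an integer in [0, num_classes).")
  }
  m <- matrix(0, nrow = length(label), ncol = num_classes)
  m[cbind(seq_along(label), label + 1)] <- 1
  if (length(label) == 1) drop(m) else m
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max) # overflow-safe
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of the contraction-class MLP
#'
#' One hidden layer of ReLU units followed by a softmax output:
#' `a1 = max(0, x W1 + b1)`, `a2 = softmax(a1 W2 + b2)`. Output rows are
#' probability vectors summing to 1.
#'
#' @param model An `emg_mlp` (from [train_mlp()]) or a bare list with
#'   `W1`, `b1`, `W2`, `b2`.
#' @param x A feature vector or matrix (rows = examples), already
#'   standardized.
#' @return A matrix of class probabilities (rows = examples).
#' @export
mlp_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(model$W1)) {
    rlang::abort("Input dimension does not match W1.")
  }
  n1 <- sweep(x %*% model$W1, 2, model$b1, "+")
  a1 <- pmax(n1, 0)
  n2 <- sweep(a1 %*% model$W2, 2, model$b2, "+")
  softmax_rows(n2)
}

#' Categorical cross-entropy
#'
#' `L = -(1/N) * sum_ij y_ij log(yhat_ij)`, the conventional negated mean.
#' Predicted probabilities are clipped at `1e-12` (with a warning) so a zero
#' probability on a true class yields a large finite loss.
#'
#' @param y One-hot label matrix.
#' @param yhat Predicted probability matrix of the same shape.
#' @return Scalar loss (non-negative).
#' @export
#' @examples
#' cross_entropy(one_hot(0, 4), rep(0.25, 4)) # log(4)
cross_entropy <- function(y, yhat) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (is.null(dim(yhat))) yhat <- matrix(yhat, nrow = 1)
  if (!all(dim(y) == dim(yhat))) {
    rlang::abort("`y` and `yhat` must have matching shapes.")
  }
  if (any(yhat[y > 0] <= 0)) {
    rlang::warn("Zero predicted probability for a true class; clipping at 1e-12.")
  }
  yhat <- pmax(yhat, 1e-12)
  -sum(y * log(yhat)) / nrow(y)
}

# Forward + backward pass; returns loss and analytic gradients.
mlp_grad <- function(params, x, y) {
  n1 <- sweep(x %*% params$W1, 2, params$b1, "+")
  a1 <- pmax(n1, 0)
  n2 <- sweep(a1 %*% params$W2, 2, params$b2, "+")
  a2 <- softmax_rows(n2)
  n_obs <- nrow(x)
  loss <- cross_entropy(y, a2)
  d2 <- (a2 - y) / n_obs # dL/dn2 for softmax + cross-entropy
  gW2 <- t(a1) %*% d2
  gb2 <- colSums(d2)
  d1 <- (d2 %*% t(params$W2)) * (n1 > 0)
  gW1 <- t(x) %*% d1
  gb1 <- colSums(d1)
  list(loss = loss, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2, probs = a2)
}

adam_state <- function(params) {
  purrr::map(params, ~ list(m = .x * 0, v = .x * 0))
}

adam_update <- function(params, grads, state, t, lr, beta1, beta2, eps) {
  for (nm in names(params)) {
    g <- grads[[paste0("g", nm)]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    m_hat <- st$m / (1 - beta1^t)
    v_hat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

#' Training configuration for the contraction-class MLP
#'
#' Defaults follow the training recipe being reproduced: 3000 epochs, 4
#' hidden nodes, a 0.20 test split and 0.1 validation split with seed 42, and
#' Adam optimization.
#'
#' @param epochs Training epochs (full-batch).
#' @param hidden_nodes Hidden-layer width.
#' @param test_fraction Held-out test fraction.
#' @param validation_fraction Validation fraction (of the training remainder).
#' @param seed RNG seed for the split and weight initialization.
#' @param learning_rate Adam step size.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param init_scale Weights start uniform in `[-init_scale, init_scale)`.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 3000, hidden_nodes = 4,
                         test_fraction = 0.20, validation_fraction = 0.1,
                         seed = 42, learning_rate = 0.01,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         init_scale = 0.5) {
  stopifnot(
    epochs >= 1, hidden_nodes >= 1,
    test_fraction > 0, test_fraction < 1,
    validation_fraction > 0, validation_fraction < 1
  )
  structure(
    list(
      epochs = epochs, hidden_nodes = hidden_nodes,
      test_fraction = test_fraction,
      validation_fraction = validation_fraction, seed = seed,
      learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
      epsilon = epsilon, init_scale = init_scale
    ),
    class = "train_config"
  )
}

#' Train the contraction-class MLP
#'
#' Trains a one-hidden-layer ReLU/softmax network on labeled segment
#' features by full-batch Adam on the categorical cross-entropy. Features are
#' standardized with a scaler fitted on the full feature table; examples are
#' split into test / validation / training subsets with the configured seed;
#' weights initialize uniformly in `[-init_scale, init_scale)`.
#'
#' @param features A tibble with the four feature columns (`duration_s`,
#'   `rms_mv`, `mav_mv`, `zcr_hz`) and a `class` column of class names
#'   (see [extract_features()]).
#' @param config A [train_config()].
#' @return An `emg_mlp` object: weights `W1`, `b1`, `W2`, `b2`, the fitted
#'   `scaler`, the class map, per-epoch `history` (train/validation loss and
#'   accuracy), the split row indices, and held-out test accuracy.
#' @export
#' @examples
#' \donttest{
#' s <- emg_generate(emg_session_plan(reps = 12, shuffle = FALSE), seed = 42)
#' feats <- extract_features(s$recording, s$events)
#' fit <- train_mlp(feats, train_config(epochs = 300))
#' glance(fit)
#' }
train_mlp <- function(features, config = train_config()) {
  fn <- feature_names()
  if (!all(fn %in% names(features)) || !"class" %in% names(features)) {
    rlang::abort("`features` needs columns duration_s, rms_mv, mav_mv, zcr_hz, class.")
  }
  labels <- class_label(features$class)
  n_class <- 4
  counts <- table(factor(labels, levels = 0:3))
  x_raw <- as.matrix(features[, fn])
  scaler <- fit_scaler(x_raw)
  x <- scale_features(x_raw, scaler)
  y <- one_hot(labels, n_class)

  with_local_seed(config$seed, {
    n <- nrow(x)
    perm <- sample(n)
    n_test <- max(1, round(config$test_fraction * n))
    idx_test <- perm[seq_len(n_test)]
    rest <- perm[-seq_len(n_test)]
    n_val <- max(1, round(config$validation_fraction * length(rest)))
    idx_val <- rest[seq_len(n_val)]
    idx_train <- rest[-seq_len(n_val)]
    if (length(unique(labels[idx_train])) < n_class) {
      rlang::abort("A class is absent from the training split; provide more examples.")
    }
    d_in <- ncol(x)
    h <- config$hidden_nodes
    init <- function(nr, nc) {
      matrix((2 * stats::runif(nr * nc) - 1) * config$init_scale, nr, nc)
    }
    params <- list(
      W1 = init(d_in, h), b1 = rep(0, h),
      W2 = init(h, n_class), b2 = rep(0, n_class)
    )
    st <- adam_state(params)
    hist <- matrix(NA_real_, nrow = config$epochs, ncol = 4)
    colnames(hist) <- c("train_loss", "val_loss", "train_acc", "val_acc")
    xt <- x[idx_train, , drop = FALSE]
    yt <- y[idx_train, , drop = FALSE]
    xv <- x[idx_val, , drop = FALSE]
    yv <- y[idx_val, , drop = FALSE]
    acc <- function(p, yy) {
      mean(max.col(p, ties.method = "first") ==
        max.col(yy, ties.method = "first"))
    }
    for (e in seq_len(config$epochs)) {
      g <- mlp_grad(params, xt, yt)
      up <- adam_update(
        params, g, st, e, config$learning_rate,
        config$beta1, config$beta2, config$epsilon
      )
      params <- up$params
      st <- up$state
      pv <- mlp_forward(params, xv)
      hist[e, ] <- c(
        g$loss, cross_entropy(yv, pv),
        acc(g$probs, yt), acc(pv, yv)
      )
    }
    p_test <- mlp_forward(params, x[idx_test, , drop = FALSE])
    test_acc <- acc(p_test, y[idx_test, , drop = FALSE])
    structure(
      list(
        W1 = unname(params$W1), b1 = unname(params$b1),
        W2 = unname(params$W2), b2 = unname(params$b2),
        scaler = scaler, classes = contraction_classes(),
        config = config,
        history = dplyr::bind_cols(
          tibble::tibble(epoch = seq_len(config$epochs)),
          tibble::as_tibble(hist)
        ),
        split = list(train = idx_train, validation = idx_val, test = idx_test),
        test_accuracy = test_acc
      ),
      class = "emg_mlp"
    )
  })
}

#' @export
print.emg_mlp <- function(x, ...) {
  cat(sprintf(
    "<emg_mlp> %d-%d-%d ReLU/softmax, %d epochs, test accuracy %.3f\n",
    nrow(x$W1), ncol(x$W1), ncol(x$W2),
    nrow(x$history), x$test_accuracy
  ))
  invisible(x)
}

#' Classify segments with a trained model
#'
#' Standardizes segment features with the model's scaler, runs the forward
#' pass and takes the arg-max class (ties broken toward the lowest class
#' index). The `pulse` columns are the one-hot activation the state machine
#' consumes, in machine bit order `[NIM, SMP3, SMP5, SMP]`.
#'
#' @param model A trained `emg_mlp`.
#' @param features A tibble with the four feature columns (one row per
#'   segment), e.g. from [extract_features()].
#' @return `features` with `class` (predicted), `prob` (winning probability)
#'   and `pulse` (4-character bit word) columns appended.
#' @export
predict_class <- function(model, features) {
  if (!inherits(model, "emg_mlp")) {
    rlang::abort("`model` must be a trained emg_mlp.")
  }
  fn <- feature_names()
  if (!all(fn %in% names(features))) {
    rlang::abort("`features` needs columns duration_s, rms_mv, mav_mv, zcr_hz.")
  }
  if (nrow(features) == 0) {
    return(dplyr::mutate(features,
      class = character(0), prob = numeric(0), pulse = character(0)
    ))
  }
  x <- scale_features(as.matrix(features[, fn]), model$scaler)
  p <- mlp_forward(model, x)
  win <- apply(p, 1, function(r) which(r == max(r))[1]) # lowest index on ties
  cls <- model$classes$class[match(win - 1, model$classes$label)]
  out <- dplyr::mutate(features,
    class = cls,
    prob = p[cbind(seq_len(nrow(p)), win)],
    pulse = purrr::map_chr(cls, encode_inputs)
  )
  out
}

#' Serialize / load a trained model as JSON
#'
#' Weights are stored as row-major nested lists with explicit shapes,
#' together with the scaler and the class map.
#'
#' @param model An `emg_mlp`.
#' @param path Output path.
#' @return `read_mlp()` returns an `emg_mlp` (without training history).
#' @export
write_mlp <- function(model, path) {
  obj <- list(
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    scaler = list(mean = model$scaler$mean, std = model$scaler$std),
    class_map = model$classes,
    test_accuracy = model$test_accuracy
  )
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      W1 = obj$W1, b1 = obj$b1, W2 = obj$W2, b2 = obj$b2,
      scaler = structure(
        list(
          mean = stats::setNames(obj$scaler$mean, feature_names()),
          std = stats::setNames(obj$scaler$std, feature_names())
        ),
        class = "feature_scaler"
      ),
      classes = tibble::as_tibble(obj$class_map),
      history = NULL,
      test_accuracy = obj$test_accuracy
    ),
    class = "emg_mlp"
  )
}
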