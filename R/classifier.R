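#' The seven-expression label scheme and its positive/negative collapse
#'
#' The deployed recognition model is two-class: the six basic emotions plus
#' neutral are collapsed onto `negative` (anger, disgust, fear, sadness) and
#' `positive` (happiness, surprise, neutral). Seven-class names are retained
#' for logging and per-expression reporting.
#'
#' @return A `label_scheme`: list with `seven_classes`, `binary_map` (named
#'   character) and `binary_levels` (class order used for tie-breaking).
#' @export
label_scheme <- function() {
  seven <- c("anger", "disgust", "fear", "happiness", "neutral",
             "sadness", "surprise")
  binary_map <- c(anger = "negative", disgust = "negative", fear = "negative",
                  sadness = "negative", happiness = "positive",
                  surprise = "positive", neutral = "positive")
  structure(list(seven_classes = seven,
                 binary_map = binary_map[seven],
                 binary_levels = c("negative", "positive")),
            class = "label_scheme")
}

#' Collapse a seven-class expression label to positive/negative
#'
#' @param label Character vector of seven-class names.
#' @param scheme A [label_scheme()].
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
map_to_binary <- function(label, scheme = label_scheme()) {
  out <- scheme$binary_map[label]
  if (anyNA(out)) {
    stop_fm("label", sprintf("unknown expression label(s): %s",
                             paste(unique(label[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

#' Training configuration for the recognition network
#'
#' Defaults reproduce the published recipe: one hidden dense layer of size
#' 10 with sigmoid activation and a softmax classification layer, trained
#' 200 epochs with Adam, batch size 128, initial learning rate 0.01, on a
#' 90/10 train/validation split.
#'
#' @param hidden_size Hidden layer width.
#' @param epochs Number of full passes over the training set.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param optimizer_name Only `"adam"` is implemented.
#' @param validation_fraction Fraction held out by [split_dataset()].
#' @param seed Integer seed governing init and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(hidden_size = 10L, epochs = 200L, batch_size = 128L,
                         learning_rate = 0.01, optimizer_name = "adam",
                         validation_fraction = 0.10, seed = 1L) {
  stopifnot(hidden_size >= 1, epochs >= 1, batch_size >= 1, learning_rate > 0)
  if (!identical(optimizer_name, "adam")) {
    stop_fm("config", "only the adam optimizer is supported")
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop_fm("config", "validation_fraction must lie strictly in (0, 1)")
  }
  structure(list(hidden_size = as.integer(hidden_size),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer_name = optimizer_name,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/validation split
#'
#' Splits a labeled feature data frame into disjoint, exhaustive training and
#' validation sets, stratified by binary label. Validation size is
#' `round(n * fraction)` overall, apportioned across strata by largest
#' remainder so per-class proportions are preserved.
#'
#' @param features Data frame with a `label` column (seven-class names) or a
#'   `binary` column.
#' @param fraction Validation fraction in (0, 1).
#' @param seed Integer seed; identical inputs and seed give identical splits.
#' @param scheme A [label_scheme()].
#' @return List with data frames `train` and `validation`.
#' @export
split_dataset <- function(features, fraction = 0.10, seed = 1L,
                          scheme = label_scheme()) {
  if (fraction <= 0 || fraction >= 1) {
    stop_fm("config", "split fraction must lie strictly in (0, 1)")
  }
  binary <- if ("binary" %in% names(features)) features$binary
            else map_to_binary(features$label, scheme)
  n <- nrow(features)
  n_val <- round(n * fraction)
  strata <- split(seq_len(n), binary)
  quota <- vapply(strata, length, integer(1)) * fraction
  take <- floor(quota)
  rem <- n_val - sum(take)
  if (rem > 0) {
    order_frac <- order(quota - take, decreasing = TRUE)
    take[order_frac[seq_len(rem)]] <- take[order_frac[seq_len(rem)]] + 1
  }
  val_idx <- with_seed(seed, {
    unlist(Map(function(idx, k) {
      if (k == 0) integer(0) else sample(idx, k)
    }, strata, take), use.names = FALSE)
  })
  list(train = features[setdiff(seq_len(n), val_idx), , drop = FALSE],
       validation = features[sort(val_idx), , drop = FALSE])
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(abs(seed) %% 2147483647))
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# split a labeled feature data frame into X matrix and binary factor y
design_matrix <- function(features, scheme = label_scheme()) {
  feat_cols <- grep("^(R_|theta_)", names(features), value = TRUE)
  X <- as.matrix(features[, feat_cols, drop = FALSE])
  storage.mode(X) <- "double"
  binary <- if ("binary" %in% names(features)) features$binary
            else map_to_binary(features$label, scheme)
  list(X = X, y = factor(binary, levels = scheme$binary_levels))
}

#' Train the expression recognition network
#'
#' One hidden dense layer (sigmoid) and a softmax classification layer,
#' fitted by mini-batch Adam on categorical cross-entropy. Weights use
#' seeded Glorot-uniform initialization; the epoch shuffling uses the same
#' seed stream, so training is bit-reproducible for a fixed seed.
#'
#' @param features Labeled feature data frame (columns `R_*`, `theta_*`, and
#'   `label` or `binary`).
#' @param config A [train_config()].
#' @param scheme A [label_scheme()].
#' @return A `trained_model` with weight matrices, the per-epoch training
#'   loss `history`, `feature_dimension` and the label scheme.
#' @export
train_model <- function(features, config = train_config(),
                        scheme = label_scheme()) {
  dm <- design_matrix(features, scheme)
  X <- dm$X
  y <- dm$y
  if (anyNA(X)) stop_fm("data", "non-finite feature values in training data")
  if (any(table(y) == 0)) {
    stop_fm("data", sprintf("empty class in training data: %s",
                            paste(levels(y)[table(y) == 0], collapse = ", ")))
  }
  n <- nrow(X); d <- ncol(X); h <- config$hidden_size
  k <- length(scheme$binary_levels)
  Y <- diag(k)[as.integer(y), , drop = FALSE]   # one-hot

  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  with_seed(config$seed, {
    W1 <- glorot(d, h); b1 <- rep(0, h)
    W2 <- glorot(h, k); b2 <- rep(0, k)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0
    history <- numeric(config$epochs)

    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        nb <- length(idx)
        H <- sigmoid(sweep(Xb %*% params$W1, 2, params$b1, "+"))
        P <- softmax_rows(sweep(H %*% params$W2, 2, params$b2, "+"))
        epoch_loss <- epoch_loss - sum(log(pmax(P[Yb == 1], 1e-12)))
        dZ2 <- (P - Yb) / nb
        grads <- list(
          W1 = NULL, b1 = NULL,
          W2 = crossprod(H, dZ2), b2 = colSums(dZ2))
        dH <- dZ2 %*% t(params$W2) * H * (1 - H)
        grads$W1 <- crossprod(Xb, dH)
        grads$b1 <- colSums(dH)
        t_step <- t_step + 1
        for (nm in names(params)) {
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
          m_hat <- m[[nm]] / (1 - beta1^t_step)
          v_hat <- v[[nm]] / (1 - beta2^t_step)
          params[[nm]] <- params[[nm]] -
            config$learning_rate * m_hat / (sqrt(v_hat) + eps)
        }
      }
      history[epoch] <- epoch_loss / n
    }
    structure(list(weights = params,
                   feature_dimension = d,
                   feature_names = colnames(X),
                   label_scheme = scheme,
                   config = config,
                   train_history = history),
              class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> %d features -> %d hidden (sigmoid) -> %d classes (softmax)\n",
    x$feature_dimension, x$config$hidden_size, length(x$label_scheme$binary_levels)))
  cat(sprintf("  trained %d epochs; final loss %.4f\n",
              length(x$train_history), tail_loss(x)))
  invisible(x)
}

tail_loss <- function(model) model$train_history[length(model$train_history)]

#' Class probabilities and predicted labels
#'
#' Forward pass through the trained network. `predict_model` returns the
#' full probability matrix plus argmax labels (ties broken toward the first
#' class in scheme order).
#'
#' @param model A `trained_model`.
#' @param features Feature data frame or numeric matrix whose columns match
#'   the model's feature dimension.
#' @return List with `probabilities` (rows sum to 1) and `labels`.
#' @export
predict_model <- function(model, features) {
  X <- if (is.matrix(features)) features
       else if (inherits(features, "feature_vector"))
         matrix(as.numeric(features), nrow = 1)
       else design_matrix(features, model$label_scheme)$X
  storage.mode(X) <- "double"
  if (ncol(X) != model$feature_dimension) {
    stop_fm("shape", sprintf(
      "feature dimension %d does not match the model's expected %d",
      ncol(X), model$feature_dimension))
  }
  w <- model$weights
  H <- sigmoid(sweep(X %*% w$W1, 2, w$b1, "+"))
  P <- softmax_rows(sweep(H %*% w$W2, 2, w$b2, "+"))
  colnames(P) <- model$label_scheme$binary_levels
  labels <- model$label_scheme$binary_levels[max.col(P, ties.method = "first")]
  list(probabilities = P, labels = labels)
}

#' Validation accuracy of a model on a labeled feature set
#'
#' @param model A `trained_model`.
#' @param features Labeled feature data frame.
#' @return Fraction of rows whose predicted binary label matches the binary
#'   image of the true label.
#' @export
model_accuracy <- function(model, features) {
  dm <- design_matrix(features, model$label_scheme)
  mean(predict_model(model, dm$X)$labels == as.character(dm$y))
}

#' Serialize / restore a trained model as JSON
#'
#' Architecture metadata, flattened weights, label scheme and training
#' configuration in one language-neutral JSON document.
#'
#' @param model A `trained_model`.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  w <- model$weights
  doc <- list(
    architecture = list(
      input = model$feature_dimension,
      hidden = model$config$hidden_size,
      hidden_activation = "sigmoid",
      output = length(model$label_scheme$binary_levels),
      output_activation = "softmax"),
    feature_names = model$feature_names,
    weights = list(W1 = as.vector(w$W1), b1 = w$b1,
                   W2 = as.vector(w$W2), b2 = w$b2),
    label_scheme = list(
      seven_classes = model$label_scheme$seven_classes,
      binary_map = as.list(model$label_scheme$binary_map),
      binary_levels = model$label_scheme$binary_levels),
    train_config = unclass(model$config),
    train_history = model$train_history)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  d <- doc$architecture$input; h <- doc$architecture$hidden
  k <- doc$architecture$output
  scheme <- structure(list(
    seven_classes = doc$label_scheme$seven_classes,
    binary_map = unlist(doc$label_scheme$binary_map),
    binary_levels = doc$label_scheme$binary_levels), class = "label_scheme")
  cfg <- do.call(train_config, doc$train_config)
  structure(list(
    weights = list(W1 = matrix(doc$weights$W1, d, h), b1 = doc$weights$b1,
                   W2 = matrix(doc$weights$W2, h, k), b2 = doc$weights$b2),
    feature_dimension = d,
    feature_names = doc$feature_names,
    label_scheme = scheme,
    config = cfg,
    train_history = doc$train_history),
    class = "trained_model")
}
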