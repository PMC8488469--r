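#' Deep-neural-network configuration
#'
#' Settings for the pair classifier: a small feedforward network with ReLU
#' hidden layers and a sigmoid output unit, trained on the binary
#' cross-entropy loss with the Adam adaptive-learning-rate optimiser and
#' inverted dropout on hidden activations.
#'
#' Two architectures are available. `merged` feeds the whole pair
#' descriptor through the hidden layers (default: two hidden layers of 48
#' neurons). `siamese` splits the descriptor into its two per-protein
#' halves, passes each half through its own twin subnetwork (width
#' `hidden[1]`, independent weights), concatenates the twin outputs and
#' passes them through the remaining fused layers.
#'
#' @param architecture `"merged"` (default) or `"siamese"`.
#' @param hidden Integer vector of hidden-layer widths (default `c(48, 48)`).
#' @param dropout Dropout rate in `[0, 1)` applied to hidden activations
#'   during training only (default 0.5).
#' @param learning_rate Adam step size (default 0.001).
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 64).
#' @param seed Integer seed driving initialisation, shuffling and dropout.
#' @return A list of class `dnn_config`.
#' @export
dnn_config <- function(architecture = c("merged", "siamese"),
                       hidden = c(48L, 48L), dropout = 0.5,
                       learning_rate = 0.001, epochs = 100L,
                       batch_size = 64L, seed = 1L) {
  architecture <- match.arg(architecture)
  hidden <- as.integer(hidden)
  if (length(hidden) < 1L || any(hidden < 1L))
    stop("hidden must contain at least one positive width")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(architecture = architecture, hidden = hidden,
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "dnn_config")
}

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

# Layer skeleton: list(W, b, mask) per layer; mask (0/1) encodes the
# block-diagonal twin structure of the siamese first hidden layer and is
# applied to both initial weights and every gradient, which is equivalent
# to two weight-independent twin subnetworks.
build_layers <- function(cfg, d) {
  if (cfg$architecture == "siamese") {
    if (d %% 2L != 0L)
      stop("siamese architecture needs an even input dimension, got ", d)
    half <- d %/% 2L
    twin <- cfg$hidden[1L]
    dims <- c(d, 2L * twin, cfg$hidden[-1L], 1L)
    mask1 <- matrix(0, d, 2L * twin)
    mask1[seq_len(half), seq_len(twin)] <- 1
    mask1[half + seq_len(half), twin + seq_len(twin)] <- 1
    masks <- c(list(mask1), vector("list", length(dims) - 2L))
  } else {
    dims <- c(d, cfg$hidden, 1L)
    masks <- vector("list", length(dims) - 1L)
  }
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fi <- dims[l]; fo <- dims[l + 1L]
    lim <- sqrt(6 / (fi + fo))
    W <- matrix(stats::runif(fi * fo, -lim, lim), fi, fo)
    if (!is.null(masks[[l]])) W <- W * masks[[l]]
    layers[[l]] <- list(W = W, b = numeric(fo), mask = masks[[l]])
  }
  layers
}

# Forward pass. dropout_masks: NULL (inference) or list of pre-scaled
# inverted-dropout masks per hidden layer. Returns activations per layer.
dnn_forward <- function(layers, X, dropout_masks = NULL) {
  L <- length(layers)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    if (l < L) {
      act <- relu(Z[[l]])
      if (!is.null(dropout_masks) && !is.null(dropout_masks[[l]]))
        act <- act * dropout_masks[[l]]
      A[[l + 1L]] <- act
    } else {
      A[[l + 1L]] <- sigmoid(Z[[l]])
    }
  }
  list(A = A, Z = Z)
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Loss and exact gradients of the mean binary cross-entropy by
# backpropagation. Verified against finite differences in the test suite.
dnn_loss_grad <- function(layers, X, y, dropout_masks = NULL) {
  n <- nrow(X)
  L <- length(layers)
  fw <- dnn_forward(layers, X, dropout_masks)
  p <- fw$A[[L + 1L]]
  loss <- bce_loss(p, y)
  grads <- vector("list", L)
  dZ <- (p - y) / n                      # d loss / d z_out for sigmoid+BCE
  for (l in rev(seq_len(L))) {
    dW <- crossprod(fw$A[[l]], dZ)
    if (!is.null(layers[[l]]$mask)) dW <- dW * layers[[l]]$mask
    grads[[l]] <- list(W = dW, b = colSums(dZ))
    if (l > 1L) {
      dA <- dZ %*% t(layers[[l]]$W)
      if (!is.null(dropout_masks) && !is.null(dropout_masks[[l - 1L]]))
        dA <- dA * dropout_masks[[l - 1L]]
      dZ <- dA * (fw$Z[[l - 1L]] > 0)
    }
  }
  list(loss = loss, grads = grads)
}

#' Train the feedforward pair classifier
#'
#' Optimises the binary cross-entropy loss
#' `L = -(1/n) * sum(y * log(p) + (1 - y) * log(1 - p))` with Adam
#' (beta1 = 0.9, beta2 = 0.999), mini-batch shuffling and inverted
#' dropout on hidden activations. All randomness (weight initialisation,
#' shuffling, dropout masks) is driven by `cfg$seed`, so identical calls
#' produce identical models; the caller's RNG state is left untouched.
#'
#' @param X Numeric n x d matrix of pair descriptors.
#' @param y Binary labels (0/1), length n, both classes present.
#' @param cfg A [dnn_config()].
#' @return An object of class `dnn_model` with fields `layers`, `config`
#'   and `loss_trace` (full-data loss after each epoch).
#' @export
train_dnn <- function(X, y, cfg = dnn_config()) {
  stopifnot(inherits(cfg, "dnn_config"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X contains non-finite values")
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; need both 0 and 1")
  n <- nrow(X); d <- ncol(X)
  ym <- matrix(y, ncol = 1L)
  keep <- 1 - cfg$dropout

  with_seed(cfg$seed, {
    layers <- build_layers(cfg, d)
    L <- length(layers)
    adam <- lapply(layers, function(l)
      list(mW = l$W * 0, vW = l$W * 0,
           mb = numeric(length(l$b)), vb = numeric(length(l$b))))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
    trace <- numeric(cfg$epochs)

    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- ym[idx, , drop = FALSE]
        dm <- NULL
        if (cfg$dropout > 0) {
          dm <- lapply(seq_len(L - 1L), function(l) {
            w <- ncol(layers[[l]]$W)
            matrix(stats::rbinom(length(idx) * w, 1L, keep) / keep,
                   length(idx), w)
          })
        }
        lg <- dnn_loss_grad(layers, Xb, yb, dm)
        t <- t + 1L
        for (l in seq_len(L)) {
          g <- lg$grads[[l]]
          a <- adam[[l]]
          a$mW <- b1 * a$mW + (1 - b1) * g$W
          a$vW <- b2 * a$vW + (1 - b2) * g$W^2
          a$mb <- b1 * a$mb + (1 - b1) * g$b
          a$vb <- b2 * a$vb + (1 - b2) * g$b^2
          mWh <- a$mW / (1 - b1^t); vWh <- a$vW / (1 - b2^t)
          mbh <- a$mb / (1 - b1^t); vbh <- a$vb / (1 - b2^t)
          step_W <- cfg$learning_rate * mWh / (sqrt(vWh) + eps)
          if (!is.null(layers[[l]]$mask)) step_W <- step_W * layers[[l]]$mask
          layers[[l]]$W <- layers[[l]]$W - step_W
          layers[[l]]$b <- layers[[l]]$b - cfg$learning_rate * mbh / (sqrt(vbh) + eps)
          adam[[l]] <- a
        }
      }
      p <- dnn_forward(layers, X)$A[[L + 1L]]
      trace[epoch] <- bce_loss(p, ym)
    }
    structure(list(layers = layers, config = cfg, loss_trace = trace,
                   input_dim = d),
              class = "dnn_model")
  })
}

#' @export
print.dnn_model <- function(x, ...) {
  widths <- vapply(x$layers, function(l) ncol(l$W), integer(1))
  cat(sprintf("<dnn_model> %s, %d -> %s, final loss %.4f\n",
              x$config$architecture, x$input_dim,
              paste(widths, collapse = " -> "),
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Predict interaction scores with a trained network
#'
#' Deterministic forward pass with dropout disabled; returns the sigmoid
#' output, an interaction probability in (0, 1), per row of `newdata`.
#'
#' @param object A `dnn_model`.
#' @param newdata Numeric matrix with the training input dimension.
#' @param ... Unused.
#' @return Numeric vector of scores in (0, 1).
#' @export
predict.dnn_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_dim)
    stop("newdata has ", ncol(newdata), " columns, model expects ",
         object$input_dim)
  as.numeric(dnn_forward(object$layers, newdata)$A[[length(object$layers) + 1L]])
}

#' Train a baseline classifier (KNN or random forest)
#'
#' Comparator classifiers sharing the scoring contract of
#' [predict.dnn_model()]: probability scores in `[0, 1]` for the positive
#' class. KNN scores are the fraction of the k nearest training
#' neighbours labelled positive; RF scores are the forest's class-1 vote
#' fraction.
#'
#' @param kind `"knn"` or `"rf"`.
#' @param X Numeric n x d training matrix.
#' @param y Binary labels (0/1).
#' @param k Number of neighbours for KNN (default 5).
#' @param trees Number of trees for RF (default 500).
#' @param seed Integer seed (RF fitting and KNN tie-breaks).
#' @return Object of class `ppi_baseline` with a `predict` method.
#' @export
train_baseline <- function(kind, X, y, k = 5L, trees = 500L, seed = 1L) {
  if (!kind %in% c("knn", "rf"))
    stop("unsupported baseline kind: '", kind, "' (use \"knn\" or \"rf\")")
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  fit <- if (kind == "rf") {
    with_seed(seed, randomForest::randomForest(
      x = X, y = factor(y, levels = c(0L, 1L)), ntree = as.integer(trees)))
  } else NULL
  structure(list(kind = kind, X = X, y = y, k = as.integer(k),
                 fit = fit, seed = as.integer(seed)),
            class = "ppi_baseline")
}

#' @rdname train_baseline
#' @param object A `ppi_baseline`.
#' @param newdata Matrix of descriptors to score.
#' @param ... Unused.
#' @export
predict.ppi_baseline <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$kind == "rf")
    return(as.numeric(
      stats::predict(object$fit, newdata, type = "prob")[, "1"]))
  with_seed(object$seed, {
    pred <- class::knn(object$X, newdata,
                       cl = factor(object$y, levels = c(0L, 1L)),
                       k = object$k, prob = TRUE)
    pr <- attr(pred, "prob")
    as.numeric(ifelse(pred == "1", pr, 1 - pr))
  })
}
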