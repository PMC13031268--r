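#' Classifier hyperparameters
#'
#' Defaults follow the reference configuration: two hidden layers of 128 and
#' 32 units, tanh activations, cross-entropy loss, Adam with learning rate
#' 1e-3 and no weight decay, batch size 128, 100 epochs, and a 10% stratified
#' validation split used for monitoring only (no early stopping). Alternative
#' configurations (ReLU/LeakyReLU, dropout, decoupled weight decay, class
#' weighting, other batch sizes) are expressible through the corresponding
#' arguments.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param activation One of `"tanh"`, `"relu"`, `"leaky_relu"`.
#' @param learning_rate Adam step size.
#' @param weight_decay Decoupled (AdamW-style) weight decay; 0 disables it.
#' @param dropout Dropout rate applied to hidden activations during training.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (fixed; no early stopping).
#' @param validation_fraction Fraction held out per peer for monitoring, in
#'   `[0, 0.5)`; 0 disables the split.
#' @param class_weights `NULL`, or `"balanced"` for inverse-frequency loss
#'   weights, or a named numeric vector over classes.
#' @param seed Integer seed controlling initialization, splits and shuffles.
#' @return An `mlp_hyperparams` list.
#' @export
mlp_hyperparams <- function(hidden_sizes = c(128L, 32L),
                            activation = c("tanh", "relu", "leaky_relu"),
                            learning_rate = 1e-3,
                            weight_decay = 0,
                            dropout = 0,
                            batch_size = 128L,
                            epochs = 100L,
                            validation_fraction = 0.1,
                            class_weights = NULL,
                            seed = 1L) {
  activation <- match.arg(activation)
  if (any(hidden_sizes <= 0)) stop("hidden sizes must be positive", call. = FALSE)
  stopifnot_scalar_num(learning_rate, "learning_rate", 0)
  stopifnot_scalar_num(batch_size, "batch_size", 0, strict = TRUE)
  stopifnot_scalar_num(epochs, "epochs", 0, strict = TRUE)
  if (validation_fraction < 0 || validation_fraction >= 0.5) {
    stop("'validation_fraction' must lie in [0, 0.5)", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("'dropout' must lie in [0, 1)", call. = FALSE)
  structure(list(
    hidden_sizes = as.integer(hidden_sizes), activation = activation,
    learning_rate = learning_rate, weight_decay = weight_decay,
    dropout = dropout, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), validation_fraction = validation_fraction,
    class_weights = class_weights, seed = as.integer(seed)
  ), class = "mlp_hyperparams")
}

activation_funs <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(a) 1 - a^2),
    relu = list(f = function(z) pmax(z, 0), df = function(a) (a > 0) * 1),
    leaky_relu = list(
      f = function(z) ifelse(z > 0, z, 0.01 * z),
      df = function(a) ifelse(a > 0, 1, 0.01)
    ),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

#' Initialize classifier parameters and optimizer state
#'
#' Weights are Glorot-uniform, biases zero, Adam moments zero; the result is
#' deterministic for a fixed seed.
#'
#' @param n_features Input dimension (length of the shared feature space).
#' @param class_labels Ordered class vocabulary (at least two classes).
#' @param hp An [mlp_hyperparams()] object.
#' @param feature_ids Optional ordered gene ids recorded on the parameters.
#' @return A list with `params` (weights `W`, biases `b`, vocabularies) and
#'   `opt` (zeroed Adam state).
#' @export
init_mlp <- function(n_features, class_labels, hp = mlp_hyperparams(),
                     feature_ids = NULL) {
  class_labels <- as.character(class_labels)
  if (n_features < 1) stop("need at least one feature", call. = FALSE)
  if (length(class_labels) < 2 || anyDuplicated(class_labels)) {
    stop("class vocabulary must hold at least two distinct labels", call. = FALSE)
  }
  dims <- c(n_features, hp$hidden_sizes, length(class_labels))
  params <- with_seed(derive_seed(hp$seed, "init"), {
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      lim <- sqrt(6 / (dims[l] + dims[l + 1L]))
      W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -lim, lim),
                       nrow = dims[l], ncol = dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
    list(W = W, b = b, class_labels = class_labels,
         feature_ids = feature_ids, activation = hp$activation)
  })
  list(params = params, opt = zero_opt_state(params))
}

zero_opt_state <- function(params) {
  zeros <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  list(mW = lapply(params$W, zeros), vW = lapply(params$W, zeros),
       mb = lapply(params$b, zeros), vb = lapply(params$b, zeros),
       step = 0L)
}

## Forward / backward --------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass: class probabilities
#'
#' @param params Parameters from [init_mlp()] (or a `swarm_mlp` fit, whose
#'   `$params` are used).
#' @param X Numeric matrix whose columns follow `params$feature_ids` order
#'   (checked when both carry names).
#' @return Matrix of class probabilities, rows summing to 1.
#' @export
mlp_forward <- function(params, X) {
  if (inherits(params, "swarm_mlp")) params <- params$params
  X <- as.matrix(X)
  if (ncol(X) != nrow(params$W[[1L]])) {
    stop(sprintf("input has %d features but the model expects %d",
                 ncol(X), nrow(params$W[[1L]])), call. = FALSE)
  }
  if (!is.null(params$feature_ids) && !is.null(colnames(X)) &&
      !identical(colnames(X), params$feature_ids)) {
    stop("input column order does not match the model's feature_ids", call. = FALSE)
  }
  act <- activation_funs(params$activation)$f
  H <- X
  L <- length(params$W)
  for (l in seq_len(L - 1L)) {
    H <- act(sweep(H %*% params$W[[l]], 2L, params$b[[l]], "+"))
  }
  logits <- sweep(H %*% params$W[[L]], 2L, params$b[[L]], "+")
  P <- softmax_rows(logits)
  colnames(P) <- params$class_labels
  P
}

# Forward keeping activations; optional per-layer dropout masks (list or NULL).
forward_cached <- function(params, X, drop_masks = NULL) {
  act <- activation_funs(params$activation)$f
  L <- length(params$W)
  A <- vector("list", L)  # A[[l]]: input to layer l
  H <- X
  for (l in seq_len(L - 1L)) {
    A[[l]] <- H
    H <- act(sweep(H %*% params$W[[l]], 2L, params$b[[l]], "+"))
    if (!is.null(drop_masks)) H <- H * drop_masks[[l]]
  }
  A[[L]] <- H
  logits <- sweep(H %*% params$W[[L]], 2L, params$b[[L]], "+")
  list(A = A, P = softmax_rows(logits))
}

# Mean cross-entropy and parameter gradients for one batch.
# y: integer class indices; w: optional per-sample loss weights (mean-normalized).
mlp_loss_grads <- function(params, X, y, sample_w = NULL, drop_masks = NULL) {
  n <- nrow(X)
  fc <- forward_cached(params, X, drop_masks)
  P <- fc$P
  picked <- P[cbind(seq_len(n), y)]
  w <- if (is.null(sample_w)) rep(1, n) else sample_w
  w <- w / sum(w) * n
  loss <- -mean(w * log(pmax(picked, 1e-12)))

  dact <- activation_funs(params$activation)$df
  L <- length(params$W)
  Y <- matrix(0, n, ncol(P))
  Y[cbind(seq_len(n), y)] <- 1
  delta <- (P - Y) * (w / n)  # d loss / d logits
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fc$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params$W[[l]])) * dact(fc$A[[l]])
      if (!is.null(drop_masks)) delta <- delta * drop_masks[[l - 1L]]
    }
  }
  list(loss = loss, gW = gW, gb = gb)
}

adam_update <- function(params, opt, grads, hp,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$step <- opt$step + 1L
  t <- opt$step
  lr <- hp$learning_rate
  for (l in seq_along(params$W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    mhat <- opt$mW[[l]] / (1 - beta1^t)
    vhat <- opt$vW[[l]] / (1 - beta2^t)
    step <- mhat / (sqrt(vhat) + eps)
    if (hp$weight_decay > 0) step <- step + hp$weight_decay * params$W[[l]]
    params$W[[l]] <- params$W[[l]] - lr * step

    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    mhatb <- opt$mb[[l]] / (1 - beta1^t)
    vhatb <- opt$vb[[l]] / (1 - beta2^t)
    params$b[[l]] <- params$b[[l]] - lr * mhatb / (sqrt(vhatb) + eps)
  }
  list(params = params, opt = opt)
}

#' One Adam step per batch on mean cross-entropy
#'
#' Consumes a list of batches in order; the update sequence is a
#' deterministic function of the starting state and the batch sequence.
#'
#' @param params,opt State from [init_mlp()] (or a later call).
#' @param batches List of batches, each a list with `x` (matrix in the
#'   model's feature order) and `y` (integer class indices or labels in the
#'   class vocabulary).
#' @param hp An [mlp_hyperparams()].
#' @return Updated `list(params, opt, losses)`.
#' @export
train_batches <- function(params, opt, batches, hp = mlp_hyperparams()) {
  losses <- numeric(length(batches))
  cw <- resolve_class_weights(hp$class_weights, params$class_labels, NULL)
  for (i in seq_along(batches)) {
    b <- batches[[i]]
    y <- batch_class_indices(b$y, params$class_labels)
    sw <- if (is.null(cw)) NULL else cw[y]
    g <- mlp_loss_grads(params, as.matrix(b$x), y, sample_w = sw)
    if (!is.finite(g$loss)) {
      stop(sprintf("non-finite training loss (%.4g) at batch %d", g$loss, i),
           call. = FALSE)
    }
    upd <- adam_update(params, opt, g, hp)
    params <- upd$params
    opt <- upd$opt
    losses[i] <- g$loss
  }
  list(params = params, opt = opt, losses = losses)
}

batch_class_indices <- function(y, class_labels) {
  if (is.numeric(y)) {
    y <- as.integer(y)
    if (any(y < 1 | y > length(class_labels))) {
      stop("class index outside vocabulary", call. = FALSE)
    }
    return(y)
  }
  idx <- match(as.character(y), class_labels)
  if (anyNA(idx)) {
    stop("labels outside the class vocabulary: ",
         paste(unique(y[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

resolve_class_weights <- function(spec, class_labels, y_idx) {
  if (is.null(spec)) return(NULL)
  if (identical(spec, "balanced")) {
    if (is.null(y_idx)) {
      # without data frequencies, fall back to uniform (no-op)
      return(NULL)
    }
    freq <- tabulate(y_idx, nbins = length(class_labels))
    w <- ifelse(freq > 0, sum(freq) / (length(class_labels) * freq), 0)
    return(w)
  }
  w <- spec[class_labels]
  if (anyNA(w)) stop("class_weights must name every class", call. = FALSE)
  as.numeric(w)
}
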