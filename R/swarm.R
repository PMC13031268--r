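#' Swarm protocol configuration
#'
#' @param sync_interval_batches Number of lockstep training rounds between
#'   synchronization (parameter-merge) events. Default 100, matching the
#'   reference protocol's sync frequency.
#' @param weighting `"dataset_size"` (merge weights proportional to each
#'   peer's number of training cells, the default) or `"uniform"`.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(sync_interval_batches = 100L,
                         weighting = c("dataset_size", "uniform")) {
  weighting <- match.arg(weighting)
  if (!is.infinite(sync_interval_batches)) {
    stopifnot_scalar_num(sync_interval_batches, "sync_interval_batches", 1)
  }
  structure(list(sync_interval_batches = sync_interval_batches,
                 weighting = weighting),
            class = "swarm_config")
}

#' Weighted average of model parameters
#'
#' Merges peer models elementwise: every weight and bias tensor of the result
#' equals `sum_i w_i * theta_i / sum_i w_i`. Class and feature vocabularies
#' must be identical across inputs and are passed through unchanged. Weights
#' are normalized to sum 1 before combining, and a single input is returned
#' unchanged, so merging one model is an exact identity.
#'
#' @param params_list List of parameter sets with identical shapes and
#'   vocabularies.
#' @param weights Non-negative merge weights, not all zero.
#' @return The merged parameter set.
#' @export
weighted_average <- function(params_list, weights) {
  if (length(params_list) < 1) stop("need at least one model", call. = FALSE)
  if (length(weights) != length(params_list)) {
    stop("one weight per model required", call. = FALSE)
  }
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  ref <- params_list[[1L]]
  for (p in params_list[-1L]) {
    if (!identical(p$class_labels, ref$class_labels) ||
        !identical(p$feature_ids, ref$feature_ids)) {
      stop("models disagree on class or feature vocabulary", call. = FALSE)
    }
    same_shape <- all(mapply(function(a, b) identical(dim(a), dim(b)),
                             p$W, ref$W)) &&
      all(mapply(function(a, b) length(a) == length(b), p$b, ref$b))
    if (!same_shape) stop("models disagree on layer shapes", call. = FALSE)
  }
  if (length(params_list) == 1L) return(ref)
  w <- weights / sum(weights)
  out <- ref
  for (l in seq_along(ref$W)) {
    out$W[[l]] <- Reduce(`+`, Map(function(p, wi) wi * p$W[[l]], params_list, w))
    out$b[[l]] <- Reduce(`+`, Map(function(p, wi) wi * p$b[[l]], params_list, w))
  }
  out
}

param_checksum <- function(params) {
  sum(vapply(params$W, sum, numeric(1))) + sum(vapply(params$b, sum, numeric(1)))
}

## Lockstep training engine --------------------------------------------------

# Stratified (falling back to unstratified) validation indices for one peer.
validation_split <- function(y_idx, fraction, seed) {
  n <- length(y_idx)
  if (fraction <= 0 || n < 2) return(integer(0))
  with_seed(seed, {
    counts <- table(y_idx)
    if (any(counts < 2)) {
      warning("a class has fewer than 2 cells; using an unstratified validation split",
              call. = FALSE)
      return(sample.int(n, max(1L, floor(fraction * n))))
    }
    unlist(lapply(split(seq_len(n), y_idx), function(idx) {
      k <- floor(fraction * length(idx))
      if (k > 0) sample(idx, k) else integer(0)
    }), use.names = FALSE)
  })
}

# The shared engine behind fit_local() and run_swarm(): peers train privately
# in lockstep rounds and merge parameters at sync events. Peer RNG streams are
# derived from the peer *id*, so a pooled single-peer fit and a one-peer swarm
# consume identical randomness.
train_peers <- function(peers, hp, cfg, class_labels, feature_ids,
                        setting = "Swarm") {
  stopifnot(length(peers) >= 1)
  # canonical peer order: results depend only on the peer set, not list order
  peers <- peers[order(vapply(peers, `[[`, character(1), "peer_id"))]
  n_features <- length(feature_ids)
  init <- init_mlp(n_features, class_labels, hp, feature_ids = feature_ids)

  states <- lapply(peers, function(p) {
    if (nrow(p$x) == 0) stop("peer '", p$peer_id, "' has no cells", call. = FALSE)
    y_idx <- batch_class_indices(p$y, class_labels)
    val <- validation_split(y_idx, hp$validation_fraction,
                            derive_seed(hp$seed, "val", p$peer_id))
    tr <- setdiff(seq_len(nrow(p$x)), val)
    list(
      peer_id = p$peer_id,
      x = p$x, y = y_idx, train_idx = tr, val_idx = val,
      params = init$params, opt = init$opt,
      cw = if (identical(hp$class_weights, "balanced")) {
        freq <- tabulate(y_idx[tr], nbins = length(class_labels))
        ifelse(freq > 0, sum(freq) / (length(class_labels) * freq), 0)
      } else resolve_class_weights(hp$class_weights, class_labels, NULL),
      epoch = 0L, queue = list(),
      batches_per_epoch = ceiling(length(tr) / hp$batch_size),
      losses = numeric(0)
    )
  })

  next_batch <- function(st) {
    if (length(st$queue) == 0L) {
      st$epoch <- st$epoch + 1L
      perm <- with_seed(derive_seed(hp$seed, "shuffle", st$peer_id, st$epoch),
                        st$train_idx[sample.int(length(st$train_idx))])
      grp <- ceiling(seq_along(perm) / hp$batch_size)
      st$queue <- unname(split(perm, factor(grp, levels = unique(grp))))
    }
    st$batch <- st$queue[[1L]]
    st$queue <- st$queue[-1L]
    st
  }

  step_peer <- function(st, round) {
    idx <- st$batch
    X <- st$x[idx, , drop = FALSE]
    y <- st$y[idx]
    masks <- NULL
    if (hp$dropout > 0) {
      masks <- with_seed(derive_seed(hp$seed, "drop", st$peer_id, round), {
        lapply(hp$hidden_sizes, function(h) {
          matrix(stats::rbinom(length(idx) * h, 1L, 1 - hp$dropout) /
                   (1 - hp$dropout), length(idx), h)
        })
      })
    }
    sw <- if (is.null(st$cw)) NULL else st$cw[y]
    g <- mlp_loss_grads(st$params, X, y, sample_w = sw, drop_masks = masks)
    if (!is.finite(g$loss)) {
      stop(sprintf("non-finite loss on peer '%s' at round %d", st$peer_id, round),
           call. = FALSE)
    }
    upd <- adam_update(st$params, st$opt, g, hp)
    st$params <- upd$params
    st$opt <- upd$opt
    st$losses <- c(st$losses, g$loss)
    st
  }

  merge_weights <- vapply(states, function(st) {
    if (cfg$weighting == "dataset_size") length(st$train_idx) else 1
  }, numeric(1))

  do_merge <- function(states, round, kind) {
    pre <- vapply(states, function(st) param_checksum(st$params), numeric(1))
    merged <- weighted_average(lapply(states, `[[`, "params"), merge_weights)
    post <- param_checksum(merged)
    for (i in seq_along(states)) states[[i]]$params <- merged
    list(states = states,
         event = data.frame(
           step_index = round, kind = kind,
           participating_peers = paste(vapply(states, `[[`, character(1), "peer_id"),
                                       collapse = ","),
           pre_checksums = paste(sprintf("%.10g", pre), collapse = ","),
           post_checksum = post, stringsAsFactors = FALSE))
  }

  total_rounds <- hp$epochs * max(vapply(states, `[[`, numeric(1), "batches_per_epoch"))
  sync <- cfg$sync_interval_batches
  events <- list()
  for (r in seq_len(total_rounds)) {
    for (i in seq_along(states)) {
      states[[i]] <- next_batch(states[[i]])
      states[[i]] <- step_peer(states[[i]], r)
    }
    if (is.finite(sync) && r %% sync == 0) {
      m <- do_merge(states, r, "sync")
      states <- m$states
      events[[length(events) + 1L]] <- m$event
    }
  }
  m <- do_merge(states, total_rounds, "final")
  states <- m$states
  events[[length(events) + 1L]] <- m$event

  history <- lapply(states, function(st) {
    val <- NULL
    if (length(st$val_idx) > 0) {
      P <- mlp_forward(st$params, st$x[st$val_idx, , drop = FALSE])
      yv <- st$y[st$val_idx]
      val <- list(
        loss = -mean(log(pmax(P[cbind(seq_along(yv), yv)], 1e-12))),
        accuracy = mean(max.col(P, ties.method = "first") == yv)
      )
    }
    list(peer_id = st$peer_id, train_losses = st$losses,
         n_train = length(st$train_idx), n_val = length(st$val_idx),
         epochs_consumed = st$epoch, validation = val)
  })

  structure(list(
    params = m$states[[1L]]$params,
    hp = hp, cfg = cfg, setting = setting,
    class_labels = class_labels, feature_ids = feature_ids,
    sync_log = do.call(rbind, events),
    history = history,
    total_rounds = total_rounds
  ), class = "swarm_mlp")
}

#' Simulate swarm training over a set of peers
#'
#' All peers start from the same seeded initialization and train privately in
#' lockstep rounds, each consuming one minibatch of its own seeded shuffle
#' per round (peers with fewer batches per epoch wrap to a new local epoch).
#' After every `cfg$sync_interval_batches` rounds the peers' weights and
#' biases are replaced by their weighted average (optimizer moments are kept
#' per peer). The total number of rounds is
#' `epochs * max_i ceiling(n_i / batch_size)` and a final merge is always
#' performed, yielding one unified model.
#'
#' @param peers List of peers, each a list with `peer_id`, `x` (cells x
#'   features matrix in the shared feature order) and `y` (labels).
#' @param cfg A [swarm_config()].
#' @param hp An [mlp_hyperparams()].
#' @param class_labels Shared class vocabulary; defaults to the sorted union
#'   of peer labels.
#' @return A `swarm_mlp` fit whose `sync_log` records every merge event.
#' @seealso [fit_local()] for the pooled-data (local learning) counterpart.
#' @export
run_swarm <- function(peers, cfg = swarm_config(), hp = mlp_hyperparams(),
                      class_labels = NULL) {
  if (length(peers) < 1) stop("need at least one peer", call. = FALSE)
  feats <- lapply(peers, function(p) colnames(p$x))
  if (length(peers) > 1 &&
      !all(vapply(feats[-1], identical, logical(1), feats[[1]]))) {
    stop("peers disagree on the shared feature space", call. = FALSE)
  }
  if (is.null(class_labels)) {
    class_labels <- sort(unique(unlist(lapply(peers, function(p) as.character(p$y)))))
  }
  train_peers(peers, hp, cfg, class_labels, feats[[1L]] %||%
                paste0("F", seq_len(ncol(peers[[1L]]$x))),
              setting = "Swarm")
}

#' Train a pooled (local learning) classifier
#'
#' Concatenates the projected training studies, carves a stratified
#' validation split (monitoring only), and trains the classifier for the
#' fixed number of epochs. Implemented as a single-peer run of the swarm
#' engine, so a one-peer swarm and a one-study local fit are bitwise
#' identical under the same seed. Note the bookkeeping asymmetry versus the
#' swarm setting: a pooled fit consumes `sum(n_i)` cells per epoch, whereas
#' each swarm peer consumes its own `n_i` per local epoch.
#'
#' @param train List of preprocessed studies, each a list with `study_id`
#'   (or `peer_id`), a normalized matrix `norm` (or `x`), and labels `y`.
#'   Typically built by [prepare_design_data()].
#' @param fs Optional [union_feature_space()]; when given, each study's
#'   matrix is projected onto it first.
#' @param hp An [mlp_hyperparams()].
#' @param class_labels Class vocabulary; defaults to the sorted union of the
#'   training labels.
#' @return A `swarm_mlp` fit.
#' @export
fit_local <- function(train, fs = NULL, hp = mlp_hyperparams(),
                      class_labels = NULL) {
  if (length(train) < 1) stop("need at least one training study", call. = FALSE)
  ids0 <- vapply(train, function(tr) tr$peer_id %||% tr$study_id, character(1))
  train <- train[order(ids0)]  # pooled data order independent of input order
  mats <- lapply(train, function(tr) {
    x <- tr$x %||% tr$norm
    if (!is.null(fs)) x <- project_to_features(x, fs) else x <- as.matrix(x)
    x
  })
  ids <- vapply(train, function(tr) tr$peer_id %||% tr$study_id, character(1))
  x <- do.call(rbind, mats)
  y <- unlist(lapply(train, `[[`, "y"), use.names = FALSE)
  if (is.null(class_labels)) class_labels <- sort(unique(as.character(y)))
  pooled <- list(list(peer_id = paste(ids, collapse = "+"), x = x, y = y))
  fit <- train_peers(pooled, hp, swarm_config(sync_interval_batches = Inf),
                     class_labels,
                     colnames(x) %||% paste0("F", seq_len(ncol(x))),
                     setting = sprintf("Local_%d", length(train)))
  fit
}

#' @rdname fit_local
#' @details `run_local_setting()` is a thin alias of [fit_local()] so that
#'   local and swarm experiment settings can be named uniformly.
#' @export
run_local_setting <- function(train, fs = NULL, hp = mlp_hyperparams(),
                              class_labels = NULL) {
  fit_local(train, fs, hp, class_labels)
}
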