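#' @export
print.swarm_mlp <- function(x, ...) {
  dims <- c(length(x$feature_ids), x$hp$hidden_sizes, length(x$class_labels))
  cat(sprintf("<swarm_mlp> %s setting\n", x$setting))
  cat(sprintf("  architecture: %s (%s), %d classes\n",
              paste(dims, collapse = " -> "), x$hp$activation,
              length(x$class_labels)))
  cat(sprintf("  peers: %s\n",
              paste(vapply(x$history, `[[`, character(1), "peer_id"),
                    collapse = ", ")))
  cat(sprintf("  training rounds: %d; sync events: %d\n",
              x$total_rounds, nrow(x$sync_log)))
  invisible(x)
}

#' @export
summary.swarm_mlp <- function(object, ...) {
  cat(sprintf("Swarm/local MLP classifier (%s)\n", object$setting))
  print(object)
  for (h in object$history) {
    line <- sprintf("  peer %s: %d train cells, %d local epochs, final batch loss %.4f",
                    h$peer_id, h$n_train, h$epochs_consumed,
                    utils::tail(h$train_losses, 1))
    if (!is.null(h$validation)) {
      line <- sprintf("%s; validation loss %.4f, accuracy %.3f",
                      line, h$validation$loss, h$validation$accuracy)
    }
    cat(line, "\n")
  }
  invisible(object)
}

#' @export
coef.swarm_mlp <- function(object, ...) {
  list(W = object$params$W, b = object$params$b)
}

#' Predict cell-type labels or class probabilities
#'
#' @param object A `swarm_mlp` fit.
#' @param newdata Cells x features matrix. If it carries column names they
#'   must contain the model's feature ids (columns are reordered as needed);
#'   use [project_to_features()] to map a study onto the model's feature
#'   space.
#' @param type `"class"` for labels (argmax, ties broken by lowest class
#'   index) or `"prob"` for the probability matrix.
#' @param ... Unused.
#' @return A character vector of labels or a probability matrix.
#' @export
predict.swarm_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && !is.null(object$feature_ids) &&
      !identical(colnames(X), object$feature_ids)) {
    idx <- match(object$feature_ids, colnames(X))
    if (anyNA(idx)) {
      stop("newdata lacks model features: ",
           paste(utils::head(object$feature_ids[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    X <- X[, idx, drop = FALSE]
  }
  P <- mlp_forward(object$params, X)
  if (type == "prob") return(P)
  object$class_labels[max.col(P, ties.method = "first")]
}

#' Plot training loss trajectories
#'
#' One line per peer, minibatch cross-entropy against training round.
#'
#' @param x A `swarm_mlp` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.swarm_mlp <- function(x, ...) {
  losses <- lapply(x$history, `[[`, "train_losses")
  ylim <- range(unlist(losses))
  graphics::plot(NA, xlim = c(1, max(lengths(losses))), ylim = ylim,
                 xlab = "training round", ylab = "minibatch cross-entropy",
                 main = sprintf("%s training", x$setting), ...)
  for (i in seq_along(losses)) {
    graphics::lines(seq_along(losses[[i]]), losses[[i]], col = i)
  }
  graphics::legend("topright",
                   legend = vapply(x$history, `[[`, character(1), "peer_id"),
                   col = seq_along(losses), lty = 1, bty = "n")
  invisible(x)
}
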