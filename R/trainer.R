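# Training and scoring: minibatch fitting of a built network, the
# proxy-fitness protocol (few epochs, each on a fresh small sample of the
# training windows), full training, and the class-support-weighted F1.

# windowed_dataset tensor (N x 1 x w x C) -> (N x w x C) array
wd_array <- function(wd) {
  X <- wd$tensor
  dim(X) <- dim(X)[c(1, 3, 4)]
  X
}

#' Class-support-weighted F1 score
#'
#' `F1 = 2 * sum_c (n_c / N) * precision_c * recall_c /
#' (precision_c + recall_c)`, where `n_c / N` is the proportion of samples
#' whose true class is `c`. A class with `precision + recall = 0`
#' contributes 0.
#'
#' @param true_labels,predicted_labels equal-length integer class vectors.
#' @return an object of class `eval_score`: list with `f1`, `per_class`
#'   (data frame `class`, `precision`, `recall`, `support`) and `n`.
#' @export
weighted_f1 <- function(true_labels, predicted_labels) {
  gn_assert(length(true_labels) == length(predicted_labels),
            "label vectors must have equal length")
  gn_assert(length(true_labels) >= 1, "need at least one sample")
  classes <- sort(unique(c(true_labels, predicted_labels)))
  N <- length(true_labels)
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    data.frame(class = cl,
               precision = if (tp + fp > 0) tp / (tp + fp) else 0,
               recall = if (tp + fn > 0) tp / (tp + fn) else 0,
               support = tp + fn)
  }))
  pr <- per$precision + per$recall
  contrib <- ifelse(pr > 0, per$precision * per$recall / pr, 0)
  f1 <- 2 * sum(per$support / N * contrib)
  structure(list(f1 = f1, per_class = per, n = N), class = "eval_score")
}

#' @export
print.eval_score <- function(x, ...) {
  cat("<eval_score> weighted F1 = ", format(x$f1, digits = 4), " over ",
      x$n, " samples, ", nrow(x$per_class), " classes\n", sep = "")
  invisible(x)
}

# one or more epochs of minibatch SGD-family training; uses the caller's
# RNG stream for shuffling, sampling and dropout
fit_epochs <- function(model, X, y, epochs, batch_size, opt,
                       sample_fraction = 1) {
  N <- dim(X)[[1]]
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- if (sample_fraction < 1) {
      # fresh uniform sample each epoch
      sample.int(N, max(1L, round(sample_fraction * N)))
    } else seq_len(N)
    idx <- idx[sample.int(length(idx))]
    tot <- 0; nb <- 0L
    for (b0 in seq(1L, length(idx), by = batch_size)) {
      bi <- idx[b0:min(b0 + batch_size - 1L, length(idx))]
      Xb <- X[bi, , , drop = FALSE]
      fw <- model_forward(model, Xb, train = TRUE)
      sx <- softmax_xent(fw$logits, y[bi])
      grads <- model_backward(model, fw$caches, sx$dlogits)
      model <- apply_gradients(model, grads, opt)
      tot <- tot + sx$loss; nb <- nb + 1L
    }
    losses[[ep]] <- tot / max(nb, 1L)
  }
  list(model = model, losses = losses)
}

#' Predict window classes with a built/trained network
#'
#' @param object a `gn_model`.
#' @param newdata a `windowed_dataset` or an `N x w x C` array.
#' @param chunk forward-pass chunk size (memory guard).
#' @param ... unused.
#' @return list with `labels` (0-based argmax classes) and `probs`
#'   (`N x n_classes` softmax matrix, rows summing to 1).
#' @export
predict.gn_model <- function(object, newdata, chunk = 1024L, ...) {
  X <- if (inherits(newdata, "windowed_dataset")) wd_array(newdata) else newdata
  gn_assert(length(dim(X)) == 3, "newdata must be an N x w x C array")
  gn_assert(dim(X)[[2]] == object$spec$window_size &&
              dim(X)[[3]] == object$n_channels,
            sprintf("window shape %d x %d does not match model input %d x %d",
                    dim(X)[[2]], dim(X)[[3]], object$spec$window_size,
                    object$n_channels))
  N <- dim(X)[[1]]
  probs <- matrix(numeric(0), 0, object$n_classes)
  if (N > 0) {
    out <- lapply(seq(1L, N, by = chunk), function(b0) {
      bi <- b0:min(b0 + chunk - 1L, N)
      softmax_rows(model_forward(object, X[bi, , , drop = FALSE],
                                 train = FALSE)$logits)
    })
    probs <- do.call(rbind, out)
  }
  labels <- if (N > 0) max.col(probs, ties.method = "first") - 1L else integer(0)
  list(labels = labels, probs = probs)
}

#' Proxy fitness of a topology
#'
#' The architecture-search fitness estimate: build the network, train it
#' for `epochs` epochs, each on a fresh uniformly-drawn `sample_fraction`
#' of the training windows, and return the weighted F1 on the validation
#' windows. Infeasible or failing topologies score 0.
#'
#' @param spec a [topology_spec()]; the datasets must be windowed with the
#'   spec's own `w` and `wstep`.
#' @param train_wd,val_wd `windowed_dataset`s.
#' @param epochs training epochs (default 5).
#' @param sample_fraction fraction of training windows drawn per epoch
#'   (default 0.05).
#' @param n_classes number of classes; default inferred from the labels.
#' @param seed optional seed (training is stochastic).
#' @param param_ceiling passed to [build_model()].
#' @return fitness in `[0, 1]`.
#' @export
proxy_fitness <- function(spec, train_wd, val_wd, epochs = 5L,
                          sample_fraction = 0.05, n_classes = NULL,
                          seed = NULL, param_ceiling = 5e6) {
  if (is.null(n_classes))
    n_classes <- max(train_wd$labels, val_wd$labels) + 1L
  res <- tryCatch({
    with_seed(seed, {
      model <- build_model(spec, dim(train_wd$tensor)[[4]], n_classes,
                           param_ceiling = param_ceiling)
      opt <- make_optimizer(spec$optimizer, spec$learning_rate)
      fit <- fit_epochs(model, wd_array(train_wd), train_wd$labels, epochs,
                        spec$batch_size, opt, sample_fraction)
      pr <- predict(fit$model, val_wd)
      weighted_f1(val_wd$labels, pr$labels)$f1
    })
  },
  gennas_infeasible = function(e) {
    message("infeasible topology scored 0: ", conditionMessage(e))
    0
  },
  error = function(e) {
    warning("fitness evaluation failed, scored 0: ", conditionMessage(e))
    0
  })
  if (!is.finite(res)) 0 else res
}

#' Fully train a topology
#'
#' Trains on the complete training set for `epochs` epochs (default 30)
#' and returns the trained network with its per-epoch loss log.
#'
#' @inheritParams proxy_fitness
#' @param epochs training epochs.
#' @return a `gn_model` with a `training_log` element (per-epoch mean
#'   minibatch cross-entropy).
#' @export
full_train <- function(spec, train_wd, epochs = 30L, n_classes = NULL,
                       seed = NULL, param_ceiling = 5e6) {
  if (is.null(n_classes)) n_classes <- max(train_wd$labels) + 1L
  with_seed(seed, {
    model <- build_model(spec, dim(train_wd$tensor)[[4]], n_classes,
                         param_ceiling = param_ceiling)
    if (epochs > 0) {
      opt <- make_optimizer(spec$optimizer, spec$learning_rate)
      fit <- fit_epochs(model, wd_array(train_wd), train_wd$labels, epochs,
                        spec$batch_size, opt)
      model <- fit$model
      model$training_log <- fit$losses
    } else {
      model$training_log <- numeric(0)
    }
    model
  })
}
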