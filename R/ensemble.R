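# Committees of trained networks: majority voting with a deterministic
# tie-break chain, incremental committee evaluation, and normalized
# confusion matrices.

#' Build a committee of trained models
#'
#' Members must share window size and step so they vote on aligned windows
#' (batch size is a training-only property and may differ).
#'
#' @param models list of `gn_model`s ordered by rank (best first).
#' @return an object of class `committee`.
#' @export
committee <- function(models) {
  gn_assert(length(models) >= 1, "a committee needs at least one member")
  gn_assert(all(vapply(models, inherits, logical(1), "gn_model")),
            "members must be gn_model objects")
  w <- vapply(models, function(m) m$spec$window_size, integer(1))
  ws <- vapply(models, function(m) m$spec$window_step, integer(1))
  nc <- vapply(models, function(m) m$n_classes, integer(1))
  gn_assert(length(unique(w)) == 1 && length(unique(ws)) == 1,
            "committee members must share window size and step")
  gn_assert(length(unique(nc)) == 1,
            "committee members must share the class map")
  structure(list(models = models), class = "committee")
}

#' Majority vote over member predictions
#'
#' Per window, the modal label wins. Ties are broken by the highest summed
#' probability among the tied classes, then by the lowest class index; the
#' chain is deterministic.
#'
#' @param per_model_labels list (one element per member) of 0-based label
#'   vectors over the same windows.
#' @param per_model_probs list of matching `N x n_classes` probability
#'   matrices (used only for tie-breaking; may be `NULL` to fall back to
#'   lowest-index tie-breaks).
#' @return integer vector of committee labels.
#' @export
majority_vote <- function(per_model_labels, per_model_probs = NULL) {
  M <- length(per_model_labels)
  gn_assert(M >= 1, "need at least one member")
  N <- length(per_model_labels[[1]])
  gn_assert(all(lengths(per_model_labels) == N),
            "members predicted different window sets")
  if (N == 0) return(integer(0))
  L <- do.call(cbind, per_model_labels)          # N x M
  n_classes <- if (!is.null(per_model_probs))
    ncol(per_model_probs[[1]]) else max(L) + 1L
  votes <- matrix(0L, N, n_classes)
  for (m in seq_len(M))
    votes[cbind(seq_len(N), L[, m] + 1L)] <-
      votes[cbind(seq_len(N), L[, m] + 1L)] + 1L
  psum <- if (!is.null(per_model_probs)) Reduce(`+`, per_model_probs)
          else matrix(0, N, n_classes)
  vapply(seq_len(N), function(i) {
    v <- votes[i, ]
    tied <- which(v == max(v))
    if (length(tied) > 1) {
      p <- psum[i, tied]
      tied <- tied[p == max(p)]
    }
    tied[[1]] - 1L       # lowest class index among remaining ties
  }, integer(1))
}

#' Predict with a committee
#'
#' @param object a [committee()].
#' @param newdata a `windowed_dataset` (or `N x w x C` array) extracted
#'   with the members' shared `w`/`wstep`.
#' @param ... unused.
#' @return list with `labels` (majority-vote classes), `member_labels` and
#'   `member_probs`.
#' @export
predict.committee <- function(object, newdata, ...) {
  preds <- lapply(object$models, predict, newdata = newdata)
  labels <- majority_vote(lapply(preds, `[[`, "labels"),
                          lapply(preds, `[[`, "probs"))
  list(labels = labels,
       member_labels = lapply(preds, `[[`, "labels"),
       member_probs = lapply(preds, `[[`, "probs"))
}

#' Evaluate incremental committees
#'
#' For k = 1..K, forms the committee of the first k models (hall-of-fame
#' order) and reports its majority-vote weighted F1 next to the mean of the
#' members' individual F1 scores.
#'
#' @param models list of `gn_model`s ordered by hall-of-fame rank.
#' @param test_wd a `windowed_dataset` of evaluation windows.
#' @param true_labels 0-based true class per window (default: the dataset's
#'   own labels).
#' @return a data frame with columns `k`, `committee_f1`, `mean_member_f1`.
#' @export
incremental_committee_eval <- function(models, test_wd,
                                       true_labels = test_wd$labels) {
  gn_assert(length(models) >= 1, "need at least one model")
  preds <- lapply(models, predict, newdata = test_wd)
  incremental_from_preds(preds, true_labels)
}

#' Align windows across models with different window setups
#'
#' Committee members must vote on the same instants. When hall-of-fame
#' models use different `w`/`wstep`, windows are re-extracted per model
#' from the evaluation recording and aligned by their end timestep: only
#' instants where every model has a window ending are kept. Under the
#' last-timestep label rule all aligned windows share one true label.
#'
#' @param models list of `gn_model`s.
#' @param frame a preprocessed (filtered, interpolated, normalized)
#'   [sensor_frame()].
#' @param label_rule window label rule (see [slide_windows()]).
#' @return list with `datasets` (one `windowed_dataset` per model, equal
#'   window counts, aligned) and `labels` (shared true labels).
#' @export
align_windows <- function(models, frame, label_rule = "last") {
  wds <- lapply(models, function(m)
    slide_windows(frame, m$spec$window_size, m$spec$window_step,
                  label_rule = label_rule))
  ends <- lapply(wds, function(wd) wd$starts + wd$w)
  common <- Reduce(intersect, ends)
  if (length(common) == 0)
    gn_stop("no common window end-timesteps across committee members",
            "gennas_validation_error")
  common <- sort(common)
  datasets <- lapply(seq_along(wds), function(i)
    subset_windows(wds[[i]], match(common, ends[[i]])))
  list(datasets = datasets, labels = datasets[[1]]$labels)
}

# incremental committee table from precomputed per-model predictions
incremental_from_preds <- function(preds, true_labels) {
  member_f1 <- vapply(preds, function(p)
    weighted_f1(true_labels, p$labels)$f1, numeric(1))
  do.call(rbind, lapply(seq_along(preds), function(k) {
    lab <- majority_vote(lapply(preds[seq_len(k)], `[[`, "labels"),
                         lapply(preds[seq_len(k)], `[[`, "probs"))
    data.frame(k = k,
               committee_f1 = weighted_f1(true_labels, lab)$f1,
               mean_member_f1 = mean(member_f1[seq_len(k)]))
  }))
}

#' Confusion matrix with a row-normalized view
#'
#' @param true_labels,predicted_labels 0-based class vectors in
#'   `[0, n_classes)`.
#' @param n_classes number of classes.
#' @return an object of class `confusion_matrix`: list with `counts`
#'   (`n_classes x n_classes`, rows = true class) and `normalized`
#'   (rows divided by their sums; zero-support rows stay 0).
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes) {
  gn_assert(length(true_labels) == length(predicted_labels),
            "label vectors must have equal length")
  ok <- function(x) all(x >= 0 & x < n_classes)
  if (!ok(true_labels) || !ok(predicted_labels))
    gn_stop("labels out of [0, n_classes)", "gennas_argument_error")
  counts <- matrix(0L, n_classes, n_classes,
                   dimnames = list(true = 0:(n_classes - 1),
                                   predicted = 0:(n_classes - 1)))
  for (i in seq_along(true_labels))
    counts[true_labels[[i]] + 1L, predicted_labels[[i]] + 1L] <-
      counts[true_labels[[i]] + 1L, predicted_labels[[i]] + 1L] + 1L
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs > 0, rs, 1)
  structure(list(counts = counts, normalized = normalized),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> ", nrow(x$counts), " classes, ",
      sum(x$counts), " samples\n", sep = "")
  print(round(x$normalized, 2))
  invisible(x)
}

#' Weighted F1 recomputed from a confusion matrix
#'
#' @param cm a [confusion_matrix()].
#' @return a number; equals [weighted_f1()] on the raw label vectors.
#' @export
f1_from_confusion <- function(cm) {
  counts <- cm$counts
  N <- sum(counts)
  tp <- diag(counts)
  support <- rowSums(counts)
  predicted <- colSums(counts)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  pr <- precision + recall
  contrib <- ifelse(pr > 0, precision * recall / pr, 0)
  2 * sum(support / N * contrib)
}
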