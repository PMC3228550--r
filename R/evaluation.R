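# Confusion metrics, vote-sweep ROC/AUC, per-structure leave-one-out
# cross-validation and the epitope-vs-non-epitope distance statistics.

#' Confusion-matrix metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy, precision,
#' recall and the F-measure `2*precision*recall/(precision+recall)`. A metric
#' whose denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return Named list: SN, SP, ACC, precision, recall, F.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sn <- div(tp, tp + fn)
  sp <- div(tn, tn + fp)
  acc <- div(tp + tn, tp + tn + fp + fn)
  prec <- div(tp, tp + fp)
  rec <- sn
  f <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(SN = sn, SP = sp, ACC = acc, precision = prec, recall = rec, F = f)
}

#' ROC curve and AUC from ensemble votes
#'
#' Sweeps the vote cutoff over `0, 1, ..., n_sub + 1` (the endpoints give the
#' all-positive and all-negative corners, so the curve spans (0,0)-(1,1)),
#' records one (sensitivity, 1 - specificity) point per cutoff, and
#' integrates by the trapezoidal rule. Equivalent to the rank (Mann-Whitney)
#' statistic with half credit for ties.
#'
#' @param votes Per-instance vote counts (or any integer-valued scores in
#'   `[0, n_sub]`).
#' @param labels Binary 0/1 labels; both classes must be present.
#' @param n_sub Number of sub-classifiers (maximum vote count).
#' @return List with `points` (data frame: cutoff, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(votes, labels, n_sub = max(votes)) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("ROC requires at least one positive and one negative label")
  stopifnot(length(votes) == length(labels))
  cutoffs <- seq(0, n_sub + 1)
  pts <- t(vapply(cutoffs, function(co) {
    pred <- as.integer(votes >= co)
    c(fpr = sum(pred == 1 & labels == 0) / sum(labels == 0),
      tpr = sum(pred == 1 & labels == 1) / sum(labels == 1))
  }, numeric(2)))
  pts <- data.frame(cutoff = cutoffs, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  ord <- order(pts$fpr, pts$tpr)
  auc <- sum(diff(pts$fpr[ord]) * (utils::head(pts$tpr[ord], -1) +
                                     utils::tail(pts$tpr[ord], -1)) / 2)
  list(points = pts, auc = auc)
}

# AUC for real-valued scores (pooled folds where n_sub differs): threshold
# sweep over the observed score values plus the two degenerate endpoints.
score_auc <- function(scores, labels) {
  thr <- sort(unique(scores))
  labels <- as.integer(labels)
  pts <- t(vapply(c(-Inf, thr, Inf), function(co) {
    pred <- as.integer(scores >= co)
    c(sum(pred == 1 & labels == 0) / sum(labels == 0),
      sum(pred == 1 & labels == 1) / sum(labels == 1))
  }, numeric(2)))
  ord <- order(pts[, 1], pts[, 2])
  sum(diff(pts[ord, 1]) * (utils::head(pts[ord, 2], -1) +
                             utils::tail(pts[ord, 2], -1)) / 2)
}

#' Per-structure leave-one-out cross-validation
#'
#' For a dataset of `m` labelled structures, each fold trains the balanced
#' ensemble on the pooled surface-residue instances of `m - 1` structures
#' and predicts the held-out structure, so no residue of a test structure
#' ever appears in training. Reports per-structure confusion metrics at the
#' default half-votes cutoff, per-structure AUC by vote sweep, the unweighted
#' mean of per-structure AUCs (the primary summary), and a pooled-residue
#' AUC over the vote fractions for transparency.
#'
#' @param dataset List of labelled `epitope_features` objects (each with a
#'   non-NULL `y`); at least two structures.
#' @param n_sub,ntree,mtry,cutoff Passed to [epitope_rf()] per fold (with
#'   `n_sub = NULL` each fold sizes its own ensemble from its imbalance).
#' @param seed Master seed; per-fold seeds are derived deterministically.
#' @return Object of class `"epitope_cv"`: `per_structure` data frame,
#'   `mean_auc`, `pooled_auc`, `mean_metrics`, per-fold predictions.
#' @export
epitope_loocv <- function(dataset, n_sub = NULL, ntree = 10, mtry = NULL,
                          seed = 1, cutoff = NULL) {
  stopifnot(length(dataset) >= 2)
  for (d in dataset)
    if (!inherits(d, "epitope_features") || is.null(d$y))
      stop("every dataset element must be a labelled epitope_features object")
  ids <- vapply(dataset, function(d) d$structure_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate structure ids in dataset")
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max, length(dataset))

  rows <- list(); preds <- list()
  pooled_scores <- numeric(0); pooled_labels <- integer(0)
  for (i in seq_along(dataset)) {
    train <- dataset[-i]; test <- dataset[[i]]
    xtr <- do.call(rbind, lapply(train, `[[`, "x"))
    ytr <- unlist(lapply(train, `[[`, "y"))
    fit <- epitope_rf(xtr, ytr, n_sub = n_sub, ntree = ntree, mtry = mtry,
                      seed = fold_seeds[i], cutoff = cutoff)
    votes <- predict(fit, test$x, type = "votes")
    call <- decide(votes, fit$n_sub, fit$cutoff)
    tp <- sum(call == 1 & test$y == 1); tn <- sum(call == 0 & test$y == 0)
    fp <- sum(call == 1 & test$y == 0); fn <- sum(call == 0 & test$y == 1)
    met <- confusion_metrics(tp, tn, fp, fn)
    auc <- if (length(unique(test$y)) < 2) {
      warning("structure '", test$structure_id,
              "' has single-class labels; skipped for AUC")
      NA_real_
    } else roc_auc(votes, test$y, fit$n_sub)$auc
    rows[[i]] <- data.frame(structure = test$structure_id,
                            n = length(test$y), n_pos = sum(test$y),
                            TP = tp, TN = tn, FP = fp, FN = fn,
                            SN = met$SN, SP = met$SP, ACC = met$ACC,
                            precision = met$precision, F = met$F, AUC = auc,
                            stringsAsFactors = FALSE)
    preds[[i]] <- data.frame(structure = test$structure_id, res_uid = test$ids,
                             votes = votes, n_sub = fit$n_sub,
                             score = votes / fit$n_sub, call = call,
                             label = test$y, stringsAsFactors = FALSE)
    pooled_scores <- c(pooled_scores, votes / fit$n_sub)
    pooled_labels <- c(pooled_labels, test$y)
  }
  per <- do.call(rbind, rows)
  mean_metrics <- colMeans(per[, c("SN", "SP", "ACC", "precision", "F")],
                           na.rm = TRUE)
  out <- list(per_structure = per,
              mean_auc = mean(per$AUC, na.rm = TRUE),
              pooled_auc = score_auc(pooled_scores, pooled_labels),
              mean_metrics = as.list(mean_metrics),
              predictions = do.call(rbind, preds),
              seed = seed)
  class(out) <- "epitope_cv"
  out
}

#' @export
print.epitope_cv <- function(x, ...) {
  cat("Per-structure leave-one-out cross-validation (epitope_cv)\n")
  cat(sprintf("  %d structures, %d surface residues (%d epitope)\n",
              nrow(x$per_structure), sum(x$per_structure$n),
              sum(x$per_structure$n_pos)))
  cat(sprintf("  mean AUC %.3f (pooled %.3f)\n", x$mean_auc, x$pooled_auc))
  cat(sprintf("  at the half-votes cutoff: SN %.3f  SP %.3f  ACC %.3f  F %.3f\n",
              x$mean_metrics$SN, x$mean_metrics$SP, x$mean_metrics$ACC,
              x$mean_metrics$F))
  invisible(x)
}

#' @export
summary.epitope_cv <- function(object, ...) {
  print(object)
  cat("\nper-structure results:\n")
  print(object$per_structure, digits = 3, row.names = FALSE)
  invisible(object)
}

#' Pooled ROC curve of a cross-validation run
#'
#' @param x An `epitope_cv` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.epitope_cv <- function(x, ...) {
  sc <- x$predictions$score; lb <- x$predictions$label
  thr <- c(-Inf, sort(unique(sc)), Inf)
  pts <- t(vapply(thr, function(co) {
    pred <- as.integer(sc >= co)
    c(sum(pred == 1 & lb == 0) / sum(lb == 0),
      sum(pred == 1 & lb == 1) / sum(lb == 1))
  }, numeric(2)))
  ord <- order(pts[, 1], pts[, 2])
  graphics::plot(pts[ord, 1], pts[ord, 2], type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("pooled ROC (AUC %.3f, mean per-structure %.3f)",
                                x$pooled_auc, x$mean_auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# Paired t-test from its closed form; sd 0 with mean 0 is the exact null
# (t = 0, p = 1), sd 0 with nonzero mean is reported as p = 0.
paired_t_test <- function(x, y) {
  d <- x - y
  m <- length(d)
  if (m < 2) return(list(t = NA_real_, p = NA_real_, df = m - 1))
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = m - 1))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = m - 1))
  }
  t <- mean(d) / (s / sqrt(m))
  list(t = t, p = 2 * stats::pt(-abs(t), df = m - 1), df = m - 1)
}

#' Distance statistics of epitope versus non-epitope patches
#'
#' Computes the two distance summaries that motivate the ARD feature:
#' (1) the mean adjacent-residue distance per central amino-acid type,
#' compared between epitope and non-epitope patches with a paired t-test
#' across the types present in both classes; and (2) the mean distance of
#' the kth nearest neighbour (k = 1..n-1) per class, compared with a paired
#' t-test across k.
#'
#' @param patches Named list of `residue_patch` objects (uniform size),
#'   keyed by central residue uid.
#' @param labels Named 0/1 vector (or data frame with res_uid/label) giving
#'   each patch centre's class.
#' @param aa Named one-letter types of the central residues; taken from
#'   `labels` when it is a data frame carrying an `aa` column.
#' @return Object of class `"distance_profile"`: `by_type` and `by_k` data
#'   frames, the paired t statistics/p-values for both pairings, class
#'   counts and any types excluded because one class was absent.
#' @export
patch_distance_statistics <- function(patches, labels, aa = NULL) {
  if (is.data.frame(labels)) {
    if (!is.null(labels$aa) && is.null(aa))
      aa <- structure(labels$aa, names = labels$res_uid)
    labels <- structure(labels$label, names = labels$res_uid)
  }
  uids <- names(patches)
  lab <- labels[uids]
  if (anyNA(lab)) stop("labels missing for patch centre(s): ",
                       paste(uids[is.na(lab)], collapse = ", "))
  if (length(unique(lab)) < 2) stop("both classes must be present")
  sizes <- vapply(patches, function(p) p$n, numeric(1))
  if (length(unique(sizes)) != 1) stop("patch sizes are not uniform")
  k_max <- sizes[1] - 1
  dmat <- t(vapply(patches, function(p) p$adjacent$d, numeric(k_max)))
  mean_d <- rowMeans(dmat)

  by_k <- data.frame(
    k = seq_len(k_max),
    epitope = colMeans(dmat[lab == 1, , drop = FALSE]),
    non_epitope = colMeans(dmat[lab == 0, , drop = FALSE]))
  tk <- paired_t_test(by_k$epitope, by_k$non_epitope)

  by_type <- NULL; tt <- list(t = NA_real_, p = NA_real_, df = NA)
  excluded <- character(0)
  if (!is.null(aa)) {
    ca <- aa[uids]
    types <- sort(unique(ca))
    rows <- lapply(types, function(ty) {
      e <- mean_d[ca == ty & lab == 1]; ne <- mean_d[ca == ty & lab == 0]
      data.frame(aa = ty, n_epitope = length(e), n_non = length(ne),
                 epitope = if (length(e)) mean(e) else NA_real_,
                 non_epitope = if (length(ne)) mean(ne) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    by_type <- do.call(rbind, rows)
    paired <- by_type$n_epitope > 0 & by_type$n_non > 0
    excluded <- by_type$aa[!paired]
    if (sum(paired) >= 2)
      tt <- paired_t_test(by_type$epitope[paired], by_type$non_epitope[paired])
  }
  out <- list(by_type = by_type, by_k = by_k,
              t_type = tt$t, p_type = tt$p,
              t_k = tk$t, p_k = tk$p,
              n_pos = sum(lab == 1), n_neg = sum(lab == 0),
              excluded_types = excluded)
  class(out) <- "distance_profile"
  out
}

#' @export
print.distance_profile <- function(x, ...) {
  cat("Epitope vs non-epitope patch distance profile\n")
  cat(sprintf("  %d epitope / %d non-epitope patches\n", x$n_pos, x$n_neg))
  gap <- mean(x$by_k$epitope - x$by_k$non_epitope)
  cat(sprintf("  mean kth-neighbour distance gap %.3f A (paired t over k: t = %.2f, p = %.3g)\n",
              gap, x$t_k, x$p_k))
  if (!is.null(x$by_type) && !is.na(x$t_type))
    cat(sprintf("  paired t over central residue types: t = %.2f, p = %.3g (%d types excluded)\n",
                x$t_type, x$p_type, length(x$excluded_types)))
  invisible(x)
}
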