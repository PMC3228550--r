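# Balanced bootstrap-and-vote random-forest ensemble for the imbalanced
# epitope/non-epitope instance set.

#' Balanced training subsets by negative-class downsampling
#'
#' Draws `n_sub` subsets of the negative instance indices, each of size
#' `|A+|` sampled without replacement (within a subset; subsets are drawn
#' independently of each other so overlap across subsets is allowed), to be
#' combined with the full positive set.
#'
#' @param neg Indices (or ids) of negative instances.
#' @param pos Indices (or ids) of positive instances.
#' @param n_sub Number of subsets.
#' @param seed Integer seed; subsets are reproducible given the seed.
#' @return List of `n_sub` vectors of negative indices, each of length
#'   `length(pos)`. If there are fewer negatives than positives, a single
#'   unbalanced subset containing all negatives is returned with a warning.
#' @export
make_balanced_subsets <- function(neg, pos, n_sub, seed = 1) {
  stopifnot(length(pos) >= 1, n_sub >= 1)
  if (length(neg) < length(pos)) {
    warning("fewer negatives (", length(neg), ") than positives (",
            length(pos), "); using a single unbalanced subset")
    return(list(neg))
  }
  set.seed(seed)
  lapply(seq_len(n_sub), function(i) sample(neg, length(pos), replace = FALSE))
}

#' Fit a balanced bootstrap-and-vote random-forest ensemble
#'
#' The fitting function at the core of the package. Epitope data are heavily
#' imbalanced (far more non-epitope than epitope surface residues), so
#' instead of one classifier on the raw data, `n_sub` random forests are
#' each trained on the full positive set plus an equally sized random sample
#' of the negatives ([make_balanced_subsets()]). At prediction time each
#' sub-classifier casts a binary vote and an instance is called positive
#' when the votes reach the cutoff (half the sub-classifiers by default).
#'
#' @param x Numeric feature matrix (rows instances, e.g. stacked
#'   [structure_features()] rows).
#' @param y Binary labels (0/1 or logical), length `nrow(x)`.
#' @param n_sub Number of sub-classifiers; defaults to
#'   `round(|A-| / |A+|)` (at least 1) so the subsets jointly cover about
#'   the whole negative set.
#' @param ntree Trees per forest (10, matching the Weka-era random-forest
#'   default the method was developed with).
#' @param mtry Candidate features per split; default `floor(log2(p)) + 1`.
#' @param seed Master seed; per-subset sampling and forest seeds are spawned
#'   from it deterministically.
#' @param cutoff Vote cutoff for [predict.epitope_rf()]; default
#'   `n_sub / 2`, with ties at exactly half counted as positive.
#' @return Object of class `"epitope_rf"` with components `forests`,
#'   `subsets`, `n_sub`, `rf_params`, `cutoff`, `feature_names` and class
#'   counts; supports `print`, `summary` and `predict`.
#' @seealso [predict.epitope_rf()], [decide()], [epitope_loocv()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), 100); y <- as.integer(x[, 1] + rnorm(100, sd = .5) > 1)
#' fit <- epitope_rf(x, y, seed = 1)
#' fit
#' @export
epitope_rf <- function(x, y, n_sub = NULL, ntree = 10, mtry = NULL, seed = 1,
                       cutoff = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (length(pos) == 0 || length(neg) == 0)
    stop("training data must contain both classes")
  if (is.null(n_sub)) n_sub <- max(1L, as.integer(round(length(neg) / length(pos))))
  if (is.null(mtry)) mtry <- floor(log2(ncol(x))) + 1
  if (is.null(cutoff)) cutoff <- n_sub / 2
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))

  subsets <- make_balanced_subsets(neg, pos, n_sub, seed = seed)
  n_sub <- length(subsets)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_sub)
  forests <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    idx <- c(pos, subsets[[i]])
    yi <- factor(y[idx], levels = c(0L, 1L))
    if (length(unique(yi)) < 2)
      stop("degenerate single-class training subset ", i)
    set.seed(sub_seeds[i])
    forests[[i]] <- randomForest::randomForest(
      x = x[idx, , drop = FALSE], y = yi, ntree = ntree,
      mtry = min(mtry, ncol(x)))
  }
  out <- list(forests = forests, subsets = subsets, n_sub = n_sub,
              rf_params = list(ntree = ntree, mtry = mtry, seed = seed),
              cutoff = cutoff, feature_names = colnames(x),
              n_pos = length(pos), n_neg = length(neg),
              call = match.call())
  class(out) <- "epitope_rf"
  out
}

#' Vote counts and calls from an epitope ensemble
#'
#' Each sub-classifier casts one binary vote per instance; the vote count,
#' the vote fraction (`votes / n_sub`, a cutoff-agnostic score in [0, 1])
#' or the final call at the ensemble's cutoff can be returned.
#'
#' @param object An `epitope_rf` fit.
#' @param newdata Feature matrix with the training feature columns.
#' @param type `"votes"`, `"score"` or `"class"`.
#' @param cutoff Vote cutoff overriding the fit's default.
#' @param ... Unused.
#' @return Numeric (votes or score) or integer 0/1 (class) vector.
#' @export
predict.epitope_rf <- function(object, newdata,
                               type = c("votes", "score", "class"),
                               cutoff = NULL, ...) {
  type <- match.arg(type)
  # restored archives need the engine's S3 methods registered
  requireNamespace("randomForest", quietly = TRUE)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_names))
    stop("newdata has ", ncol(newdata), " features; the ensemble was ",
         "trained on ", length(object$feature_names))
  colnames(newdata) <- object$feature_names
  votes <- rowSums(vapply(object$forests, function(f)
    as.integer(as.character(predict(f, newdata))), numeric(nrow(newdata))))
  if (type == "votes") return(votes)
  if (type == "score") return(votes / object$n_sub)
  decide(votes, object$n_sub, if (is.null(cutoff)) object$cutoff else cutoff)
}

#' Final decision from vote counts
#'
#' Positive when at least `cutoff` of the `n_sub` sub-classifiers vote
#' positive; the default cutoff is half the sub-classifiers, with exactly
#' half counting as positive.
#'
#' @param votes Integer vote counts in `[0, n_sub]`.
#' @param n_sub Number of sub-classifiers.
#' @param cutoff Vote cutoff; default `n_sub / 2`.
#' @return Integer vector of 0/1 calls.
#' @export
decide <- function(votes, n_sub, cutoff = n_sub / 2) {
  stopifnot(all(votes >= 0), all(votes <= n_sub))
  as.integer(votes >= cutoff)
}

#' @export
print.epitope_rf <- function(x, ...) {
  cat("Balanced bootstrap-and-vote random-forest ensemble (epitope_rf)\n")
  cat(sprintf("  %d sub-classifiers x %d trees (mtry %d), vote cutoff %.1f\n",
              x$n_sub, x$rf_params$ntree, x$rf_params$mtry, x$cutoff))
  cat(sprintf("  trained on %d positives / %d negatives (%d features)\n",
              x$n_pos, x$n_neg, length(x$feature_names)))
  invisible(x)
}

#' @export
summary.epitope_rf <- function(object, ...) {
  imp <- Reduce(`+`, lapply(object$forests, randomForest::importance))
  imp <- imp[order(-imp[, 1]), , drop = FALSE]
  out <- list(fit = object, importance = imp)
  class(out) <- "summary.epitope_rf"
  out
}

#' @export
print.summary.epitope_rf <- function(x, ...) {
  print(x$fit)
  cat("top features by summed Gini importance:\n")
  print(utils::head(x$importance, 10))
  invisible(x)
}

#' Persist / restore an ensemble as a versioned archive
#'
#' The archive is a plain `.rds` of the fit plus format version; parameters,
#' seeds and subset indices are all inside the object, so a saved model
#' reproduces its predictions exactly.
#'
#' @param object An `epitope_rf` fit.
#' @param path Archive path.
#' @return `save_ensemble` returns the path; `load_ensemble` the fit.
#' @export
save_ensemble <- function(object, path) {
  stopifnot(inherits(object, "epitope_rf"))
  saveRDS(list(format = "epipatch-ensemble-1", fit = object), path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "epipatch-ensemble-1"))
    stop("not an epipatch ensemble archive: ", path)
  obj$fit
}
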