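# Model assessment: Matthews correlation from confusion counts, seeded
# stratified k-fold cross-validation with counts pooled across folds, and
# best-model selection over a method-kernel-hyperparameter grid.

#' Matthews correlation coefficient from confusion counts
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' binary-classification score in \[-1, 1\]. When any factor of the
#' denominator is zero the coefficient is defined as 0 (standard
#' convention).
#'
#' @param tp,fp,tn,fn Non-negative confusion counts, or `tp` may be a named
#'   list/vector with elements `tp`, `fp`, `tn`, `fn`.
#' @return Numeric scalar in \[-1, 1\].
#' @examples
#' mcc(tp = 3, fp = 1, tn = 4, fn = 2) # 10 / sqrt(600)
#' @export
mcc <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp) || (is.numeric(tp) && length(tp) == 4 && !is.null(names(tp)))) {
    c0 <- tp
    tp <- c0[["tp"]]
    fp <- c0[["fp"]]
    tn <- c0[["tn"]]
    fn <- c0[["fn"]]
  }
  # double precision: the denominator product overflows 32-bit integers
  tp <- as.numeric(unname(tp))
  fp <- as.numeric(unname(fp))
  tn <- as.numeric(unname(tn))
  fn <- as.numeric(unname(fn))
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(denom)
}

confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  c(
    tp = sum(truth & predicted), fp = sum(!truth & predicted),
    tn = sum(!truth & !predicted), fn = sum(truth & !predicted)
  )
}

# Seeded stratified k-fold assignment: each class is shuffled once and dealt
# round-robin into folds.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validate a classifier specification
#'
#' Stratified k-fold cross-validation; per-fold confusion counts are summed
#' and the Matthews correlation is computed from the pooled counts (stable
#' for small folds, unlike averaging per-fold coefficients).
#'
#' @param spec A [classifier_spec()].
#' @param pos,neg Lists of fingerprints per class; each must hold at least
#'   `k` members.
#' @param k Number of folds, default 5.
#' @param seed Integer seed controlling the fold split and any classifier
#'   randomness.
#' @return A `cv_result`: list with `spec`, `fold_counts` (k x 4 matrix),
#'   `pooled` (named counts), `mcc`, `seed`.
#' @export
cross_validate <- function(spec, pos, neg, k = 5L, seed = 1L) {
  if (length(pos) < k || length(neg) < k) {
    stop("each class needs at least k = ", k, " members", call. = FALSE)
  }
  x <- c(pos, neg)
  y <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
  fold <- stratified_folds(y, k, seed)
  fold_counts <- matrix(0L, k, 4, dimnames = list(NULL, c("tp", "fp", "tn", "fn")))
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- train_classifier(spec, x[tr & y], x[tr & !y], seed = seed)
    pred <- predict(model, x[!tr])
    fold_counts[f, ] <- confusion_counts(y[!tr], pred)
  }
  pooled <- colSums(fold_counts)
  structure(
    list(
      spec = spec, fold_counts = fold_counts, pooled = pooled,
      mcc = mcc(pooled["tp"], pooled["fp"], pooled["tn"], pooled["fn"]),
      seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result ", spec_label(x$spec), ": pooled MCC = ",
    format(x$mcc, digits = 4), ">\n",
    sep = ""
  )
  invisible(x)
}

#' The default method-kernel-hyperparameter grid
#'
#' SVMs with RBF (three widths), Tanimoto and Sorensen kernels at four cost
#' values; naive Bayes at three smoothing strengths; the kernel discriminant
#' at three basis sizes and two ridge strengths per kernel. A compact,
#' fully user-overridable stand-in for an exhaustive production grid.
#'
#' @return List of [classifier_spec()] objects.
#' @export
default_model_grid <- function() {
  grid <- list()
  for (C in c(0.1, 1, 10, 100)) {
    for (g in c(0.01, 0.1, 1)) {
      grid <- c(grid, list(classifier_spec("svm", "rbf", C = C, gamma = g)))
    }
    for (kern in c("tanimoto", "sorensen")) {
      grid <- c(grid, list(classifier_spec("svm", kern, C = C)))
    }
  }
  for (alpha in c(0.5, 1, 2)) {
    grid <- c(grid, list(classifier_spec("naive_bayes", alpha = alpha)))
  }
  for (kern in c("tanimoto", "sorensen")) {
    for (m in c(64L, 128L, 256L)) {
      for (eps in c(1e-3, 1e-2)) {
        grid <- c(grid, list(classifier_spec("eem", kern, m = m, eps = eps)))
      }
    }
  }
  grid
}

#' Select the best model over a specification grid
#'
#' Every specification is cross-validated and the one with the highest
#' pooled-count Matthews correlation wins. Exact ties break
#' deterministically: method order naive_bayes < svm < eem, then smaller
#' cost/basis size, then grid order.
#'
#' @param grid Non-empty list of [classifier_spec()] objects.
#' @inheritParams cross_validate
#' @return List with `spec` (winner), `cv` (its `cv_result`), and `audit`
#'   (tibble of every evaluated spec with its MCC, in grid order).
#' @export
select_best_model <- function(grid, pos, neg, k = 5L, seed = 1L) {
  if (length(grid) == 0) stop("empty model grid", call. = FALSE)
  results <- lapply(grid, cross_validate, pos = pos, neg = neg, k = k, seed = seed)
  mccs <- vapply(results, `[[`, numeric(1), "mcc")
  method_rank <- vapply(grid, function(s) {
    match(s$method, c("naive_bayes", "svm", "eem"))
  }, numeric(1))
  size_rank <- vapply(grid, function(s) {
    hp <- s$hyperparams
    if (!is.null(hp$C)) hp$C else if (!is.null(hp$m)) hp$m else 0
  }, numeric(1))
  ord <- order(-mccs, method_rank, size_rank, seq_along(grid))
  best <- ord[1]
  audit <- tibble::tibble(
    label = vapply(grid, spec_label, character(1)),
    method = vapply(grid, `[[`, character(1), "method"),
    kernel = vapply(grid, `[[`, character(1), "kernel"),
    mcc = mccs,
    selected = seq_along(grid) == best
  )
  list(spec = grid[[best]], cv = results[[best]], audit = audit)
}

# ---- broom-style accessors -------------------------------------------------

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble with one row per fold: fold number, confusion counts,
#'   per-fold Matthews correlation.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(
    fold = seq_len(nrow(x$fold_counts)),
    tp = x$fold_counts[, "tp"], fp = x$fold_counts[, "fp"],
    tn = x$fold_counts[, "tn"], fn = x$fold_counts[, "fn"],
    mcc = apply(x$fold_counts, 1, function(r) mcc(r["tp"], r["fp"], r["tn"], r["fn"]))
  )
}

#' Glance at a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble: model label, pooled counts, pooled MCC, seed.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    model = spec_label(x$spec),
    tp = x$pooled[["tp"]], fp = x$pooled[["fp"]],
    tn = x$pooled[["tn"]], fn = x$pooled[["fn"]],
    mcc = x$mcc, folds = nrow(x$fold_counts), seed = x$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
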