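# Classifier families used for activity/selectivity discrimination: kernel
# SVMs (via kernlab on precomputed Gram matrices), Bernoulli naive Bayes
# over fingerprint bits, and a closed-form regularized kernel discriminant
# in the extreme-entropy-machine family (random kernel basis, Fisher-style
# weight vector, midpoint threshold).

#' Specify a classifier
#'
#' @param ... The first two (optionally named `method` and `kernel`)
#'   arguments select the classifier family -- `"svm"`, `"naive_bayes"` or
#'   `"eem"` -- and its kernel -- `"rbf"`, `"tanimoto"`, `"sorensen"`, or
#'   `"none"` (naive Bayes). Remaining named arguments are hyperparameters:
#'   `C` (svm cost), `gamma` (rbf width), `alpha` (naive Bayes Laplace
#'   smoothing), `m` (eem basis size), `eps` (eem ridge). Matching is exact
#'   (a hyperparameter `m` never abbreviates `method`).
#' @return A `classifier_spec` object.
#' @examples
#' classifier_spec("svm", "tanimoto", C = 1)
#' classifier_spec("eem", "sorensen", m = 64, eps = 1e-2)
#' @export
classifier_spec <- function(...) {
  a <- list(...)
  nm <- names(a)
  if (is.null(nm)) nm <- rep("", length(a))
  positional <- a[nm == ""]
  method <- a[["method"]] %||%
    (if (length(positional) >= 1) positional[[1]] else NULL)
  kernel <- a[["kernel"]] %||%
    (if (length(positional) >= 2) positional[[2]] else "none")
  if (length(positional) > 2) {
    stop("too many positional arguments to classifier_spec()", call. = FALSE)
  }
  method <- match.arg(method, c("svm", "naive_bayes", "eem"))
  kernel <- match.arg(kernel, c("none", "rbf", "tanimoto", "sorensen"))
  hp <- a[!(nm %in% c("method", "kernel", ""))]
  if (method == "naive_bayes") {
    if (kernel != "none") stop("naive_bayes takes no kernel", call. = FALSE)
    if (is.null(hp$alpha)) hp$alpha <- 1
  }
  if (method == "svm") {
    if (kernel == "none") stop("svm requires a kernel", call. = FALSE)
    if (is.null(hp$C)) hp$C <- 1
    if (kernel == "rbf" && is.null(hp$gamma)) {
      stop("svm with rbf kernel requires gamma", call. = FALSE)
    }
  }
  if (method == "eem") {
    if (!kernel %in% c("tanimoto", "sorensen")) {
      stop("eem requires a tanimoto or sorensen kernel", call. = FALSE)
    }
    if (is.null(hp$m)) hp$m <- 128L
    if (is.null(hp$eps)) hp$eps <- 1e-2
  }
  structure(list(method = method, kernel = kernel, hyperparams = hp),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparams), unlist(x$hyperparams),
    sep = "=", collapse = ", "
  )
  cat("<classifier_spec ", x$method,
    if (x$kernel != "none") paste0("/", x$kernel), " ", hp, ">\n",
    sep = ""
  )
  invisible(x)
}

spec_label <- function(spec) {
  hp <- spec$hyperparams
  paste0(
    spec$method,
    if (spec$kernel != "none") paste0("_", spec$kernel),
    if (!is.null(hp$C)) paste0("_C", hp$C),
    if (!is.null(hp$gamma)) paste0("_g", hp$gamma),
    if (!is.null(hp$alpha)) paste0("_a", hp$alpha),
    if (!is.null(hp$m)) paste0("_m", hp$m),
    if (!is.null(hp$eps)) paste0("_e", hp$eps)
  )
}

#' Train a binary classifier on positive and negative fingerprints
#'
#' @param spec A [classifier_spec()].
#' @param pos,neg Lists of `nsfp_fingerprint` objects (or bit views) for the
#'   positive and negative class.
#' @param seed Integer seed (the eem basis sample is the only stochastic
#'   element).
#' @return A `trained_classifier` with a [predict()] method returning
#'   logical labels.
#' @export
train_classifier <- function(spec, pos, neg, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  bits <- c(lapply(pos, as_bitview), lapply(neg, as_bitview))
  y <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
  vocabulary <- sort(unique(unlist(bits)))
  fit <- switch(spec$method,
    svm = fit_svm(spec, bits, y, vocabulary),
    naive_bayes = fit_nb(spec, bits, y, vocabulary),
    eem = fit_eem(spec, bits, y, vocabulary, seed)
  )
  ks <- if (inherits(pos[[1]], "nsfp_fingerprint")) {
    attr(pos[[1]], "keyset_name")
  } else {
    NULL
  }
  structure(
    list(
      spec = spec, fit = fit, vocabulary = vocabulary, seed = seed,
      keyset_name = ks
    ),
    class = "trained_classifier"
  )
}

fit_svm <- function(spec, bits, y, vocabulary) {
  k <- gram_matrix(spec$kernel, bits,
    gamma = spec$hyperparams$gamma,
    vocabulary = vocabulary
  )
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  # the shrinking heuristic converges pathologically slowly on fingerprint
  # Gram matrices with many near-duplicate rows; plain SMO is fast here
  model <- kernlab::ksvm(kernlab::as.kernelMatrix(k), yf,
    type = "C-svc",
    C = spec$hyperparams$C, scaled = FALSE, shrinking = FALSE
  )
  list(model = model, train_bits = bits, sv_index = kernlab::SVindex(model))
}

# Bernoulli naive Bayes over feature presence bits with Laplace smoothing:
# P(f = 1 | class) = (n_class_with_f + alpha) / (n_class + 2 alpha).
fit_nb <- function(spec, bits, y, vocabulary) {
  alpha <- spec$hyperparams$alpha
  m <- bitview_matrix(bits, vocabulary)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  p_pos <- (colSums(m[y, , drop = FALSE]) + alpha) / (n_pos + 2 * alpha)
  p_neg <- (colSums(m[!y, , drop = FALSE]) + alpha) / (n_neg + 2 * alpha)
  list(
    log_prior = log(c(pos = n_pos, neg = n_neg) / (n_pos + n_neg)),
    lp_pos = log(p_pos), lq_pos = log(1 - p_pos),
    lp_neg = log(p_neg), lq_neg = log(1 - p_neg)
  )
}

# Closed-form kernel discriminant: map each example to similarities against
# a random basis of m training points, then w = (S+ + S- + eps I)^-1 (mu+ - mu-)
# with the decision threshold at the midpoint of the projected class means.
fit_eem <- function(spec, bits, y, vocabulary, seed) {
  m <- min(spec$hyperparams$m, length(bits))
  eps <- spec$hyperparams$eps
  set.seed(seed)
  basis_idx <- sort(sample.int(length(bits), m))
  basis <- bits[basis_idx]
  phi <- gram_matrix(spec$kernel, bits, basis, vocabulary = vocabulary)
  mu_pos <- colMeans(phi[y, , drop = FALSE])
  mu_neg <- colMeans(phi[!y, , drop = FALSE])
  cov_of <- function(mm) {
    if (nrow(mm) < 2) matrix(0, ncol(mm), ncol(mm)) else stats::cov(mm)
  }
  s <- cov_of(phi[y, , drop = FALSE]) + cov_of(phi[!y, , drop = FALSE]) +
    diag(eps, m)
  if (eps == 0 && rcond(s) < .Machine$double.eps) {
    stop("singular covariance; use eps > 0", call. = FALSE)
  }
  w <- solve(s, mu_pos - mu_neg)
  thr <- sum(w * (mu_pos + mu_neg)) / 2
  list(basis = basis, w = w, threshold = thr)
}

#' Predict binary labels for fingerprints
#'
#' @param object A `trained_classifier`.
#' @param newdata List of `nsfp_fingerprint` objects or bit views.
#' @param ... Unused.
#' @return Logical vector (`TRUE` = positive class).
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  bits <- lapply(newdata, as_bitview)
  spec <- object$spec
  if (spec$method == "svm") {
    ktest <- gram_matrix(spec$kernel, bits, object$fit$train_bits,
      gamma = spec$hyperparams$gamma, vocabulary = object$vocabulary
    )
    pr <- kernlab::predict(
      object$fit$model,
      kernlab::as.kernelMatrix(ktest[, object$fit$sv_index, drop = FALSE])
    )
    return(pr == "pos")
  }
  if (spec$method == "naive_bayes") {
    m <- bitview_matrix(bits, object$vocabulary)
    f <- object$fit
    score_pos <- f$log_prior["pos"] + m %*% f$lp_pos + (1 - m) %*% f$lq_pos
    score_neg <- f$log_prior["neg"] + m %*% f$lp_neg + (1 - m) %*% f$lq_neg
    return(as.vector(score_pos > score_neg))
  }
  phi <- gram_matrix(spec$kernel, bits, object$fit$basis,
    vocabulary = object$vocabulary
  )
  as.vector(phi %*% object$fit$w >= object$fit$threshold)
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat("<trained_classifier ", spec_label(x$spec), ", ",
    length(x$vocabulary), " features>\n",
    sep = ""
  )
  invisible(x)
}
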