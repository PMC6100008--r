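# Fingerprint kernels. Binary fingerprints are sets of feature tuples;
# Tanimoto and Sorensen set similarities are positive semi-definite on such
# sets and serve directly as SVM/discriminant kernels. The RBF kernel
# operates on the dense 0/1 vector view.

#' Tanimoto kernel between two binary fingerprints
#'
#' `|x & y| / |x | y|`; by convention 1 when both sets are empty.
#'
#' @param x,y Character vectors of present features ([binarize()] output) or
#'   `nsfp_fingerprint` objects.
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimoto_kernel(c("a", "b", "c"), c("b", "c", "d")) # 0.5
#' @export
tanimoto_kernel <- function(x, y) {
  x <- as_bitview(x)
  y <- as_bitview(y)
  u <- length(union(x, y))
  if (u == 0) {
    return(1)
  }
  length(intersect(x, y)) / u
}

#' Sorensen (Dice) kernel between two binary fingerprints
#'
#' `2 |x & y| / (|x| + |y|)`; 1 when both sets are empty.
#'
#' @inheritParams tanimoto_kernel
#' @return Similarity in \[0, 1\].
#' @export
sorensen_kernel <- function(x, y) {
  x <- as_bitview(x)
  y <- as_bitview(y)
  denom <- length(x) + length(y)
  if (denom == 0) {
    return(1)
  }
  2 * length(intersect(x, y)) / denom
}

#' Radial basis function kernel on dense 0/1 vectors
#'
#' `exp(-gamma * ||x - y||^2)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Positive width parameter.
#' @return Similarity in (0, 1\].
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  stopifnot(length(x) == length(y))
  exp(-gamma * sum((x - y)^2))
}

as_bitview <- function(x) {
  if (inherits(x, "nsfp_fingerprint")) binarize(x) else as.character(x)
}

# Gram matrix over two lists of bit views (or one, symmetric case) computed
# through the dense indicator matrix: intersections are a cross product.
gram_matrix <- function(kernel = c("tanimoto", "sorensen", "rbf"),
                        x, y = NULL, gamma = NULL, vocabulary = NULL) {
  kernel <- match.arg(kernel)
  sym <- is.null(y)
  if (sym) y <- x
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(c(unlist(x), unlist(y))))
  }
  mx <- bitview_matrix(x, vocabulary)
  my <- bitview_matrix(y, vocabulary)
  inter <- tcrossprod(mx, my)
  sx <- rowSums(mx)
  sy <- rowSums(my)
  if (kernel == "tanimoto") {
    uni <- outer(sx, sy, "+") - inter
    k <- ifelse(uni == 0, 1, inter / uni)
  } else if (kernel == "sorensen") {
    denom <- outer(sx, sy, "+")
    k <- ifelse(denom == 0, 1, 2 * inter / denom)
  } else {
    if (is.null(gamma) || gamma <= 0) stop("gamma must be positive", call. = FALSE)
    # squared Euclidean distance between 0/1 rows
    d2 <- outer(sx, sy, "+") - 2 * inter
    k <- exp(-gamma * d2)
  }
  unname(k)
}

bitview_matrix <- function(bitviews, vocabulary) {
  m <- matrix(0, length(bitviews), length(vocabulary))
  colnames(m) <- vocabulary
  for (i in seq_along(bitviews)) {
    present <- intersect(as_bitview(bitviews[[i]]), vocabulary)
    m[i, present] <- 1
  }
  m
}
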