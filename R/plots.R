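# ggplot2 views of the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-fold cross-validation performance
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot: per-fold Matthews correlation with the pooled value as
#'   a horizontal reference.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$fold), y = .data$mcc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mcc, linetype = 2) +
    ggplot2::labs(
      x = "fold", y = "MCC",
      title = spec_label(object$spec),
      subtitle = sprintf("pooled MCC = %.3f", object$mcc)
    ) +
    ggplot2::ylim(-1, 1)
}

#' Plot a model-selection audit
#'
#' @param audit The `audit` tibble returned by [select_best_model()].
#' @return A ggplot of cross-validated MCC per candidate specification,
#'   winner highlighted.
#' @export
plot_model_grid <- function(audit) {
  ggplot2::ggplot(
    audit,
    ggplot2::aes(
      x = stats::reorder(.data$label, .data$mcc), y = .data$mcc,
      fill = .data$selected
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "cross-validated MCC")
}

#' Plot a rank-consensus result
#'
#' @param consensus Output of [delta_max()].
#' @param top_fraction Optional fraction to mark (e.g. 0.10).
#' @return A ggplot: sorted delta-max values, selectivity boundary at 0,
#'   optional top-fraction cut.
#' @export
plot_consensus <- function(consensus, top_fraction = NULL) {
  df <- dplyr::mutate(consensus, idx = dplyr::row_number())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$delta_max)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$selected), show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "seagreen")) +
    ggplot2::labs(
      x = "compound (sorted)", y = expression(Delta[max]),
      title = "Rank-difference consensus"
    )
  if (!is.null(top_fraction)) {
    n_sel <- sum(df$selected)
    cut <- floor(n_sel * top_fraction)
    if (cut >= 1) p <- p + ggplot2::geom_vline(xintercept = cut + 0.5, colour = "firebrick")
  }
  p
}

#' Plot the screening funnel of a pipeline run
#'
#' @param manifest A manifest list from [run_pipeline()].
#' @return A ggplot of the monotone funnel counts.
#' @export
plot_funnel <- function(manifest) {
  f <- manifest$funnel
  df <- tibble::tibble(
    stage = factor(names(f), levels = names(f)),
    count = as.numeric(unlist(f))
  )
  df <- df[!is.na(df$count), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "compounds", title = "Screening funnel")
}

#' Glance at a trained classifier
#'
#' @param x A `trained_classifier`.
#' @param ... Unused.
#' @return One-row tibble: method, kernel, hyperparameters, feature count.
#' @method glance trained_classifier
#' @export
glance.trained_classifier <- function(x, ...) {
  tibble::tibble(
    model = spec_label(x$spec),
    method = x$spec$method,
    kernel = x$spec$kernel,
    n_features = length(x$vocabulary),
    keyset = x$keyset_name %||% NA_character_
  )
}

#' Tidy a fingerprint into a feature table
#'
#' @param x An `nsfp_fingerprint`.
#' @param ... Unused.
#' @return Tibble `feature`, `count`.
#' @method tidy nsfp_fingerprint
#' @export
tidy.nsfp_fingerprint <- function(x, ...) {
  tibble::tibble(feature = names(x), count = as.integer(x))
}
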