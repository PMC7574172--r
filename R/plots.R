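# ggplot2 autoplot methods for the package's result objects.

#' Plot a feature screen
#'
#' Bar chart of per-feature AUC with the selection cutoff marked.
#'
#' @param object A `feature_screen` (see [screen_features()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_screen <- function(object, ...) {
  cutoff <- attr(object, "cutoff")
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$auc),
    y = .data$auc, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ROC AUC vs labeled pairs",
                  fill = paste0("AUC > ", cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param object A `pr_curve` (see [precision_recall_curve()]).
#' @param ... Additional `pr_curve` objects to overlay, named in the legend
#'   by argument name.
#' @return A ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), "pr_curve")]
  curves <- c(list(network = object), extra)
  if (is.null(names(curves)) || names(curves)[1] == "") {
    names(curves)[1] <- "network"
  }
  df <- dplyr::bind_rows(lapply(curves, tibble::as_tibble), .id = "curve")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::lims(x = c(0, NA), y = c(0, 1)) +
    ggplot2::labs(x = "Recall (new annotations recovered)",
                  y = "Precision (reported annotations correct)") +
    ggplot2::theme_minimal()
}

#' Plot a GSLA result
#'
#' Candidate gene sets on the density / significance plane with the Q1 and
#' Q2 cutoffs marked; hits highlighted.
#'
#' @param object A `gsla_result` (see [run_gsla()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsla_result <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$density,
                                   y = -log10(.data$p_value),
                                   colour = .data$hit)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = cfg$density_cutoff,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(cfg$p_cutoff),
                        linetype = "dashed") +
    ggplot2::labs(x = "Inter-set density (Q1)",
                  y = "-log10 permutation p (Q2)", colour = "Reported") +
    ggplot2::theme_minimal()
}

#' Tidy the hyperparameter search table of a fitted model
#'
#' @param x A `fic_model`.
#' @param ... Unused.
#' @return The grid-search cross-validation table (one row per grid point),
#'   or a one-row tibble with the chosen hyperparameters when the model was
#'   fitted without a search.
#' @export
tidy.fic_model <- function(x, ...) {
  if (!is.null(x$cv_table)) return(tibble::as_tibble(x$cv_table))
  tibble::tibble(sigma = x$sigma, c = x$c)
}

#' One-row summary of a fitted model
#'
#' @param x A `fic_model`.
#' @param ... Unused.
#' @return One-row tibble: hyperparameters, feature count, training
#'   composition, support-vector count.
#' @export
glance.fic_model <- function(x, ...) {
  tibble::tibble(
    sigma = x$sigma, c = x$c,
    n_features = length(x$feature_names),
    n_positive = x$n_positive, n_negative = x$n_negative,
    n_support_vectors = x$svm$tot.nSV
  )
}
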