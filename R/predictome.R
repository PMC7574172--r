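# predictome: score all gene pairs with a trained model, assemble the
# predicted functional interactome, and solve the interactome-size equation.

#' Score all gene pairs of a universe and keep predicted associations
#'
#' Enumerates every unordered gene pair of the universe in batches (memory is
#' O(batch)), obtains features from `feature_provider`, and keeps pairs whose
#' decision value exceeds the model threshold. Edge weight is the decision
#' value squashed into (0, 1) by the logistic function; source is
#' `"predicted"`. Output is independent of `batch_size`.
#'
#' @param model A `fic_model`.
#' @param feature_provider Function taking a pair tibble (`gene_a`, `gene_b`)
#'   and returning a feature matrix for those pairs including all of the
#'   model's features.
#' @param universe Character vector of genes.
#' @param batch_size Pairs scored per batch (default 20000).
#' @param exclude Optional `interactome` or pair tibble whose pairs are
#'   skipped (e.g. the known positives, which are merged back afterwards via
#'   [merge_interactomes()]).
#' @return An `interactome` with `source = "predicted"` over `universe`.
#' @export
predict_all_pairs <- function(model, feature_provider, universe,
                              batch_size = 20000L, exclude = NULL) {
  stopifnot(inherits(model, "fic_model"), length(universe) >= 2)
  genes <- sort(unique(universe))
  excl_keys <- character()
  if (!is.null(exclude)) {
    ex <- if (inherits(exclude, "interactome")) exclude$edges else exclude
    excl_keys <- pair_key(ex$gene_a, ex$gene_b)
  }
  g <- length(genes)
  acc <- list()
  buf_a <- character(0); buf_b <- character(0)
  flush <- function(a, b) {
    pairs <- tibble::tibble(gene_a = a, gene_b = b)
    if (length(excl_keys) > 0) {
      pairs <- pairs[!(pair_key(pairs$gene_a, pairs$gene_b) %in% excl_keys), ]
    }
    if (nrow(pairs) == 0) return(NULL)
    fm <- feature_provider(pairs)
    d <- predict(model, fm, type = "decision")
    keep <- d > model$threshold
    if (!any(keep)) return(NULL)
    tibble::tibble(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
                   weight = plogis(d[keep]), source = "predicted")
  }
  for (i in seq_len(g - 1L)) {
    js <- (i + 1L):g
    buf_a <- c(buf_a, rep(genes[i], length(js)))
    buf_b <- c(buf_b, genes[js])
    if (length(buf_a) >= batch_size) {
      acc[[length(acc) + 1L]] <- flush(buf_a, buf_b)
      buf_a <- character(0); buf_b <- character(0)
    }
  }
  if (length(buf_a) > 0) acc[[length(acc) + 1L]] <- flush(buf_a, buf_b)
  interactome(dplyr::bind_rows(acc), genes = genes)
}

#' Estimate the size of the underlying interactome
#'
#' Solves the accounting identity
#' `N_interactome * sens + (N_all_pairs - N_interactome) * (1 - spec) =
#' N_predict` for `N_interactome`: the predicted associations are the true
#' interactions the model catches plus the false positives among all
#' remaining pairs. Requires `sensitivity > 1 - specificity` (otherwise the
#' equation is not identifiable). The solution is clipped to
#' `[0, n_all_pairs]` with a warning if it falls outside.
#'
#' @param n_predict Number of predicted associations.
#' @param n_all_pairs Number of gene pairs in the universe (must be supplied
#'   explicitly, typically `choose(G, 2)` for a G-gene universe).
#' @param sensitivity,specificity Validated accuracy of the prediction model.
#' @return A one-row tibble of class `size_estimate` with the equation
#'   inputs, the solved `n_interactome`, and the derived
#'   `expected_ppi_in_predictions` / `expected_ppi_fraction`.
#' @export
estimate_interactome_size <- function(n_predict, n_all_pairs, sensitivity,
                                      specificity) {
  stopifnot(n_predict >= 0, n_all_pairs > 0,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  fpr <- 1 - specificity
  if (sensitivity <= fpr) {
    stop("non-identifiable: sensitivity must exceed the false positive ",
         "rate (1 - specificity)", call. = FALSE)
  }
  n_int <- (n_predict - n_all_pairs * fpr) / (sensitivity - fpr)
  if (n_int < 0 || n_int > n_all_pairs) {
    warning("interactome size estimate ", signif(n_int, 6),
            " outside [0, n_all_pairs]; clipped", call. = FALSE)
    n_int <- min(max(n_int, 0), n_all_pairs)
  }
  ep <- expected_ppi(n_int, sensitivity, n_predict)
  out <- tibble::tibble(
    n_predict = n_predict, n_all_pairs = n_all_pairs,
    sensitivity = sensitivity, specificity = specificity,
    n_interactome = n_int,
    expected_ppi_in_predictions = ep$count,
    expected_ppi_fraction = ep$fraction
  )
  class(out) <- c("size_estimate", class(out))
  out
}

#' Expected protein interactions among the predictions
#'
#' `count = n_interactome * sensitivity` true interactions are expected to be
#' caught by the model; `fraction = count / n_predict` is the share of the
#' predicted associations expected to represent protein interactions.
#'
#' @param n_interactome Estimated interactome size.
#' @param sensitivity Model sensitivity.
#' @param n_predict Number of predicted associations (> 0).
#' @return One-row tibble with `count` and `fraction`.
#' @export
expected_ppi <- function(n_interactome, sensitivity, n_predict) {
  stopifnot(n_predict > 0, n_interactome >= 0)
  count <- n_interactome * sensitivity
  tibble::tibble(count = count, fraction = count / n_predict)
}

#' Fraction of the interactome covered by detected true interactions
#'
#' @param n_detected_true Number of true interactions detected.
#' @param n_interactome Interactome size (> 0).
#' @return Fraction in \[0, 1\].
#' @export
coverage_of_interactome <- function(n_detected_true, n_interactome) {
  stopifnot(n_interactome > 0, n_detected_true >= 0)
  n_detected_true / n_interactome
}

#' Pick the sensitivity used for size estimation
#'
#' The conservative default takes the smaller of the training-stage and
#' validation-stage sensitivities.
#'
#' @param training,validation Sensitivities from the two stages.
#' @param policy `"min"` (default), `"validation"`, or `"training"`.
#' @return A single sensitivity value.
#' @export
choose_sensitivity <- function(training, validation,
                               policy = c("min", "validation", "training")) {
  policy <- match.arg(policy)
  switch(policy,
         min = min(training, validation),
         validation = validation,
         training = training)
}

#' @export
glance.size_estimate <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
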