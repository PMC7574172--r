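# train: labeled training/validation pair construction and the soft-margin
# Gaussian-kernel SVM with harmonic-mean model selection.
#
# Conventions fixed across the module: positives are high-quality known
# interactions; negatives are random non-positive pairs at a configurable
# ratio (default 1:100, handled by the data ratio itself, no class weights);
# the Gaussian kernel is K(x, y) = exp(-||x - y||^2 / (2 sigma^2)), i.e.
# libSVM gamma = 1 / (2 sigma^2); the decision threshold is 0 (sign of the
# decision value), with no probability calibration.

#' Filter protein-interaction records down to high-quality positives
#'
#' A record survives iff it was reported in at least two independent studies
#' AND is not supported exclusively by high-throughput experiments; records
#' failing either condition are removed. Duplicated unordered pairs are
#' collapsed.
#'
#' @param records Tibble with columns `gene_a`, `gene_b`, `n_studies`
#'   (non-negative integer) and `only_high_throughput` (logical).
#' @return Tibble of retained canonical pairs (`gene_a`, `gene_b`), with a
#'   `"filter_stats"` attribute recording input/retained counts.
#' @export
filter_high_quality_ppis <- function(records) {
  stopifnot(all(c("gene_a", "gene_b", "n_studies", "only_high_throughput")
                %in% names(records)))
  if (any(records$gene_a == records$gene_b)) {
    stop("self-interactions are not valid positive examples", call. = FALSE)
  }
  keep <- records$n_studies >= 2 & !records$only_high_throughput
  out <- canonical_pairs(records$gene_a[keep], records$gene_b[keep]) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  attr(out, "filter_stats") <- list(n_input = nrow(records),
                                    n_retained = nrow(out))
  out
}

#' Sample negative gene pairs
#'
#' Draws exactly `ratio * nrow(positives)` distinct unordered pairs from the
#' universe, none of which is a positive or a self-loop. Rejection sampling
#' with canonical pair encoding keeps the draw reproducible under `seed`;
#' when the requested count is close to the number of available pairs the
#' complement is enumerated instead.
#'
#' @param genes Character vector: the gene universe.
#' @param positives Tibble with columns `gene_a`, `gene_b`.
#' @param ratio Negatives per positive (default 100).
#' @param seed Integer seed for reproducibility.
#' @return Tibble of canonical negative pairs; attributes `"ratio"`, `"seed"`.
#' @export
sample_negatives <- function(genes, positives, ratio = 100, seed = NULL) {
  genes <- sort(unique(genes))
  g <- length(genes)
  pos_keys <- unique(pair_key(positives$gene_a, positives$gene_b))
  n_needed <- ratio * length(pos_keys)
  n_avail <- choose(g, 2) - length(pos_keys)
  if (n_avail < n_needed) {
    stop("universe of ", g, " genes has only ", n_avail,
         " non-positive pairs; ", n_needed, " negatives requested",
         call. = FALSE)
  }
  out <- with_seed_if(seed, {
    if (n_needed > 0.5 * n_avail) {
      all_p <- all_pairs_tbl(genes)
      all_p <- all_p[!(pair_key(all_p$gene_a, all_p$gene_b) %in% pos_keys), ]
      all_p[sample(nrow(all_p), n_needed), ]
    } else {
      seen <- character(0)
      acc <- list()
      while (length(seen) < n_needed) {
        k <- max(1000L, ceiling((n_needed - length(seen)) * 1.3))
        a <- genes[sample.int(g, k, replace = TRUE)]
        b <- genes[sample.int(g, k, replace = TRUE)]
        cp <- canonical_pairs(a, b)
        keys <- pair_key(cp$gene_a, cp$gene_b)
        ok <- a != b & !(keys %in% pos_keys) & !(keys %in% seen) &
          !duplicated(keys)
        cp <- cp[ok, ]
        cp <- utils::head(cp, n_needed - length(seen))
        seen <- c(seen, pair_key(cp$gene_a, cp$gene_b))
        acc[[length(acc) + 1L]] <- cp
      }
      dplyr::bind_rows(acc)
    }
  })
  out <- dplyr::arrange(out, .data$gene_a, .data$gene_b)
  attr(out, "ratio") <- ratio
  attr(out, "seed") <- seed
  out
}

#' Combine positives and negatives into a labeled pair set
#'
#' @param positives,negatives Canonical pair tibbles (disjoint).
#' @return Tibble `gene_a`, `gene_b`, `label` ("positive"/"negative").
#' @export
make_labeled_pairs <- function(positives, negatives) {
  pk <- pair_key(positives$gene_a, positives$gene_b)
  nk <- pair_key(negatives$gene_a, negatives$gene_b)
  if (length(intersect(pk, nk)) > 0) {
    stop("positives and negatives overlap", call. = FALSE)
  }
  dplyr::bind_rows(
    tibble::tibble(gene_a = positives$gene_a, gene_b = positives$gene_b,
                   label = "positive"),
    tibble::tibble(gene_a = negatives$gene_a, gene_b = negatives$gene_b,
                   label = "negative")
  )
}

# ---- preprocessing (imputation + scaling), stored with the model ----------

# Per-feature median imputation values and min-max bounds from labeled data.
compute_preprocess <- function(x) {
  med <- apply(x, 2, median, na.rm = TRUE)
  med[is.na(med)] <- 0  # feature entirely missing: impute 0
  lo <- apply(x, 2, min, na.rm = TRUE)
  hi <- apply(x, 2, max, na.rm = TRUE)
  lo[!is.finite(lo)] <- 0
  hi[!is.finite(hi)] <- 1
  list(median = med, min = lo, max = hi)
}

apply_preprocess <- function(x, prep) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    v[is.na(v)] <- prep$median[j]
    span <- prep$max[j] - prep$min[j]
    x[, j] <- if (span > 0) (v - prep$min[j]) / span else 0
  }
  x
}

feature_matrix_of <- function(fm, feature_names = NULL) {
  cols <- feature_names %||% numeric_feature_names(fm)
  missing_cols <- setdiff(cols, names(fm))
  if (length(missing_cols) > 0) {
    stop("feature matrix lacks required feature(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as.matrix(fm[, cols, drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- SVM core -------------------------------------------------------------

# Fit libSVM (via e1071) with the Gaussian kernel parameterized by sigma.
fit_svm_core <- function(x, y, sigma, c) {
  yf <- factor(ifelse(y, "positive", "negative"),
               levels = c("positive", "negative"))
  if (length(unique(y)) < 2) {
    stop("cannot fit an SVM on single-class labels", call. = FALSE)
  }
  e1071::svm(x, yf, type = "C-classification", kernel = "radial",
             gamma = 1 / (2 * sigma^2), cost = c, scale = FALSE)
}

# Decision values oriented so that larger = more positive-like.
svm_decision <- function(svm_fit, x) {
  pr <- predict(svm_fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  d <- dv[, 1]
  # libSVM orients the decision value toward the first factor level of the
  # column label; flip when "negative" comes first.
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (identical(first, "negative")) d <- -d
  unname(d)
}

confusion_metrics <- function(truth, predicted_positive) {
  tp <- sum(truth & predicted_positive)
  fn <- sum(truth & !predicted_positive)
  tn <- sum(!truth & !predicted_positive)
  fp <- sum(!truth & predicted_positive)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    harmonic_mean = harmonic_mean(sens, spec),
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}

#' Cross-validated sensitivity/specificity for one hyperparameter pair
#'
#' Stratified k-fold cross-validation: imputation and scaling are recomputed
#' on each training fold, an SVM is fitted, and the held-out confusion counts
#' are pooled over folds (pooling, rather than averaging per-fold rates,
#' stays well defined under extreme class imbalance). The harmonic mean of
#' the pooled sensitivity and specificity is the model-selection target.
#'
#' @param fm Feature matrix tibble (rows aligned with `labels`).
#' @param labels Positive/negative labels.
#' @param sigma Gaussian kernel width (> 0).
#' @param c Soft-margin cost (> 0).
#' @param folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param feature_names Optional subset of feature columns to use.
#' @return One-row tibble `sensitivity`, `specificity`, `harmonic_mean` plus
#'   pooled confusion counts.
#' @export
cross_validated_metrics <- function(fm, labels, sigma, c, folds = 5,
                                    seed = 1L, feature_names = NULL) {
  y <- as_binary_labels(labels)
  x <- feature_matrix_of(fm, feature_names)
  stopifnot(length(y) == nrow(x), folds >= 2)
  if (sum(y) < folds || sum(!y) < folds) {
    stop("need at least `folds` examples of each class for stratified CV",
         call. = FALSE)
  }
  fold_id <- integer(length(y))
  with_seed_if(seed, {
    fold_id[y] <- sample(rep_len(seq_len(folds), sum(y)))
    fold_id[!y] <- sample(rep_len(seq_len(folds), sum(!y)))
  })
  pred_pos <- logical(length(y))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    prep <- compute_preprocess(x[!test, , drop = FALSE])
    xt <- apply_preprocess(x[!test, , drop = FALSE], prep)
    fit <- fit_svm_core(xt, y[!test], sigma, c)
    xv <- apply_preprocess(x[test, , drop = FALSE], prep)
    pred_pos[test] <- svm_decision(fit, xv) > 0
  }
  confusion_metrics(y, pred_pos)
}

#' SVM hyperparameter search configuration
#'
#' @param sigma_grid Candidate kernel widths; `NULL` (default) derives the
#'   grid at search time as `2^(-4, -2, 0, 2, 4)` times the median pairwise
#'   distance of the preprocessed labeled data (median heuristic).
#' @param c_grid Candidate soft-margin costs (default `2^seq(-2, 6, 2)`).
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed for fold assignment.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(sigma_grid = NULL, c_grid = 2^seq(-2, 6, by = 2),
                       folds = 5, seed = 1L) {
  stopifnot(length(c_grid) >= 1, folds >= 2)
  structure(list(sigma_grid = sigma_grid, c_grid = c_grid, folds = folds,
                 seed = seed), class = "svm_config")
}

median_distance_heuristic <- function(x, max_n = 500L, seed = 1L) {
  n <- nrow(x)
  idx <- if (n > max_n) {
    with_seed_if(seed, sample.int(n, max_n))
  } else seq_len(n)
  m <- median(dist(x[idx, , drop = FALSE]))
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Grid search over (sigma, C) maximizing the cross-validated harmonic mean
#'
#' Evaluates every grid point with [cross_validated_metrics()] and returns
#' the point with the highest harmonic mean of pooled sensitivity and
#' specificity. Ties are broken by smaller C, then smaller sigma, so the
#' result does not depend on grid ordering.
#'
#' @inheritParams cross_validated_metrics
#' @param config An [svm_config()].
#' @return List with `sigma`, `c`, and `table` (per-grid-point CV metrics).
#' @export
grid_search <- function(fm, labels, config = svm_config(),
                        feature_names = NULL) {
  stopifnot(inherits(config, "svm_config"))
  x <- feature_matrix_of(fm, feature_names)
  sigma_grid <- config$sigma_grid
  if (is.null(sigma_grid)) {
    prep <- compute_preprocess(x)
    xs <- apply_preprocess(x, prep)
    sigma_grid <- median_distance_heuristic(xs, seed = config$seed) *
      2^seq(-4, 4, by = 2)
  }
  grid <- expand.grid(sigma = sigma_grid, c = config$c_grid,
                      KEEP.OUT.ATTRS = FALSE)
  tab <- purrr::pmap(grid, function(sigma, c) {
    m <- cross_validated_metrics(fm, labels, sigma, c, folds = config$folds,
                                 seed = config$seed,
                                 feature_names = feature_names)
    dplyr::bind_cols(tibble::tibble(sigma = sigma, c = c), m)
  }) |> dplyr::bind_rows()
  if (all(!is.finite(tab$harmonic_mean))) {
    stop("all grid points degenerate: no finite harmonic mean", call. = FALSE)
  }
  best <- tab |>
    dplyr::arrange(dplyr::desc(.data$harmonic_mean), .data$c, .data$sigma) |>
    dplyr::slice(1)
  list(sigma = best$sigma, c = best$c, table = tibble::as_tibble(tab))
}

#' Fit the functional-association SVM on all labeled data
#'
#' Fits the soft-margin Gaussian-kernel SVM (kernel
#' `K(x, y) = exp(-||x - y||^2 / (2 sigma^2))`) on the complete labeled set
#' at the chosen hyperparameters. Per-feature median imputation values and
#' min-max scaling bounds are computed here and stored in the model artifact
#' so that prediction is self-contained. The decision threshold is 0.
#'
#' @param fm Feature matrix tibble (with `gene_a`/`gene_b` columns if
#'   training-pair bookkeeping is wanted).
#' @param labels Positive/negative labels, one per row.
#' @param sigma Kernel width.
#' @param c Soft-margin cost.
#' @param feature_names Optional subset of feature columns (e.g. the screened
#'   selection); defaults to all numeric feature columns.
#' @param cv_table Optional grid-search table to store for audit.
#' @return An object of class `fic_model`.
#' @export
fit_association_model <- function(fm, labels, sigma, c,
                                  feature_names = NULL, cv_table = NULL) {
  y <- as_binary_labels(labels)
  feature_names <- feature_names %||% numeric_feature_names(fm)
  x <- feature_matrix_of(fm, feature_names)
  prep <- compute_preprocess(x)
  xs <- apply_preprocess(x, prep)
  fit <- fit_svm_core(xs, y, sigma, c)
  training_pairs <- if (all(c("gene_a", "gene_b") %in% names(fm))) {
    pair_key(fm$gene_a, fm$gene_b)
  } else character()
  structure(
    list(svm = fit, feature_names = feature_names, preprocess = prep,
         sigma = sigma, c = c, threshold = 0,
         n_positive = sum(y), n_negative = sum(!y),
         training_pairs = training_pairs, cv_table = cv_table),
    class = "fic_model"
  )
}

#' @export
print.fic_model <- function(x, ...) {
  cat("<fic_model> Gaussian-kernel SVM: sigma = ", signif(x$sigma, 4),
      ", C = ", signif(x$c, 4), "\n  ", length(x$feature_names),
      " features; trained on ", x$n_positive, " positives / ",
      x$n_negative, " negatives\n", sep = "")
  invisible(x)
}

#' Predict with a fitted functional-association model
#'
#' @param object A `fic_model`.
#' @param fm Feature matrix tibble containing at least the model's feature
#'   columns (an error is raised if any is absent).
#' @param type `"class"` (logical: predicted positive), `"decision"` (raw
#'   oriented decision value), or `"weight"` (decision value squashed into
#'   (0, 1) by the logistic function — the edge weight used when assembling
#'   a predicted interactome).
#' @param ... Unused.
#' @return Vector of predictions, one per row of `fm`.
#' @export
predict.fic_model <- function(object, fm,
                              type = c("class", "decision", "weight"), ...) {
  type <- match.arg(type)
  x <- feature_matrix_of(fm, object$feature_names)
  xs <- apply_preprocess(x, object$preprocess)
  d <- svm_decision(object$svm, xs)
  switch(type,
         class = d > object$threshold,
         decision = d,
         weight = plogis(d))
}

#' Validate a model on an external labeled pair set
#'
#' Computes sensitivity = TP/(TP+FN) over the validation positives and
#' specificity = TN/(TN+FP) over the validation negatives. Validation pairs
#' must be disjoint from the training pairs; overlapping pairs raise an
#' error that lists the offenders.
#'
#' @param model A `fic_model`.
#' @param fm Feature matrix for the validation pairs (with `gene_a`,
#'   `gene_b`).
#' @param labels Positive/negative labels, one per row.
#' @return One-row tibble `sensitivity`, `specificity`, `harmonic_mean` and
#'   confusion counts.
#' @export
external_validation <- function(model, fm, labels) {
  stopifnot(inherits(model, "fic_model"))
  y <- as_binary_labels(labels)
  if (sum(y) == 0) stop("validation set has no positives", call. = FALSE)
  if (sum(!y) == 0) stop("validation set has no negatives", call. = FALSE)
  if (all(c("gene_a", "gene_b") %in% names(fm)) &&
      length(model$training_pairs) > 0) {
    keys <- pair_key(fm$gene_a, fm$gene_b)
    overlap <- keys %in% model$training_pairs
    if (any(overlap)) {
      off <- head(sub("\r", "-", keys[overlap]), 10)
      stop("validation pairs overlap training pairs: ",
           paste(off, collapse = ", "),
           if (sum(overlap) > 10) " ..." else "", call. = FALSE)
    }
  }
  confusion_metrics(y, predict(model, fm, type = "class"))
}
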