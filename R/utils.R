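# Internal helpers shared across modules.

# Canonical unordered pair: lexicographically smaller gene first.
canonical_pairs <- function(gene_a, gene_b) {
  swap <- gene_a > gene_b
  a <- ifelse(swap, gene_b, gene_a)
  b <- ifelse(swap, gene_a, gene_b)
  tibble::tibble(gene_a = a, gene_b = b)
}

# Order-independent key for an unordered pair; "\r" never occurs in gene IDs.
pair_key <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\r")
}

# Enumerate all C(G, 2) unordered pairs over a sorted gene vector.
all_pairs_tbl <- function(genes) {
  genes <- sort(unique(genes))
  idx <- utils::combn(length(genes), 2L)
  tibble::tibble(gene_a = genes[idx[1L, ]], gene_b = genes[idx[2L, ]])
}

#' Harmonic mean of sensitivity and specificity
#'
#' The model-selection target used throughout training: equals 0 when both
#' arguments are 0, and never exceeds the arithmetic mean.
#'
#' @param sensitivity,specificity Numeric vectors in \[0, 1\].
#' @return Numeric vector of harmonic means.
#' @examples
#' harmonic_mean(0.2142, 0.9995)
#' @export
harmonic_mean <- function(sensitivity, specificity) {
  s <- sensitivity + specificity
  ifelse(s > 0, 2 * sensitivity * specificity / s, 0)
}

# Coerce labels to logical (TRUE = positive). Accepts logical, 0/1 numeric,
# or character/factor with values "positive"/"negative".
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1, NA))) {
      stop("numeric labels must be 0/1", call. = FALSE)
    }
    return(labels == 1)
  }
  lab <- as.character(labels)
  ok <- lab %in% c("positive", "negative") | is.na(lab)
  if (!all(ok)) {
    stop("labels must be 'positive'/'negative', logical, or 0/1", call. = FALSE)
  }
  lab == "positive"
}

# Run code under a seed when one is given; otherwise use the current RNG state.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

numeric_feature_names <- function(fm) {
  setdiff(names(fm)[vapply(fm, is.numeric, logical(1))], c("gene_a", "gene_b"))
}
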