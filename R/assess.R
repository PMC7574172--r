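# assess: neighbour-based gene function prediction and time-split
# precision-recall evaluation of an interactome.
#
# The enrichment statistic is an exact hypergeometric upper tail: given a
# gene with n network neighbours in an (N-1)-gene universe (the gene itself
# excluded) of which K genes carry a term, the p-value is the probability of
# seeing >= k term-carrying genes among the n neighbours. A gene's own
# annotations never contribute to its neighbour evidence.

neighbor_counts <- function(net, annotations_known, gene, term) {
  if (!gene %in% net$genes) stop("gene not in universe", call. = FALSE)
  ann <- dplyr::distinct(annotations_known[, c("gene", "term")])
  if (!term %in% ann$term) {
    stop("term '", term, "' absent from known annotations", call. = FALSE)
  }
  nb <- adjacency_list(net)[[gene]]
  carriers <- ann$gene[ann$term == term]
  carriers <- setdiff(carriers, gene)
  list(
    n_universe = length(net$genes) - 1L,
    n_carriers = length(carriers),
    n_neighbors = length(nb),
    k = sum(nb %in% carriers)
  )
}

#' Hypergeometric neighbour-enrichment p-value for one (gene, term)
#'
#' Upper-tail probability of observing at least `k` term-annotated genes
#' among the gene's `n` neighbours, with `K` term-annotated genes in the
#' `N`-gene universe; the query gene is excluded from the universe and from
#' the carrier count. Returns `NA` for a gene with no neighbours (no
#' prediction can be made).
#'
#' @param net An `interactome`.
#' @param annotations_known Tibble with columns `gene`, `term`.
#' @param gene Query gene (must be in the universe).
#' @param term Annotation term (must occur in `annotations_known`).
#' @return p-value in (0, 1\], or `NA` if the gene has no neighbours.
#' @export
neighbor_term_pvalue <- function(net, annotations_known, gene, term) {
  ct <- neighbor_counts(net, annotations_known, gene, term)
  if (ct$n_neighbors == 0) return(NA_real_)
  phyper(ct$k - 1L, ct$n_carriers, ct$n_universe - ct$n_carriers,
         ct$n_neighbors, lower.tail = FALSE)
}

#' Predict new annotations from network neighbourhoods
#'
#' For every gene with at least one neighbour, tests every term carried by at
#' least one neighbour, and reports the (gene, term) pairs with
#' neighbour-enrichment p-value at or below the cutoff — excluding pairs
#' already present in the known annotations, so only new predictions are
#' scored.
#'
#' @param net An `interactome`.
#' @param annotations_known Tibble with columns `gene`, `term`.
#' @param cutoff Significance cutoff in (0, 1\].
#' @return Tibble `gene`, `term`, `p_value`, sorted by p-value.
#' @export
predict_annotations <- function(net, annotations_known, cutoff) {
  stopifnot(cutoff > 0, cutoff <= 1)
  ann <- dplyr::distinct(annotations_known[, c("gene", "term")])
  adj <- adjacency_list(net)
  n_universe_all <- length(net$genes)
  term_count <- table(ann$term)
  known_keys <- paste(ann$gene, ann$term, sep = "\r")
  out <- purrr::map(names(adj), function(g) {
    nb <- adj[[g]]
    nb_terms <- ann[ann$gene %in% nb, ]
    if (nrow(nb_terms) == 0) return(NULL)
    k <- table(nb_terms$term)
    terms <- names(k)
    # carriers excluding the query gene itself
    own <- ann$term[ann$gene == g]
    K <- as.integer(term_count[terms]) - as.integer(terms %in% own)
    N <- n_universe_all - 1L
    p <- phyper(as.integer(k) - 1L, K, N - K, length(nb), lower.tail = FALSE)
    tibble::tibble(gene = g, term = terms, p_value = p)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(gene = character(), term = character(),
                          p_value = numeric()))
  }
  out <- out[out$p_value <= cutoff, ]
  out <- out[!(paste(out$gene, out$term, sep = "\r") %in% known_keys), ]
  dplyr::arrange(out, .data$p_value)
}

#' Time-split precision-recall curve of neighbour-based function prediction
#'
#' At each cutoff, predictions are the new (gene, term) pairs reported by
#' [predict_annotations()]; precision is the share of reported pairs present
#' in the full annotation corpus (known plus newly added), recall is the
#' share of the newly added annotations that are reported. Cutoffs at which
#' nothing is reported are skipped (recorded in the `"skipped_cutoffs"`
#' attribute).
#'
#' @param net An `interactome`.
#' @param annotations_known Annotations available at training time.
#' @param annotations_new Annotations added after the cutoff date (must be
#'   non-empty and disjoint from `annotations_known`).
#' @param cutoffs Vector of significance cutoffs; default 19 log-spaced
#'   points from 1e-10 to 0.1.
#' @return Tibble of class `pr_curve` with columns `cutoff`, `precision`,
#'   `recall`, `n_reported`.
#' @export
precision_recall_curve <- function(net, annotations_known, annotations_new,
                                   cutoffs = 10^seq(-10, -1,
                                                    length.out = 19)) {
  new_keys <- unique(paste(annotations_new$gene, annotations_new$term,
                           sep = "\r"))
  if (length(new_keys) == 0) {
    stop("annotations_new is empty", call. = FALSE)
  }
  known_keys <- unique(paste(annotations_known$gene, annotations_known$term,
                             sep = "\r"))
  if (length(intersect(new_keys, known_keys)) > 0) {
    stop("annotations_new must be disjoint from annotations_known",
         call. = FALSE)
  }
  cutoffs <- sort(cutoffs)
  preds <- predict_annotations(net, annotations_known, max(cutoffs))
  pred_keys <- paste(preds$gene, preds$term, sep = "\r")
  correct_keys <- c(known_keys, new_keys)
  rows <- purrr::map(cutoffs, function(ct) {
    sel <- preds$p_value <= ct
    n_rep <- sum(sel)
    if (n_rep == 0) return(NULL)
    rep_keys <- pred_keys[sel]
    tibble::tibble(
      cutoff = ct,
      precision = sum(rep_keys %in% correct_keys) / n_rep,
      recall = sum(new_keys %in% rep_keys) / length(new_keys),
      n_reported = n_rep
    )
  })
  skipped <- cutoffs[vapply(rows, is.null, logical(1))]
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped_cutoffs") <- skipped
  class(out) <- c("pr_curve", class(out))
  out
}
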