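# features: evidence-feature computation for gene pairs across six categories
# (co-expression, shared annotation, co-localization, domain interaction,
# phylogenetic profile, interolog) and ROC-AUC feature screening.
#
# Each category function takes the raw evidence table(s) plus a canonical
# pair tibble and returns a tibble `gene_a`, `gene_b`, <feature columns>,
# with NA marking pairs for which the evidence is missing (e.g. an
# unannotated gene). Feature columns are prefixed by category so that the
# assembled matrix sorts deterministically by (category, feature).

prep_pairs <- function(pairs) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  canonical_pairs(pairs$gene_a, pairs$gene_b)
}

#' Co-expression features for gene pairs
#'
#' Two features from a gene-by-sample expression matrix: the Pearson
#' correlation of the two expression profiles (`coexpr_pcc`) and the mutual
#' rank score `coexpr_mutual_rank` = 1/sqrt(rank_a(b) * rank_b(a)), where
#' rank_x(y) is the rank of y in x's correlation-sorted list over all genes
#' in the matrix (self excluded, ties averaged). Pairs with a gene absent
#' from the matrix, or with a zero-variance profile, get NA.
#'
#' @param expression Numeric matrix (genes x samples) with gene row names, or
#'   a data frame whose first column is the gene ID.
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @return Tibble `gene_a`, `gene_b`, `coexpr_pcc`, `coexpr_mutual_rank`.
#' @export
coexpression_features <- function(expression, pairs) {
  pairs <- prep_pairs(pairs)
  if (is.data.frame(expression)) {
    m <- as.matrix(expression[, -1, drop = FALSE])
    rownames(m) <- as.character(expression[[1]])
    expression <- m
  }
  if (ncol(expression) < 3) {
    stop("co-expression needs at least 3 samples", call. = FALSE)
  }
  # correlation over genes; zero-variance profiles give NA columns/rows
  cm <- suppressWarnings(cor(t(expression)))
  diag(cm) <- NA
  # rank of each gene in every other gene's descending correlation list
  rk <- apply(cm, 1L, function(v) rank(-v, ties.method = "average",
                                       na.last = "keep"))
  rk <- t(rk)  # rk[x, y] = rank of y among x's correlations
  g <- rownames(cm)
  ia <- match(pairs$gene_a, g)
  ib <- match(pairs$gene_b, g)
  ok <- !is.na(ia) & !is.na(ib)
  pcc <- rep(NA_real_, nrow(pairs))
  mr <- rep(NA_real_, nrow(pairs))
  pcc[ok] <- cm[cbind(ia[ok], ib[ok])]
  ra <- rk[cbind(ia[ok], ib[ok])]
  rb <- rk[cbind(ib[ok], ia[ok])]
  mr[ok] <- 1 / sqrt(ra * rb)
  pairs$coexpr_pcc <- pcc
  pairs$coexpr_mutual_rank <- mr
  pairs
}

#' Shared-annotation features for gene pairs
#'
#' Three features from a gene-to-term annotation table: the number of shared
#' terms (`annot_n_shared`), the Jaccard index of the two term sets
#' (`annot_jaccard`), and a rarity score `annot_rarity` = -log10 of the
#' smallest annotation frequency among the shared terms (0 when no term is
#' shared) — rare shared terms are stronger evidence than ubiquitous ones.
#' Pairs with an unannotated gene get NA.
#'
#' @param annotations Tibble with columns `gene`, `term`.
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @return Tibble `gene_a`, `gene_b`, `annot_n_shared`, `annot_jaccard`,
#'   `annot_rarity`.
#' @export
shared_annotation_features <- function(annotations, pairs) {
  pairs <- prep_pairs(pairs)
  terms_by_gene <- split(annotations$term, annotations$gene)
  n_corpus <- length(terms_by_gene)
  term_freq <- table(unique(annotations[, c("gene", "term")])$term) / n_corpus
  feats <- purrr::map2(pairs$gene_a, pairs$gene_b, function(a, b) {
    ta <- terms_by_gene[[a]]; tb <- terms_by_gene[[b]]
    if (is.null(ta) || is.null(tb)) return(c(NA_real_, NA_real_, NA_real_))
    shared <- intersect(ta, tb)
    n <- length(shared)
    jac <- n / length(union(ta, tb))
    rarity <- if (n > 0) -log10(min(term_freq[shared])) else 0
    c(n, jac, rarity)
  })
  m <- do.call(rbind, feats)
  pairs$annot_n_shared <- m[, 1]
  pairs$annot_jaccard <- m[, 2]
  pairs$annot_rarity <- m[, 3]
  pairs
}

#' Subcellular co-localization features for gene pairs
#'
#' Four features from a gene-to-compartment table: shared-compartment count
#' (`coloc_n_shared`), Jaccard of the compartment sets (`coloc_jaccard`), the
#' maximum over shared compartments of the smaller of the two localization
#' confidences (`coloc_min_conf`; confidences default to 1 when the table has
#' no `confidence` column), and an any-shared indicator (`coloc_any`).
#' Pairs with an unlocalized gene get NA.
#'
#' @param localizations Tibble with columns `gene`, `compartment` and
#'   optionally `confidence` in \[0, 1\].
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @return Tibble with the four `coloc_*` feature columns.
#' @export
colocalization_features <- function(localizations, pairs) {
  pairs <- prep_pairs(pairs)
  if (!"confidence" %in% names(localizations)) localizations$confidence <- 1
  by_gene <- split(localizations[, c("compartment", "confidence")],
                   localizations$gene)
  feats <- purrr::map2(pairs$gene_a, pairs$gene_b, function(a, b) {
    la <- by_gene[[a]]; lb <- by_gene[[b]]
    if (is.null(la) || is.null(lb)) return(rep(NA_real_, 4))
    shared <- intersect(la$compartment, lb$compartment)
    n <- length(shared)
    jac <- n / length(union(la$compartment, lb$compartment))
    conf <- if (n > 0) {
      max(pmin(la$confidence[match(shared, la$compartment)],
               lb$confidence[match(shared, lb$compartment)]))
    } else 0
    c(n, jac, conf, as.numeric(n > 0))
  })
  m <- do.call(rbind, feats)
  pairs$coloc_n_shared <- m[, 1]
  pairs$coloc_jaccard <- m[, 2]
  pairs$coloc_min_conf <- m[, 3]
  pairs$coloc_any <- m[, 4]
  pairs
}

#' Domain-interaction features for gene pairs
#'
#' Four features from per-gene domain content and a symmetric table of
#' domain-pair interaction scores: the number of scored (interacting) domain
#' pairs across the two genes (`domain_n_pairs`), and the max, sum and mean
#' of their scores (`domain_max`, `domain_sum`, `domain_mean`; all 0 when no
#' domain pair is scored). Pairs with a domainless gene get NA.
#'
#' @param domains Tibble with columns `gene`, `domain`.
#' @param domain_scores Tibble with columns `domain_a`, `domain_b`, `score`;
#'   treated as symmetric in the two domains.
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @return Tibble with the four `domain_*` feature columns.
#' @export
domain_features <- function(domains, domain_scores, pairs) {
  pairs <- prep_pairs(pairs)
  by_gene <- split(domains$domain, domains$gene)
  key <- pair_key(domain_scores$domain_a, domain_scores$domain_b)
  score_lut <- setNames(domain_scores$score, key)
  if (anyDuplicated(key)) {
    dup <- duplicated(key)
    if (any(abs(score_lut[key[dup]] - domain_scores$score[dup]) > 1e-12)) {
      stop("conflicting scores for the same domain pair", call. = FALSE)
    }
    score_lut <- score_lut[!dup]
  }
  feats <- purrr::map2(pairs$gene_a, pairs$gene_b, function(a, b) {
    da <- by_gene[[a]]; db <- by_gene[[b]]
    if (is.null(da) || is.null(db)) return(rep(NA_real_, 4))
    combos <- expand.grid(da = da, db = db, stringsAsFactors = FALSE)
    s <- score_lut[pair_key(combos$da, combos$db)]
    s <- s[!is.na(s)]
    if (length(s) == 0) return(c(0, 0, 0, 0))
    c(length(s), max(s), sum(s), mean(s))
  })
  m <- do.call(rbind, feats)
  pairs$domain_n_pairs <- m[, 1]
  pairs$domain_max <- m[, 2]
  pairs$domain_sum <- m[, 3]
  pairs$domain_mean <- m[, 4]
  pairs
}

#' Phylogenetic-profile features for gene pairs
#'
#' Three features from presence/absence profiles over a common species panel:
#' Hamming similarity, i.e. the fraction of species on which the two profiles
#' agree (`phylo_hamming`), the Pearson correlation of the binary profiles
#' (`phylo_pcc`; NA for an all-constant profile), and the Jaccard index of
#' the presence sets (`phylo_jaccard`; NA when both profiles are empty).
#' Pairs with a profile-less gene get NA.
#'
#' @param profiles 0/1 matrix (genes x species) with gene row names, or a
#'   data frame whose first column is the gene ID.
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @return Tibble with the three `phylo_*` feature columns.
#' @export
phylo_features <- function(profiles, pairs) {
  pairs <- prep_pairs(pairs)
  if (is.data.frame(profiles)) {
    m <- as.matrix(profiles[, -1, drop = FALSE])
    rownames(m) <- as.character(profiles[[1]])
    profiles <- m
  }
  ia <- match(pairs$gene_a, rownames(profiles))
  ib <- match(pairs$gene_b, rownames(profiles))
  feats <- purrr::map2(ia, ib, function(i, j) {
    if (is.na(i) || is.na(j)) return(rep(NA_real_, 3))
    pa <- profiles[i, ]; pb <- profiles[j, ]
    hamming <- mean(pa == pb)
    pcc <- if (sd(pa) == 0 || sd(pb) == 0) NA_real_ else cor(pa, pb)
    uni <- sum(pa | pb)
    jac <- if (uni == 0) NA_real_ else sum(pa & pb) / uni
    c(hamming, pcc, jac)
  })
  m <- do.call(rbind, feats)
  pairs$phylo_hamming <- m[, 1]
  pairs$phylo_pcc <- m[, 2]
  pairs$phylo_jaccard <- m[, 3]
  pairs
}

#' Interolog feature for gene pairs
#'
#' Binary interolog transfer: 1 if, in at least one foreign species, some
#' ortholog of gene A interacts with some ortholog of gene B; otherwise 0.
#' Absence of orthologs scores 0 (absence of evidence is scored as no
#' support, not as missing).
#'
#' @param orthologs Tibble with columns `species`, `gene`, `foreign_gene`
#'   (a gene may have several inparalogs per species).
#' @param foreign_edges Tibble with columns `species`, `gene_a`, `gene_b`
#'   giving interactions among foreign genes.
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @return Tibble `gene_a`, `gene_b`, `interolog_any`.
#' @export
interolog_feature <- function(orthologs, foreign_edges, pairs) {
  pairs <- prep_pairs(pairs)
  species <- unique(orthologs$species)
  orth_by_sp <- lapply(
    split(orthologs[, c("gene", "foreign_gene")], orthologs$species),
    function(d) split(d$foreign_gene, d$gene)
  )
  edge_by_sp <- lapply(
    split(foreign_edges[, c("gene_a", "gene_b")], foreign_edges$species),
    function(d) {
      e <- new.env(parent = emptyenv(), size = max(16L, nrow(d)))
      for (k in pair_key(d$gene_a, d$gene_b)) assign(k, TRUE, envir = e)
      e
    }
  )
  hit <- purrr::map2_dbl(pairs$gene_a, pairs$gene_b, function(a, b) {
    for (sp in species) {
      fa <- orth_by_sp[[sp]][[a]]
      fb <- orth_by_sp[[sp]][[b]]
      ed <- edge_by_sp[[sp]]
      if (is.null(fa) || is.null(fb) || is.null(ed)) next
      for (x in fa) for (y in fb) {
        if (x != y && exists(pair_key(x, y), envir = ed, inherits = FALSE)) {
          return(1)
        }
      }
    }
    0
  })
  pairs$interolog_any <- hit
  pairs
}

#' Assemble per-category feature columns into one feature matrix
#'
#' Joins category feature tables on the canonical pair index, checks that all
#' tables cover exactly the same pairs, orders feature columns
#' deterministically (category prefix, then name), and records the
#' missing-value mask as the `"missing_mask"` attribute. Missing values are
#' retained here; imputation happens at training time so that the imputation
#' parameters can be stored with the model.
#'
#' @param ... Feature tibbles as returned by the category functions (each
#'   with `gene_a`, `gene_b` and feature columns).
#' @return A feature-matrix tibble with attribute `"missing_mask"` (logical
#'   matrix, TRUE where the raw value was missing).
#' @export
assemble_feature_matrix <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]])) {
    tabs <- tabs[[1]]
  }
  stopifnot(length(tabs) >= 1)
  base <- tabs[[1]][, c("gene_a", "gene_b")]
  key0 <- pair_key(base$gene_a, base$gene_b)
  out <- tabs[[1]]
  for (tab in tabs[-1]) {
    if (nrow(tab) != nrow(base) ||
        !setequal(pair_key(tab$gene_a, tab$gene_b), key0)) {
      stop("feature tables are not indexed by the same pair set",
           call. = FALSE)
    }
    out <- dplyr::left_join(out, tab, by = c("gene_a", "gene_b"))
  }
  feat_cols <- sort(numeric_feature_names(out))
  out <- out[, c("gene_a", "gene_b", feat_cols)]
  mask <- is.na(as.matrix(out[, feat_cols, drop = FALSE]))
  attr(out, "missing_mask") <- mask
  out
}

#' ROC AUC of a score against binary labels
#'
#' Mann-Whitney form: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties credited 0.5. Missing
#' scores are excluded pairwise.
#'
#' @param values Numeric scores.
#' @param labels Positive/negative labels (logical, 0/1, or
#'   "positive"/"negative").
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(values, labels) {
  y <- as_binary_labels(labels)
  keep <- !is.na(values) & !is.na(y)
  v <- values[keep]; y <- y[keep]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc needs both classes present", call. = FALSE)
  }
  r <- rank(v)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Screen features by ROC AUC
#'
#' Computes the AUC of every feature column against the labels and selects
#' features whose AUC is strictly greater than the cutoff. A feature that is
#' entirely missing on the labeled pairs gets an NA AUC, is not selected, and
#' triggers a warning.
#'
#' @param fm Feature matrix (see [assemble_feature_matrix()]), rows aligned
#'   with `labels`.
#' @param labels Positive/negative labels, one per row of `fm`.
#' @param cutoff AUC selection cutoff (default 0.6; strict `>`).
#' @return A tibble of class `feature_screen` with columns `feature`, `auc`,
#'   `n_used`, `selected`; attribute `"cutoff"`.
#' @export
screen_features <- function(fm, labels, cutoff = 0.6) {
  feat_cols <- numeric_feature_names(fm)
  stopifnot(length(labels) == nrow(fm))
  y <- as_binary_labels(labels)
  rows <- purrr::map(feat_cols, function(f) {
    v <- fm[[f]]
    n_used <- sum(!is.na(v) & !is.na(y))
    auc <- if (all(is.na(v[!is.na(y)]))) {
      warning("feature '", f, "' entirely missing on labeled pairs",
              call. = FALSE)
      NA_real_
    } else {
      roc_auc(v, y)
    }
    tibble::tibble(feature = f, auc = auc, n_used = n_used,
                   selected = !is.na(auc) && auc > cutoff)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("feature_screen", class(out))
  out
}
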