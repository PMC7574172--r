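# Shared fixtures: tiny deterministic networks and a cached small synthetic
# world (built once per test run; all fixtures are generated in code).

toy_net <- function(edges, genes = NULL) {
  interactome(tibble::tibble(gene_a = edges[, 1], gene_b = edges[, 2]),
              genes = genes)
}

# small module-structured world reused across test files
small_world <- local({
  cache <- NULL
  function(seed = 11) {
    if (is.null(cache) || attr(cache, "seed_used") != seed) {
      w <- make_world(
        synth_config(n_genes = 120L, n_modules = 4L, p_in = 0.4,
                     p_out = 0.01, n_samples = 25L),
        seed = seed
      )
      attr(w, "seed_used") <- seed
      cache <<- w
    }
    cache
  }
})

# balanced labeled pairs against the planted truth of a world
world_labels <- function(world, n_per_class = 800, seed = 5) {
  pos <- world$interactome$edges[, c("gene_a", "gene_b")]
  withr::with_seed(seed, {
    pos <- pos[sample(nrow(pos), min(n_per_class, nrow(pos))), ]
  })
  neg <- sample_negatives(world$genes,
                          world$interactome$edges[, c("gene_a", "gene_b")],
                          ratio = 1, seed = seed + 1)
  withr::with_seed(seed + 2, {
    neg <- neg[sample(nrow(neg), min(n_per_class, nrow(neg))), ]
  })
  make_labeled_pairs(pos, neg)
}

# brute-force inter-set link count used as the Q1 oracle
oracle_inter_links <- function(net, set_a, set_b) {
  b2 <- setdiff(set_b, set_a)
  keys <- paste(pmin(net$edges$gene_a, net$edges$gene_b),
                pmax(net$edges$gene_a, net$edges$gene_b))
  n <- 0L
  for (a in set_a) for (b in b2) {
    if (paste(min(a, b), max(a, b)) %in% keys) n <- n + 1L
  }
  n
}

# exhaustive enumeration of simple labeled graphs on `genes` with a given
# degree sequence; returns the inter-set link-count distribution
enumerate_degree_matched <- function(genes, degrees, n_edges_fixed,
                                     set_a, set_b) {
  all_p <- t(utils::combn(genes, 2))
  m <- nrow(all_p)
  combos <- utils::combn(m, n_edges_fixed)
  b2 <- setdiff(set_b, set_a)
  counts <- integer(0)
  for (j in seq_len(ncol(combos))) {
    sel <- combos[, j]
    deg <- table(factor(c(all_p[sel, 1], all_p[sel, 2]), levels = genes))
    if (all(as.integer(deg) == degrees)) {
      links <- sum((all_p[sel, 1] %in% set_a & all_p[sel, 2] %in% b2) |
                     (all_p[sel, 2] %in% set_a & all_p[sel, 1] %in% b2))
      counts <- c(counts, links)
    }
  }
  counts
}
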