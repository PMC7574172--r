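# gsla: gene set linkage analysis. Screens an SDEG (set of differentially
# expressed genes) against a gene-set collection with two complementary
# tests: Q1, whether the inter-set functional-association density exceeds a
# fixed cutoff; and Q2, whether that density is higher than expected in
# degree-preserving randomizations of the network (controlling for gene-set
# composition: hub-rich sets pass Q1 easily but not Q2). Edge weights are
# ignored throughout — density is a count-based notion.

#' GSLA configuration
#'
#' @param density_cutoff Q1 cutoff: report a set only if inter-set density is
#'   strictly greater (default 0.01).
#' @param p_cutoff Q2 cutoff: report only if the permutation p-value is
#'   strictly smaller (default 0.001).
#' @param n_permutations Number of degree-preserving permutations (default
#'   1000). A warning is given when `n_permutations < ceiling(1/p_cutoff)-1`,
#'   since the p-value cutoff is then unattainable.
#' @param swaps_per_edge Double-edge-swap attempts per edge for each
#'   permutation (default 10).
#' @param min_set_size,max_set_size Size window for candidate gene sets.
#' @param seed Seed for the permutation stream.
#' @return A list of class `gsla_config`.
#' @export
gsla_config <- function(density_cutoff = 0.01, p_cutoff = 0.001,
                        n_permutations = 1000L, swaps_per_edge = 10L,
                        min_set_size = 5L, max_set_size = 500L,
                        seed = NULL) {
  stopifnot(density_cutoff >= 0, p_cutoff > 0, p_cutoff <= 1,
            n_permutations >= 1, swaps_per_edge >= 1,
            min_set_size >= 1, max_set_size >= min_set_size)
  if (n_permutations < ceiling(1 / p_cutoff) - 1) {
    warning("n_permutations = ", n_permutations, " cannot attain p < ",
            p_cutoff, " (minimum attainable p is 1/(n_permutations + 1))",
            call. = FALSE)
  }
  structure(list(density_cutoff = density_cutoff, p_cutoff = p_cutoff,
                 n_permutations = as.integer(n_permutations),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size), seed = seed),
            class = "gsla_config")
}

#' Inter-set link density (the Q1 statistic)
#'
#' Overlap genes are removed from the second set (`b' = set_b \ set_a`) so
#' the statistic stays well defined for overlapping sets; density is the
#' number of network edges running between `set_a` and `b'` divided by
#' `|set_a| * |b'|` possible pairs.
#'
#' @param net An `interactome`.
#' @param set_a,set_b Non-empty character vectors of genes from the universe.
#' @return List with `density`, `n_links`, `n_possible`, and a `pairs`
#'   tibble listing the contributing edges (`sdeg` side = `set_a`).
#' @export
inter_set_density <- function(net, set_a, set_b) {
  stopifnot(inherits(net, "interactome"))
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0 || length(set_b) == 0) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  if (!all(c(set_a, set_b) %in% net$genes)) {
    stop("gene sets must be subsets of the network universe", call. = FALSE)
  }
  b2 <- setdiff(set_b, set_a)
  if (length(b2) == 0) {
    stop("set_b is contained in set_a: sets indistinguishable after ",
         "overlap removal", call. = FALSE)
  }
  e <- net$edges
  a_in <- e$gene_a %in% set_a; a_in_b <- e$gene_a %in% b2
  b_in <- e$gene_b %in% set_a; b_in_b <- e$gene_b %in% b2
  hit <- (a_in & b_in_b) | (b_in & a_in_b)
  pairs <- tibble::tibble(
    sdeg_gene = ifelse(e$gene_a[hit] %in% set_a, e$gene_a[hit],
                       e$gene_b[hit]),
    set_gene = ifelse(e$gene_a[hit] %in% set_a, e$gene_b[hit],
                      e$gene_a[hit])
  )
  n_possible <- length(set_a) * length(b2)
  list(density = sum(hit) / n_possible, n_links = sum(hit),
       n_possible = n_possible, pairs = pairs)
}

#' Degree-preserving randomization of a network
#'
#' Randomizes edge placement by repeated double-edge swaps while keeping
#' every gene's neighbour count unchanged; swaps that would create a
#' self-loop or duplicate edge are rejected. A network with fewer than two
#' edges is returned unchanged with a warning. Reproducible under `seed`.
#'
#' @param net An `interactome`.
#' @param n_swap_attempts Number of swap attempts (default 10 per edge).
#' @param seed Integer seed.
#' @return A rewired `interactome` over the same universe with the same
#'   degree sequence (rewired edges carry weight 1, source `"predicted"`).
#' @export
degree_preserving_rewire <- function(net, n_swap_attempts = 10 * n_edges(net),
                                     seed = NULL) {
  stopifnot(inherits(net, "interactome"))
  if (n_edges(net) < 2) {
    warning("network has fewer than 2 edges; returned unchanged",
            call. = FALSE)
    return(net)
  }
  g <- as_igraph(net)
  rw <- with_seed_if(seed, igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE, niter = n_swap_attempts)))
  el <- igraph::as_edgelist(rw, names = TRUE)
  interactome(tibble::tibble(gene_a = el[, 1], gene_b = el[, 2]),
              genes = net$genes)
}

# Count edges between A and B' in an integer edge list given membership
# lookup vectors indexed by vertex id.
count_links_int <- function(el, in_a, in_b2) {
  sum((in_a[el[, 1]] & in_b2[el[, 2]]) | (in_a[el[, 2]] & in_b2[el[, 1]]))
}

#' Degree-preserving permutation p-value (the Q2 test)
#'
#' Compares the observed inter-set density with the densities observed in
#' independently rewired networks (fresh double-edge-swap randomization per
#' permutation, `swaps_per_edge * n_edges` attempts each). The p-value uses
#' the add-one estimator `p = (1 + #(null >= observed)) / (1 + n_perm)`, so
#' it is never 0; an observed density of 0 short-circuits to p = 1.
#'
#' @param net An `interactome`.
#' @param set_a,set_b Gene sets as in [inter_set_density()].
#' @param config A [gsla_config()].
#' @return List with `p_value`, `observed` (the [inter_set_density()]
#'   result), and `null_densities`.
#' @export
q2_pvalue <- function(net, set_a, set_b, config = gsla_config()) {
  stopifnot(inherits(config, "gsla_config"))
  obs <- inter_set_density(net, set_a, set_b)
  if (obs$n_links == 0) {
    return(list(p_value = 1, observed = obs, null_densities = numeric(0)))
  }
  b2 <- setdiff(unique(set_b), unique(set_a))
  g <- as_igraph(net)
  in_a <- net$genes %in% set_a
  in_b2 <- net$genes %in% b2
  niter <- config$swaps_per_edge * n_edges(net)
  nulls <- with_seed_if(config$seed, {
    vapply(seq_len(config$n_permutations), function(i) {
      rw <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                     niter = niter))
      el <- igraph::as_edgelist(rw, names = FALSE)
      count_links_int(el, in_a, in_b2)
    }, numeric(1))
  })
  null_dens <- nulls / obs$n_possible
  p <- (1 + sum(nulls >= obs$n_links)) / (1 + config$n_permutations)
  list(p_value = p, observed = obs, null_densities = null_dens)
}

#' Gene set linkage analysis of an SDEG against a gene-set collection
#'
#' Computes, for every gene set in the collection (after size filtering),
#' the Q1 inter-set density of the SDEG against the set and the Q2
#' degree-preserving permutation p-value. To keep the permutation cost
#' independent of the collection size, each of the `n_permutations` rewired
#' networks is shared across all candidate sets. Hits are the candidates
#' passing both tests (`density > density_cutoff` and `p < p_cutoff`),
#' ranked by p-value then by density (descending). Benjamini-Hochberg
#' q-values across candidates are reported as an extra column.
#'
#' @param net An `interactome`.
#' @param sdeg Character vector: the query gene list (a warning is given
#'   when its size is outside the recommended 50-200 range).
#' @param collection Gene-set collection tibble (see [read_gene_sets()]).
#' @param config A [gsla_config()].
#' @param idmap Optional ID map applied to `sdeg` first; the mapping report
#'   is attached to the result.
#' @return A tibble of class `gsla_result`: one row per candidate set with
#'   `set_id`, `description`, `n_set`, `n_links`, `density`, `p_value`,
#'   `q_value`, `hit`, list-columns `contributing_pairs` and
#'   `sdeg_genes_involved`; attributes `"config"` and `"mapping_report"`.
#' @export
run_gsla <- function(net, sdeg, collection, config = gsla_config(),
                     idmap = NULL) {
  stopifnot(inherits(net, "interactome"), inherits(config, "gsla_config"))
  mapping_report <- NULL
  if (!is.null(idmap)) {
    m <- map_ids(sdeg, idmap)
    mapping_report <- m[c("unmapped", "ambiguous")]
    sdeg <- m$ids
  }
  sdeg <- unique(sdeg)
  if (length(sdeg) == 0) stop("empty SDEG after ID mapping", call. = FALSE)
  if (length(sdeg) < 50 || length(sdeg) > 200) {
    warning("SDEG size ", length(sdeg),
            " is outside the recommended 50-200 range", call. = FALSE)
  }
  sdeg_in <- intersect(sdeg, net$genes)
  sizes <- lengths(collection$genes)
  cand <- collection[sizes >= config$min_set_size &
                       sizes <= config$max_set_size, ]
  if (nrow(cand) == 0) {
    stop("no candidate gene sets within the size window", call. = FALSE)
  }
  # observed statistics per candidate set
  obs <- purrr::map(cand$genes, function(gs) {
    gs <- intersect(gs, net$genes)
    b2 <- setdiff(gs, sdeg_in)
    if (length(sdeg_in) == 0 || length(b2) == 0) {
      return(list(density = 0, n_links = 0L,
                  n_possible = max(1L, length(sdeg_in) * length(b2)),
                  pairs = tibble::tibble(sdeg_gene = character(),
                                         set_gene = character())))
    }
    inter_set_density(net, sdeg_in, gs)
  })
  n_links_obs <- vapply(obs, `[[`, numeric(1), "n_links")
  # shared permutation null across candidate sets
  exceed <- integer(nrow(cand))
  active <- which(n_links_obs > 0)
  if (length(active) > 0 && n_edges(net) >= 2) {
    g <- as_igraph(net)
    in_a <- net$genes %in% sdeg_in
    in_b2_list <- lapply(cand$genes[active], function(gs) {
      net$genes %in% setdiff(intersect(gs, net$genes), sdeg_in)
    })
    niter <- config$swaps_per_edge * n_edges(net)
    with_seed_if(config$seed, {
      for (perm in seq_len(config$n_permutations)) {
        rw <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                       niter = niter))
        el <- igraph::as_edgelist(rw, names = FALSE)
        for (j in seq_along(active)) {
          if (count_links_int(el, in_a, in_b2_list[[j]]) >=
              n_links_obs[active[j]]) {
            exceed[active[j]] <- exceed[active[j]] + 1L
          }
        }
      }
    })
  }
  p <- ifelse(n_links_obs > 0,
              (1 + exceed) / (1 + config$n_permutations), 1)
  out <- tibble::tibble(
    set_id = cand$set_id,
    description = cand$description,
    n_set = lengths(cand$genes),
    n_links = as.integer(n_links_obs),
    density = vapply(obs, `[[`, numeric(1), "density"),
    p_value = p,
    q_value = p.adjust(p, method = "BH"),
    hit = vapply(obs, `[[`, numeric(1), "density") > config$density_cutoff &
      p < config$p_cutoff,
    contributing_pairs = lapply(obs, `[[`, "pairs"),
    sdeg_genes_involved = lapply(obs, function(o) unique(o$pairs$sdeg_gene))
  )
  out <- dplyr::arrange(out, .data$p_value, dplyr::desc(.data$density))
  attr(out, "config") <- config
  attr(out, "mapping_report") <- mapping_report
  attr(out, "sdeg") <- sdeg
  class(out) <- c("gsla_result", class(out))
  out
}

#' Write a GSLA report in the tab-separated web-tool layout
#'
#' A header block of `#`-prefixed parameter lines followed by the candidate
#' table (contributing pairs semicolon-joined).
#'
#' @param result A `gsla_result`.
#' @param path Output path.
#' @param hits_only Write only the reported hits (default TRUE).
#' @return `result`, invisibly.
#' @export
write_gsla_report <- function(result, path, hits_only = TRUE) {
  cfg <- attr(result, "config")
  hdr <- c(
    "# gene set linkage analysis report",
    paste0("# sdeg_size\t", length(attr(result, "sdeg"))),
    paste0("# density_cutoff\t", cfg$density_cutoff),
    paste0("# p_cutoff\t", cfg$p_cutoff),
    paste0("# n_permutations\t", cfg$n_permutations),
    paste0("# swaps_per_edge\t", cfg$swaps_per_edge),
    paste0("# set_size_window\t", cfg$min_set_size, "-", cfg$max_set_size),
    paste0("# seed\t", cfg$seed %||% "NULL"),
    paste0("# n_candidate_sets\t", nrow(result)),
    paste0("# n_hits\t", sum(result$hit))
  )
  tab <- if (hits_only) result[result$hit, ] else result
  flat <- tab |>
    dplyr::mutate(
      contributing_pairs = vapply(.data$contributing_pairs, function(p) {
        paste(paste0(p$sdeg_gene, "-", p$set_gene), collapse = ";")
      }, character(1)),
      sdeg_genes_involved = vapply(.data$sdeg_genes_involved, paste,
                                   character(1), collapse = ";")
    )
  writeLines(hdr, path)
  suppressWarnings(
    utils::write.table(as.data.frame(flat), path, append = TRUE, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  )
  invisible(result)
}
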