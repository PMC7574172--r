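# synth: fully synthetic benchmark world. Plants a module-structured true
# interactome (stochastic block model), then generates evidence tables whose
# derived features discriminate planted edges from non-edges at configured
# AUC targets, an annotation table with dates straddling a cutoff, and SDEG
# lists drawn from perturbed modules. All randomness flows from one root
# seed; identical (config, seed) gives identical worlds.
#
# Calibration: every evidence category is driven by module membership (genes
# in the same module share latent attributes), so a pair's feature
# distribution depends only on whether the pair is intra-module and, for the
# interolog channel, on whether it is a true edge. The per-category effect
# size (factor correlation, attribute adoption probability, profile flip
# rate, transfer rate) is solved numerically so that the theoretical
# Mann-Whitney AUC of the category's primary feature against planted edges
# equals the configured target, accounting for the realized fractions of
# intra-module pairs among edges (h_e) and non-edges (h_n).

#' Synthetic world configuration
#'
#' Defaults describe the benchmark conditions used throughout the test
#' suite: a 500-gene universe in 10 modules, intra-module edge probability
#' 0.3 over a 0.005 background, and all six evidence categories calibrated
#' to AUC 0.75 against the planted edges.
#'
#' @param n_genes Universe size (>= 50).
#' @param n_modules Number of planted modules (>= 2).
#' @param p_in,p_out Intra-/inter-module edge probabilities of the planted
#'   stochastic block model.
#' @param n_samples Expression samples.
#' @param n_species Species in the phylogenetic-profile panel.
#' @param n_foreign_species Foreign species for interolog transfer.
#' @param auc_targets Named vector of per-category AUC targets against the
#'   planted edges (names `coexpr`, `annot`, `coloc`, `domain`, `phylo`,
#'   `interolog`).
#' @param terms_per_module Module-linked annotation terms per module.
#' @param n_background_terms,bg_term_rate Background annotation vocabulary
#'   size and per-gene-per-term rate.
#' @param frac_new_annotations Fraction of annotation rows dated after the
#'   cutoff date (the time-split "new" truth).
#' @param cutoff_date Annotation cutoff date.
#' @param n_background_compartments,extra_compartment_rate Background
#'   compartment pool and per-gene rate of carrying a random one.
#' @param n_noise_domains,noise_domains_per_gene Unscored domain pool.
#' @param ortholog_rate Per-species probability that a gene has an ortholog.
#' @param interolog_bg_rate Per-pair-per-species background foreign-edge
#'   rate.
#' @param n_hubs,hub_degree Optional scale-free-style overlay: `n_hubs`
#'   genes each receive `hub_degree` extra random edges (for
#'   hub-confounding experiments; 0 by default).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 500L, n_modules = 10L, p_in = 0.3,
                         p_out = 0.005, n_samples = 30L, n_species = 20L,
                         n_foreign_species = 7L,
                         auc_targets = c(coexpr = 0.75, annot = 0.75,
                                         coloc = 0.75, domain = 0.75,
                                         phylo = 0.75, interolog = 0.75),
                         terms_per_module = 4L, n_background_terms = 30L,
                         bg_term_rate = 0.02, frac_new_annotations = 0.2,
                         cutoff_date = as.Date("2017-12-31"),
                         n_background_compartments = 20L,
                         extra_compartment_rate = 0.3,
                         n_noise_domains = 100L,
                         noise_domains_per_gene = 2L,
                         ortholog_rate = 0.7, interolog_bg_rate = 0.01,
                         n_hubs = 0L, hub_degree = 30L) {
  need <- c("coexpr", "annot", "coloc", "domain", "phylo", "interolog")
  stopifnot(n_genes >= 50, n_modules >= 2,
            p_in > p_out, p_in <= 1, p_out >= 0,
            n_samples >= 5, n_species >= 4, n_foreign_species >= 1,
            all(need %in% names(auc_targets)),
            all(auc_targets > 0.5 & auc_targets < 1))
  if (n_modules > n_genes / 5) {
    stop("module sizes inconsistent with universe: n_modules too large for ",
         "n_genes", call. = FALSE)
  }
  structure(as.list(environment())[names(formals(synth_config))],
            class = "synth_config")
}

# ---- AUC machinery --------------------------------------------------------

# Mann-Whitney AUC between two pmfs on the same 0-based integer support.
auc_from_pmfs <- function(p_pos, p_neg) {
  n <- max(length(p_pos), length(p_neg))
  p_pos <- c(p_pos, rep(0, n - length(p_pos)))
  p_neg <- c(p_neg, rep(0, n - length(p_neg)))
  f_neg_before <- c(0, cumsum(p_neg)[-n])
  sum(p_pos * (f_neg_before + 0.5 * p_neg))
}

conv_pmf <- function(p, q) {
  r <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    idx <- i:(i + length(q) - 1L)
    r[idx] <- r[idx] + p[i] * q
  }
  r
}

mix_pmf <- function(pmf1, pmf0, w) {
  n <- max(length(pmf1), length(pmf0))
  w * c(pmf1, rep(0, n - length(pmf1))) +
    (1 - w) * c(pmf0, rep(0, n - length(pmf0)))
}

# AUC of a module-driven count feature: pmf1 under intra-module, pmf0 under
# inter-module, mixed with the intra fractions among edges / non-edges.
auc_module_counts <- function(pmf1, pmf0, h_e, h_n) {
  auc_from_pmfs(mix_pmf(pmf1, pmf0, h_e), mix_pmf(pmf1, pmf0, h_n))
}

calibrate <- function(f, target, lower, upper, what) {
  flo <- f(lower) - target
  fhi <- f(upper) - target
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    stop("AUC target ", target, " unattainable for ", what,
         " under this configuration (attainable range ",
         signif(min(f(lower), f(upper)), 3), "-",
         signif(max(f(lower), f(upper)), 3), ")", call. = FALSE)
  }
  uniroot(function(x) f(x) - target, c(lower, upper), tol = 1e-9)$root
}

# ---- world generation -----------------------------------------------------

#' Generate a synthetic world
#'
#' Plants the true interactome and all evidence tables (see
#' [synth_config()]). For every category a "noise" counterpart table is also
#' generated by permuting gene labels of signal-shaped evidence, which
#' preserves the marginal value distribution exactly while destroying any
#' correlation with the planted edges (expected AUC 0.5).
#'
#' @param config A [synth_config()].
#' @param seed Integer root seed; the world is fully reproducible from
#'   (config, seed).
#' @return An object of class `synthetic_world`: list with `genes`,
#'   `modules` (tibble `gene`, `module`), `interactome` (the planted truth),
#'   `evidence`, `noise` (per-category tables), `params` (realized h_e/h_n
#'   and calibrated effect sizes), `collection` (module gene sets), `config`,
#'   `seed`.
#' @export
make_world <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  withr::with_seed(as.integer(seed), {
    g_n <- cfg$n_genes
    genes <- sprintf("g%05d", seq_len(g_n))
    module <- sample(rep_len(seq_len(cfg$n_modules), g_n))
    modules <- tibble::tibble(gene = genes, module = module)

    # planted truth: stochastic block model (+ optional hub overlay)
    idx <- utils::combn(g_n, 2L)
    same <- module[idx[1L, ]] == module[idx[2L, ]]
    edge <- runif(ncol(idx)) < ifelse(same, cfg$p_in, cfg$p_out)
    if (cfg$n_hubs > 0) {
      hubs <- sample.int(g_n, cfg$n_hubs)
      hub_hit <- (idx[1L, ] %in% hubs) | (idx[2L, ] %in% hubs)
      extra_p <- cfg$n_hubs * cfg$hub_degree /
        max(1, sum(hub_hit))
      edge <- edge | (hub_hit & runif(ncol(idx)) < extra_p)
    }
    truth <- interactome(
      tibble::tibble(gene_a = genes[idx[1L, edge]],
                     gene_b = genes[idx[2L, edge]],
                     weight = 1, source = "known"),
      genes = genes
    )
    h_e <- mean(same[edge])
    h_n <- mean(same[!edge])

    # ---- per-category calibration to the AUC targets ----
    tgt <- cfg$auc_targets
    tau <- 1 / sqrt(cfg$n_samples - 3)
    mu <- calibrate(function(m) {
      h_e * (1 - h_n) * stats::pnorm(m / (sqrt(2) * tau)) +
        (1 - h_e) * h_n * stats::pnorm(-m / (sqrt(2) * tau)) +
        (h_e * h_n + (1 - h_e) * (1 - h_n)) * 0.5
    }, tgt[["coexpr"]], 1e-6, 10, "co-expression")
    rho <- tanh(mu)  # shared-factor weight: intra-module population pcc

    t_m <- cfg$terms_per_module
    b_t <- cfg$n_background_terms
    pmf_bg_terms <- dbinom(0:b_t, b_t, cfg$bg_term_rate^2)
    pa <- calibrate(function(p) {
      pmf1 <- conv_pmf(dbinom(0:t_m, t_m, p^2), pmf_bg_terms)
      auc_module_counts(pmf1, pmf_bg_terms, h_e, h_n)
    }, tgt[["annot"]], 1e-3, 0.999, "shared annotation")

    # sharing probabilities conditional on both genes being localized at
    # all, because feature AUC excludes unlocalized (NA) pairs pairwise
    bg_share <- cfg$extra_compartment_rate^2 / cfg$n_background_compartments
    er <- cfg$extra_compartment_rate
    pl <- calibrate(function(p) {
      p_loc <- 1 - (1 - p) * (1 - er)
      p1 <- min(1, (1 - (1 - p^2) * (1 - bg_share)) / p_loc^2)
      p0 <- min(1, bg_share / p_loc^2)
      auc_module_counts(c(1 - p1, p1), c(1 - p0, p0), h_e, h_n)
    }, tgt[["coloc"]], 1e-3, 0.999, "co-localization")
    p_loc <- 1 - (1 - pl) * (1 - er)
    coloc_p1 <- min(1, (1 - (1 - pl^2) * (1 - bg_share)) / p_loc^2)
    coloc_p0 <- min(1, bg_share / p_loc^2)

    pd <- calibrate(function(p) {
      auc_module_counts(dbinom(0:2, 2, p^2), c(1, 0, 0), h_e, h_n)
    }, tgt[["domain"]], 1e-3, 0.999, "domain interaction")

    p_sp <- cfg$n_species
    eps <- calibrate(function(e) {
      c1 <- e^2 + (1 - e)^2
      auc_module_counts(dbinom(0:p_sp, p_sp, c1),
                        dbinom(0:p_sp, p_sp, 0.5), h_e, h_n)
    }, tgt[["phylo"]], 1e-3, 0.499, "phylogenetic profile")

    k_sp <- cfg$n_foreign_species
    r0 <- cfg$interolog_bg_rate
    pmf_b <- dbinom(0:k_sp, k_sp, cfg$ortholog_rate^2)
    q0 <- 1 - sum(pmf_b * (1 - r0)^(0:k_sp))
    r1 <- calibrate(function(r) {
      q1 <- 1 - sum(pmf_b * ((1 - r0) * (1 - r))^(0:k_sp))
      q1 * (1 - q0) + 0.5 * (q1 * q0 + (1 - q1) * (1 - q0))
    }, tgt[["interolog"]], 1e-4, 0.9999, "interolog")
    q1 <- 1 - sum(pmf_b * ((1 - r0) * (1 - r1))^(0:k_sp))

    # ---- evidence tables ----
    s_n <- cfg$n_samples
    factor_mat <- matrix(rnorm(cfg$n_modules * s_n), cfg$n_modules, s_n)
    expr <- sqrt(rho) * factor_mat[module, , drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(g_n * s_n), g_n, s_n)
    rownames(expr) <- genes
    colnames(expr) <- sprintf("s%02d", seq_len(s_n))

    gen_annotations <- function(module_of) {
      mod_terms <- lapply(seq_len(cfg$n_modules), function(m) {
        sprintf("T%02d_%d", m, seq_len(t_m))
      })
      rows_mod <- purrr::map2(genes, module_of, function(g, m) {
        t <- mod_terms[[m]][runif(t_m) < pa]
        if (length(t)) tibble::tibble(gene = g, term = t) else NULL
      })
      bg_terms <- sprintf("B%02d", seq_len(b_t))
      bg_hit <- which(matrix(runif(g_n * b_t) < cfg$bg_term_rate, g_n, b_t),
                      arr.ind = TRUE)
      ann <- dplyr::bind_rows(
        dplyr::bind_rows(rows_mod),
        tibble::tibble(gene = genes[bg_hit[, 1]], term = bg_terms[bg_hit[, 2]])
      )
      is_new <- runif(nrow(ann)) < cfg$frac_new_annotations
      ann$date <- as.Date(ifelse(
        is_new,
        cfg$cutoff_date + sample.int(200L, nrow(ann), replace = TRUE),
        cfg$cutoff_date - sample.int(1000L, nrow(ann), replace = TRUE) + 1L
      ), origin = "1970-01-01")
      ann
    }
    annotations <- gen_annotations(module)

    gen_localization <- function(module_of) {
      has_mod <- runif(g_n) < pl
      mod_rows <- tibble::tibble(
        gene = genes[has_mod],
        compartment = sprintf("C%02d", module_of[has_mod]),
        confidence = runif(sum(has_mod), 0.5, 1)
      )
      has_bg <- runif(g_n) < cfg$extra_compartment_rate
      bg_rows <- tibble::tibble(
        gene = genes[has_bg],
        compartment = sprintf("BGC%02d",
                              sample.int(cfg$n_background_compartments,
                                         sum(has_bg), replace = TRUE)),
        confidence = runif(sum(has_bg), 0.5, 1)
      )
      dplyr::bind_rows(mod_rows, bg_rows)
    }
    localization <- gen_localization(module)

    gen_domains <- function(module_of) {
      has_u <- runif(g_n) < pd
      has_v <- runif(g_n) < pd
      noise <- tibble::tibble(
        gene = rep(genes, each = cfg$noise_domains_per_gene),
        domain = sprintf("ND%03d",
                         sample.int(cfg$n_noise_domains,
                                    g_n * cfg$noise_domains_per_gene,
                                    replace = TRUE))
      )
      dplyr::bind_rows(
        tibble::tibble(gene = genes[has_u],
                       domain = sprintf("DU%02d", module_of[has_u])),
        tibble::tibble(gene = genes[has_v],
                       domain = sprintf("DV%02d", module_of[has_v])),
        noise
      ) |> dplyr::distinct()
    }
    domains <- gen_domains(module)
    domain_scores <- tibble::tibble(
      domain_a = sprintf("DU%02d", seq_len(cfg$n_modules)),
      domain_b = sprintf("DV%02d", seq_len(cfg$n_modules)),
      score = runif(cfg$n_modules, 0.6, 0.95)
    )

    base_profiles <- matrix(rbinom(cfg$n_modules * p_sp, 1, 0.5),
                            cfg$n_modules, p_sp)
    flip <- matrix(runif(g_n * p_sp) < eps, g_n, p_sp)
    profiles <- abs(base_profiles[module, , drop = FALSE] - flip)
    rownames(profiles) <- genes
    colnames(profiles) <- sprintf("sp%02d", seq_len(p_sp))

    orth <- purrr::map(seq_len(k_sp), function(s) {
      has <- runif(g_n) < cfg$ortholog_rate
      tibble::tibble(species = sprintf("fs%d", s), gene = genes[has],
                     foreign_gene = paste0("fs", s, ":", genes[has]))
    }) |> dplyr::bind_rows()
    orth_lut <- split(orth$foreign_gene, paste(orth$species, orth$gene))
    true_e <- truth$edges
    f_edges <- purrr::map(seq_len(k_sp), function(s) {
      sp <- sprintf("fs%d", s)
      fa <- orth_lut[paste(sp, true_e$gene_a)]
      fb <- orth_lut[paste(sp, true_e$gene_b)]
      ok <- !vapply(fa, is.null, logical(1)) &
        !vapply(fb, is.null, logical(1)) &
        runif(nrow(true_e)) < r1
      sig <- tibble::tibble(species = sp,
                            gene_a = unlist(fa[ok]), gene_b = unlist(fb[ok]))
      sp_genes <- orth$foreign_gene[orth$species == sp]
      n_bg <- rbinom(1, choose(length(sp_genes), 2), r0)
      bg <- if (n_bg > 0) {
        a <- sample(sp_genes, n_bg, replace = TRUE)
        b <- sample(sp_genes, n_bg, replace = TRUE)
        tibble::tibble(species = sp, gene_a = a, gene_b = b)[a != b, ]
      } else NULL
      dplyr::bind_rows(sig, bg)
    }) |> dplyr::bind_rows()

    # ---- noise counterparts: signal-shaped evidence, permuted genes ----
    permute_genes <- function(tbl, col = "gene") {
      perm <- setNames(sample(genes), genes)
      tbl[[col]] <- unname(perm[tbl[[col]]])
      tbl
    }
    factor2 <- matrix(rnorm(cfg$n_modules * s_n), cfg$n_modules, s_n)
    expr_noise <- sqrt(rho) * factor2[module, , drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(g_n * s_n), g_n, s_n)
    rownames(expr_noise) <- sample(genes)
    colnames(expr_noise) <- colnames(expr)
    profiles_noise <- profiles[sample(g_n), , drop = FALSE]
    rownames(profiles_noise) <- genes
    noise <- list(
      expression = expr_noise,
      annotations = permute_genes(gen_annotations(module)),
      localization = permute_genes(gen_localization(module)),
      domains = permute_genes(gen_domains(module)),
      domain_scores = domain_scores,
      profiles = profiles_noise,
      orthologs = permute_genes(orth),
      foreign_edges = f_edges
    )

    collection <- tibble::tibble(
      set_id = sprintf("module_%02d", seq_len(cfg$n_modules)),
      description = sprintf("genes of planted module %d",
                            seq_len(cfg$n_modules)),
      genes = split(genes, module)[as.character(seq_len(cfg$n_modules))]
    )

    structure(list(
      config = cfg, seed = as.integer(seed), genes = genes,
      modules = modules, interactome = truth,
      evidence = list(expression = expr, annotations = annotations,
                      localization = localization, domains = domains,
                      domain_scores = domain_scores, profiles = profiles,
                      orthologs = orth, foreign_edges = f_edges),
      noise = noise,
      params = list(h_e = h_e, h_n = h_n, tau = tau, mu = mu, rho = rho,
                    pa = pa, pl = pl, pd = pd, eps = eps, r0 = r0, r1 = r1,
                    q0 = q0, q1 = q1, bg_share = bg_share,
                    coloc_p1 = coloc_p1, coloc_p0 = coloc_p0),
      collection = collection
    ), class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", length(x$genes), " genes, ",
      x$config$n_modules, " modules, ", n_edges(x$interactome),
      " planted edges (h_e = ", signif(x$params$h_e, 3), ")\n", sep = "")
  invisible(x)
}

#' Draw an SDEG from a planted module
#'
#' Emulates a list of top differentially expressed genes concentrated in one
#' functional module: `(1 - contamination) * n` genes from the module, the
#' rest drawn uniformly from outside it.
#'
#' @param world A `synthetic_world`.
#' @param module_id Module to perturb.
#' @param n SDEG size.
#' @param contamination Fraction of off-module genes in \[0, 1\].
#' @param seed Integer seed.
#' @return Character vector of `n` genes.
#' @export
make_sdeg <- function(world, module_id, n, contamination = 0, seed = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!module_id %in% world$modules$module) {
    stop("unknown module_id: ", module_id, call. = FALSE)
  }
  in_mod <- world$modules$gene[world$modules$module == module_id]
  out_mod <- setdiff(world$genes, in_mod)
  n_mod <- round((1 - contamination) * n)
  n_out <- n - n_mod
  if (n_mod > length(in_mod) || n_out > length(out_mod)) {
    stop("requested SDEG larger than the available module/contamination ",
         "pool", call. = FALSE)
  }
  with_seed_if(seed, c(sample(in_mod, n_mod), sample(out_mod, n_out)))
}

#' Compute the evidence feature matrix of a synthetic world
#'
#' Runs the feature-computation functions of the package on the world's
#' evidence tables. `features = "primary"` yields the six calibrated
#' per-category signal features; `"all"` yields every implemented feature.
#' With `include_noise = TRUE`, one noise feature per category (the primary
#' feature computed on the permuted-label noise evidence) is appended under
#' a `noise_` prefix.
#'
#' @param world A `synthetic_world`.
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @param features `"primary"` or `"all"`.
#' @param include_noise Append the per-category noise features?
#' @return A feature matrix (see [assemble_feature_matrix()]).
#' @export
world_feature_matrix <- function(world, pairs,
                                 features = c("primary", "all"),
                                 include_noise = TRUE) {
  stopifnot(inherits(world, "synthetic_world"))
  features <- match.arg(features)
  ev <- world$evidence
  primary <- c("coexpr_pcc", "annot_n_shared", "coloc_any", "domain_n_pairs",
               "phylo_hamming", "interolog_any")
  tabs <- list(
    coexpression_features(ev$expression, pairs),
    shared_annotation_features(ev$annotations, pairs),
    colocalization_features(ev$localization, pairs),
    domain_features(ev$domains, ev$domain_scores, pairs),
    phylo_features(ev$profiles, pairs),
    interolog_feature(ev$orthologs, ev$foreign_edges, pairs)
  )
  if (features == "primary") {
    tabs <- lapply(tabs, function(t) {
      t[, c("gene_a", "gene_b", intersect(primary, names(t)))]
    })
  }
  if (include_noise) {
    nz <- world$noise
    noise_tabs <- list(
      coexpression_features(nz$expression, pairs)[
        , c("gene_a", "gene_b", "coexpr_pcc")],
      shared_annotation_features(nz$annotations, pairs)[
        , c("gene_a", "gene_b", "annot_n_shared")],
      colocalization_features(nz$localization, pairs)[
        , c("gene_a", "gene_b", "coloc_any")],
      domain_features(nz$domains, nz$domain_scores, pairs)[
        , c("gene_a", "gene_b", "domain_n_pairs")],
      phylo_features(nz$profiles, pairs)[
        , c("gene_a", "gene_b", "phylo_hamming")],
      interolog_feature(nz$orthologs, nz$foreign_edges, pairs)[
        , c("gene_a", "gene_b", "interolog_any")]
    )
    noise_tabs <- purrr::map(noise_tabs, function(t) {
      names(t)[3] <- paste0("noise_", names(t)[3])
      t
    })
    tabs <- c(tabs, noise_tabs)
  }
  assemble_feature_matrix(tabs)
}

#' Generative Bayes reference score for synthetic pairs
#'
#' The log-likelihood ratio log P(features | edge) / P(features | non-edge)
#' computed from the world's true generation parameters: the module-driven
#' categories enter through the latent intra-module indicator (mixed with
#' the realized intra fractions h_e / h_n), the interolog channel enters
#' directly, and noise features cancel. On the primary-feature set this is
#' the exact Bayes-optimal ranking score for the generative model, used as
#' the reference against which trained classifiers are compared.
#'
#' @param world A `synthetic_world`.
#' @param fm Feature matrix containing the six primary features (see
#'   [world_feature_matrix()]).
#' @return Numeric vector of log-likelihood ratios, one per row of `fm`.
#' @export
world_bayes_score <- function(world, fm) {
  stopifnot(inherits(world, "synthetic_world"))
  p <- world$params
  cfg <- world$config
  floor_p <- 1e-12
  n <- nrow(fm)
  l1 <- matrix(1, n, 5)  # per module-driven feature: P(x | intra)
  l0 <- matrix(1, n, 5)  # P(x | inter)

  z <- atanh(pmin(pmax(fm$coexpr_pcc, -0.9999), 0.9999))
  ok <- !is.na(z)
  l1[ok, 1] <- dnorm(z[ok], p$mu, p$tau)
  l0[ok, 1] <- dnorm(z[ok], 0, p$tau)

  t_m <- cfg$terms_per_module; b_t <- cfg$n_background_terms
  pmf_bg <- dbinom(0:b_t, b_t, cfg$bg_term_rate^2)
  pmf1_a <- conv_pmf(dbinom(0:t_m, t_m, p$pa^2), pmf_bg)
  k <- fm$annot_n_shared
  ok <- !is.na(k) & k >= 0 & k <= t_m + b_t
  l1[ok, 2] <- pmax(pmf1_a[k[ok] + 1], floor_p)
  l0[ok, 2] <- pmax(c(pmf_bg, rep(0, t_m))[k[ok] + 1], floor_p)

  x <- fm$coloc_any
  ok <- !is.na(x)
  l1[ok, 3] <- pmax(ifelse(x[ok] > 0, p$coloc_p1, 1 - p$coloc_p1), floor_p)
  l0[ok, 3] <- pmax(ifelse(x[ok] > 0, p$coloc_p0, 1 - p$coloc_p0), floor_p)

  k <- fm$domain_n_pairs
  ok <- !is.na(k) & k >= 0 & k <= 2
  l1[ok, 4] <- pmax(dbinom(k[ok], 2, p$pd^2), floor_p)
  l0[ok, 4] <- pmax(as.numeric(k[ok] == 0), floor_p)

  p_sp <- cfg$n_species
  c1 <- p$eps^2 + (1 - p$eps)^2
  agree <- round(fm$phylo_hamming * p_sp)
  ok <- !is.na(agree)
  l1[ok, 5] <- pmax(dbinom(agree[ok], p_sp, c1), floor_p)
  l0[ok, 5] <- pmax(dbinom(agree[ok], p_sp, 0.5), floor_p)

  log_lik1 <- rowSums(log(l1))  # module-driven block given intra
  log_lik0 <- rowSums(log(l0))  # given inter
  # mix over the latent intra-module indicator
  mix <- function(h) {
    m <- pmax(log_lik1, log_lik0)
    m + log(h * exp(log_lik1 - m) + (1 - h) * exp(log_lik0 - m))
  }
  llr <- mix(p$h_e) - mix(p$h_n)
  xi <- fm$interolog_any
  ok <- !is.na(xi)
  llr[ok] <- llr[ok] +
    log(ifelse(xi[ok] > 0, p$q1, 1 - p$q1)) -
    log(ifelse(xi[ok] > 0, p$q0, 1 - p$q0))
  llr
}

#' Write the synthetic world's tables in the formats the other modules read
#'
#' Emits the planted interactome as a TSV edge list, the annotation table,
#' localization/domain/profile/ortholog tables as TSVs, the module gene
#' sets as GMT, and the expression matrix as a TSV with a header of sample
#' IDs.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(dir, ...)
  write_edge_list(world$interactome, f("interactome.tsv"))
  ev <- world$evidence
  readr::write_tsv(
    dplyr::mutate(ev$annotations, date = as.character(date)),
    f("annotations.tsv"), col_names = FALSE)
  readr::write_tsv(ev$localization, f("localization.tsv"))
  readr::write_tsv(ev$domains, f("domains.tsv"))
  readr::write_tsv(ev$domain_scores, f("domain_scores.tsv"))
  readr::write_tsv(ev$orthologs, f("orthologs.tsv"))
  readr::write_tsv(ev$foreign_edges, f("foreign_edges.tsv"))
  expr <- tibble::as_tibble(ev$expression, rownames = "gene")
  readr::write_tsv(expr, f("expression.tsv"))
  prof <- tibble::as_tibble(ev$profiles, rownames = "gene")
  readr::write_tsv(prof, f("profiles.tsv"))
  gmt <- vapply(seq_len(nrow(world$collection)), function(i) {
    paste(c(world$collection$set_id[i], world$collection$description[i],
            world$collection$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, f("modules.gmt"))
  invisible(dir)
}
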