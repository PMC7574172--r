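# Evidence-feature computation and ROC-AUC screening.

pairs_of <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(gene_a = m[, 1], gene_b = m[, 2])
}

test_that("co-expression features: correlation endpoints and mutual rank oracle", {
  ex <- rbind(gA = c(1, 2, 3, 4), gB = c(1, 2, 3, 4), gC = c(3, 2, 1, 0),
              gD = c(1, 3, 2, 5))
  cf <- coexpression_features(ex, pairs_of("gA", "gB", "gA", "gC"))
  expect_equal(cf$coexpr_pcc, c(1, -1))

  # brute-force all-pairs correlation + rank oracle on a 4-gene matrix
  cm <- cor(t(ex)); diag(cm) <- NA
  oracle_mr <- function(a, b) {
    ra <- rank(-cm[a, ], na.last = "keep")[b]
    rb <- rank(-cm[b, ], na.last = "keep")[a]
    1 / sqrt(ra * rb)
  }
  p <- pairs_of("gA", "gD", "gC", "gD", "gA", "gB")
  cf2 <- coexpression_features(ex, p)
  expect_equal(cf2$coexpr_mutual_rank,
               mapply(oracle_mr, p$gene_a, p$gene_b),
               ignore_attr = TRUE)

  # zero-variance gene: correlation undefined
  ex2 <- rbind(gA = c(1, 1, 1), gB = c(1, 2, 3))
  expect_true(is.na(
    coexpression_features(ex2, pairs_of("gA", "gB"))$coexpr_pcc))
  expect_error(coexpression_features(ex[, 1:2, drop = FALSE],
                                     pairs_of("gA", "gB")), "3 samples")
})

test_that("shared-annotation features: identity, disjoint, and rarity arithmetic", {
  ann <- tibble::tibble(
    gene = c(rep("gA", 3), rep("gB", 3), "gC", "gD", "gE"),
    term = c("t1", "t2", "t3", "t1", "t2", "t3", "t4", "t4", "t9")
  )
  f <- shared_annotation_features(ann, pairs_of("gA", "gB"))
  expect_equal(f$annot_n_shared, 3)
  expect_equal(f$annot_jaccard, 1)

  f2 <- shared_annotation_features(ann, pairs_of("gA", "gC"))
  expect_equal(f2$annot_n_shared, 0)
  expect_equal(f2$annot_jaccard, 0)
  expect_equal(f2$annot_rarity, 0)

  # two genes share one term annotated to 2 genes of a 100-gene corpus
  big <- dplyr::bind_rows(
    tibble::tibble(gene = c("x1", "x2"), term = "rare"),
    tibble::tibble(gene = sprintf("f%02d", 1:98), term = "common")
  )
  f3 <- shared_annotation_features(big, pairs_of("x1", "x2"))
  expect_equal(f3$annot_rarity, -log10(0.02), tolerance = 1e-12)

  # unannotated gene is missing, not zero
  expect_true(is.na(
    shared_annotation_features(ann, pairs_of("gA", "zz"))$annot_n_shared))
})

test_that("co-localization features follow set algebra", {
  loc <- tibble::tibble(
    gene = c("gA", "gB", "gC", "gD", "gD", "gD", "gE", "gE", "gE"),
    compartment = c("nucleus", "nucleus", "membrane",
                    "A", "B", "C", "B", "C", "D")
  )
  f <- colocalization_features(loc, pairs_of("gA", "gB"))
  expect_equal(f$coloc_n_shared, 1)
  expect_equal(f$coloc_any, 1)
  f2 <- colocalization_features(loc, pairs_of("gA", "gC"))
  expect_equal(unlist(f2[, c("coloc_n_shared", "coloc_jaccard",
                             "coloc_min_conf", "coloc_any")]),
               c(0, 0, 0, 0), ignore_attr = TRUE)
  f3 <- colocalization_features(loc, pairs_of("gD", "gE"))
  expect_equal(f3$coloc_n_shared, 2)
  expect_equal(f3$coloc_jaccard, 0.5)
})

test_that("domain features enumerate scored domain pairs", {
  dom <- tibble::tibble(gene = c("gA", "gB", "gC", "gC", "gD"),
                        domain = c("d1", "d2", "d1", "d2", "d3"))
  sc <- tibble::tibble(domain_a = c("d1", "d2"), domain_b = c("d2", "d3"),
                       score = c(0.9, 0.5))
  f <- domain_features(dom, sc, pairs_of("gA", "gB"))
  expect_equal(unlist(f[, c("domain_n_pairs", "domain_max", "domain_sum")]),
               c(1, 0.9, 0.9), ignore_attr = TRUE)
  # {d1,d2} x {d3}: scores 0.5 for (d2,d3) only under this table
  f2 <- domain_features(dom, sc, pairs_of("gC", "gD"))
  expect_equal(f2$domain_n_pairs, 1)
  # two scored combos: gC {d1,d2} vs gB {d2} -> (d1,d2)=0.9; (d2,d2) unscored
  sc2 <- dplyr::bind_rows(sc, tibble::tibble(domain_a = "d3",
                                             domain_b = "d1", score = 0.2))
  f3 <- domain_features(dom, sc2, pairs_of("gC", "gD"))
  expect_equal(f3$domain_n_pairs, 2)
  expect_equal(f3$domain_max, 0.5)
  expect_equal(f3$domain_sum, 0.7)
  expect_equal(f3$domain_mean, 0.35)
  # no scored pair and missing-domain contracts
  f4 <- domain_features(dom, sc, pairs_of("gA", "gD"))
  expect_equal(f4$domain_n_pairs, 0)
  expect_equal(f4$domain_max, 0)
  expect_true(is.na(domain_features(dom, sc,
                                    pairs_of("gA", "zz"))$domain_n_pairs))
})

test_that("phylogenetic profile features count agreement and presence overlap", {
  pr <- rbind(gA = c(1, 1, 0, 0), gB = c(1, 1, 0, 0), gC = c(0, 0, 1, 1),
              gD = c(1, 0, 1, 0))
  f <- phylo_features(pr, pairs_of("gA", "gB"))
  expect_equal(f$phylo_hamming, 1)
  expect_equal(f$phylo_jaccard, 1)
  f2 <- phylo_features(pr, pairs_of("gA", "gC"))
  expect_equal(f2$phylo_hamming, 0)
  # 1100 vs 1010
  f3 <- phylo_features(pr, pairs_of("gA", "gD"))
  expect_equal(f3$phylo_hamming, 0.5)
  expect_equal(f3$phylo_jaccard, 1 / 3)
  # constant profile: correlation missing
  pr2 <- rbind(gA = c(1, 1, 1), gB = c(1, 0, 1))
  expect_true(is.na(phylo_features(pr2, pairs_of("gA", "gB"))$phylo_pcc))
})

test_that("interolog feature scans all species and scores absence as 0", {
  orth <- tibble::tibble(
    species = c("sp1", "sp1", "sp2", "sp2"),
    gene = c("gA", "gB", "gA", "gB"),
    foreign_gene = c("fA1", "fB1", "fA2", "fB2")
  )
  fe <- tibble::tibble(species = "sp2", gene_a = "fA2", gene_b = "fB2")
  f <- interolog_feature(orth, fe, pairs_of("gA", "gB"))
  expect_equal(f$interolog_any, 1)
  # no foreign interaction anywhere
  f2 <- interolog_feature(orth, fe[0, ], pairs_of("gA", "gB"))
  expect_equal(f2$interolog_any, 0)
  # orthologs exist nowhere: 0, not missing
  f3 <- interolog_feature(orth, fe, pairs_of("gA", "zz"))
  expect_equal(f3$interolog_any, 0)

  # exhaustive species-scan oracle on random small instances
  withr::with_seed(42, {
    for (rep in 1:20) {
      genes <- c("gA", "gB")
      sp <- paste0("s", 1:3)
      o <- tibble::tibble(
        species = rep(sp, each = 2),
        gene = rep(genes, 3),
        foreign_gene = paste0("f", 1:6)
      )[runif(6) < 0.7, ]
      all_f <- t(utils::combn(paste0("f", 1:6), 2))
      fe2 <- tibble::tibble(species = sample(sp, 4, replace = TRUE),
                            gene_a = all_f[1:4, 1], gene_b = all_f[1:4, 2])
      oracle <- 0
      for (s in sp) {
        fa <- o$foreign_gene[o$species == s & o$gene == "gA"]
        fb <- o$foreign_gene[o$species == s & o$gene == "gB"]
        es <- fe2[fe2$species == s, ]
        for (x in fa) for (y in fb) {
          if (any((es$gene_a == x & es$gene_b == y) |
                    (es$gene_a == y & es$gene_b == x))) oracle <- 1
        }
      }
      got <- interolog_feature(o, fe2, pairs_of("gA", "gB"))$interolog_any
      expect_equal(got, oracle)
    }
  })
})

test_that("feature matrices assemble with aligned pairs, sorted columns and a mask", {
  p <- pairs_of("g1", "g2", "g1", "g3", "g2", "g3", "g1", "g4", "g2", "g4")
  t1 <- dplyr::mutate(p, coexpr_pcc = c(0.1, NA, 0.3, 0.4, 0.5))
  t2 <- dplyr::mutate(p, annot_n_shared = 1:5)
  t3 <- dplyr::mutate(p, phylo_hamming = seq(0, 1, length.out = 5))
  fm <- assemble_feature_matrix(t1, t2, t3)
  expect_equal(dim(fm), c(5L, 5L))
  expect_equal(names(fm)[3:5],
               c("annot_n_shared", "coexpr_pcc", "phylo_hamming"))
  mask <- attr(fm, "missing_mask")
  expect_true(mask[2, "coexpr_pcc"])
  expect_equal(sum(mask), 1)
  # mismatched pair set errors
  expect_error(assemble_feature_matrix(t1, t2[1:4, ]), "same pair set")
})

test_that("roc_auc is the Mann-Whitney probability with half-credit ties", {
  # enumerate all four positive/negative comparisons by hand:
  # (2>1) + (2<4 -> 0) + (3>1) + (3<4 -> 0) = 2 of 4
  expect_equal(roc_auc(c(2, 3, 1, 4), c(1, 1, 0, 0)), 0.5)
  expect_equal(roc_auc(c(10, 9, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(7, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # complement identity for tie-free scores
  withr::with_seed(9, {
    for (i in 1:20) {
      v <- sample(seq(0, 1, by = 0.001), 40)
      y <- sample(c(rep(1, 15), rep(0, 25)))
      expect_equal(roc_auc(v, y) + roc_auc(-v, y), 1, tolerance = 1e-12)
    }
  })
})

test_that("similarity features are symmetric in the two genes", {
  w <- small_world()
  withr::with_seed(2, {
    p <- tibble::tibble(gene_a = sample(w$genes, 30),
                        gene_b = sample(w$genes, 30))
    p <- p[p$gene_a != p$gene_b, ]
  })
  swapped <- tibble::tibble(gene_a = p$gene_b, gene_b = p$gene_a)
  fm1 <- world_feature_matrix(w, p, include_noise = FALSE)
  fm2 <- world_feature_matrix(w, swapped, include_noise = FALSE)
  expect_equal(fm1, fm2, ignore_attr = TRUE)
})

test_that("screening selects strictly above the cutoff", {
  # one positive above 3 of 5 negatives: AUC exactly 0.6
  fm <- tibble::tibble(
    gene_a = paste0("a", 1:6), gene_b = paste0("b", 1:6),
    f_exact = c(3.5, 1, 2, 3, 4, 5),
    f_good = c(10, 1, 2, 3, 4, 5),
    f_bad = c(2.5, 1, 2, 3, 4, 5)
  )
  y <- c(1, 0, 0, 0, 0, 0)
  sc <- screen_features(fm, y, cutoff = 0.6)
  expect_equal(sc$auc[sc$feature == "f_exact"], 0.6)
  expect_false(sc$selected[sc$feature == "f_exact"])  # strict inequality
  expect_true(sc$selected[sc$feature == "f_good"])
  expect_false(sc$selected[sc$feature == "f_bad"])
  # cutoff 0 selects every defined feature
  expect_true(all(screen_features(fm, y, cutoff = 0)$selected))
  # entirely-missing feature: warning, NA AUC, not selected
  fm$f_void <- NA_real_
  expect_warning(sc2 <- screen_features(fm, y), "entirely missing")
  expect_false(sc2$selected[sc2$feature == "f_void"])
  expect_true(is.na(sc2$auc[sc2$feature == "f_void"]))
})

test_that("screening separates planted signal from noise features on synthetic data", {
  w <- small_world()
  lp <- world_labels(w, n_per_class = 1000)
  fm <- world_feature_matrix(w, lp[, c("gene_a", "gene_b")])
  sc <- screen_features(fm, lp$label)
  signal <- !startsWith(sc$feature, "noise_")
  expect_true(all(sc$selected[signal]))
  expect_false(any(sc$selected[!signal]))
})
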