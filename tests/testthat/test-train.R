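# Labeled pair construction, cross-validation, grid search, fitting and
# external validation.

# two well-separated 2-d Gaussian clouds (deterministic under seed)
separable_data <- function(n_pos = 40, n_neg = 40, gap = 6, seed = 3) {
  withr::with_seed(seed, {
    x <- rbind(
      cbind(rnorm(n_pos) + gap, rnorm(n_pos) + gap),
      cbind(rnorm(n_neg), rnorm(n_neg))
    )
  })
  fm <- tibble::tibble(
    gene_a = sprintf("p%03da", seq_len(n_pos + n_neg)),
    gene_b = sprintf("p%03db", seq_len(n_pos + n_neg)),
    f1 = x[, 1], f2 = x[, 2]
  )
  list(fm = fm, labels = rep(c("positive", "negative"), c(n_pos, n_neg)))
}

test_that("high-quality PPI filtering requires replication and non-HT support", {
  rec <- tibble::tibble(
    gene_a = c("a", "b", "c", "d", "d"),
    gene_b = c("x", "y", "z", "w", "w"),
    n_studies = c(1L, 3L, 2L, 2L, 2L),
    only_high_throughput = c(FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  out <- filter_high_quality_ppis(rec)
  # single-study removed; HT-only removed; duplicates collapsed
  expect_equal(nrow(out), 2)
  expect_setequal(out$gene_a, c("c", "d"))
  expect_equal(attr(out, "filter_stats")$n_input, 5)
})

test_that("negative sampling hits the exact ratio, reproducibly, without positives", {
  genes <- sprintf("g%02d", 1:30)
  pos <- tibble::tibble(gene_a = c("g01", "g02"), gene_b = c("g02", "g03"))
  neg <- sample_negatives(genes, pos, ratio = 10, seed = 7)
  expect_equal(nrow(neg), 20)
  expect_equal(anyDuplicated(paste(neg$gene_a, neg$gene_b)), 0)
  expect_true(all(neg$gene_a < neg$gene_b))
  pk <- paste(pos$gene_a, pos$gene_b)
  expect_false(any(paste(neg$gene_a, neg$gene_b) %in% pk))
  # determinism and seed sensitivity
  expect_identical(neg, sample_negatives(genes, pos, ratio = 10, seed = 7))
  neg2 <- sample_negatives(genes, pos, ratio = 10, seed = 8)
  expect_false(identical(neg$gene_a, neg2$gene_a) &&
                 identical(neg$gene_b, neg2$gene_b))
})

test_that("negative sampling enumerates the exact complement when demand is high", {
  genes <- c("a", "b", "c", "d")  # 6 pairs
  pos <- tibble::tibble(gene_a = c("a", "c"), gene_b = c("b", "d"))
  neg <- sample_negatives(genes, pos, ratio = 2, seed = 1)
  expect_equal(nrow(neg), 4)
  expect_setequal(paste(neg$gene_a, neg$gene_b),
                  c("a c", "a d", "b c", "b d"))
  expect_error(sample_negatives(genes, pos, ratio = 3, seed = 1),
               "negatives requested")
})

test_that("harmonic mean obeys its identities", {
  expect_equal(harmonic_mean(0.7, 0.7), 0.7)
  expect_equal(harmonic_mean(0, 0.9), 0)
  expect_equal(harmonic_mean(0, 0), 0)
  withr::with_seed(4, {
    s <- runif(50); p <- runif(50)
    expect_true(all(harmonic_mean(s, p) <= (s + p) / 2 + 1e-12))
    expect_true(all(harmonic_mean(s, p) <= pmax(s, p) + 1e-12))
  })
  # the published operating point
  expect_equal(harmonic_mean(0.2142, 0.9995), 0.3528, tolerance = 1e-4)
})

test_that("cross-validation recovers a separable problem and errors on degenerate folds", {
  d <- separable_data()
  m <- cross_validated_metrics(d$fm, d$labels, sigma = 1, c = 4, folds = 5,
                               seed = 1)
  expect_gte(m$sensitivity, 0.95)
  expect_gte(m$specificity, 0.95)
  # minimal input: 2 folds on 4 points, 2 per class
  d4 <- list(fm = d$fm[c(1, 2, 41, 42), ], labels = d$labels[c(1, 2, 41, 42)])
  expect_no_error(cross_validated_metrics(d4$fm, d4$labels, 1, 1, folds = 2))
  expect_error(cross_validated_metrics(d4$fm, d4$labels, 1, 1, folds = 3),
               "folds")
})

test_that("shuffled labels give chance-level sensitivity at the operating point", {
  d <- separable_data(n_pos = 30, n_neg = 90)
  diffs <- withr::with_seed(10, {
    vapply(1:20, function(i) {
      y <- sample(d$labels)
      m <- cross_validated_metrics(d$fm, y, sigma = 1, c = 4, folds = 4,
                                   seed = i)
      frac_pred_pos <- (m$tp + m$fp) / (m$tp + m$fp + m$tn + m$fn)
      m$sensitivity - frac_pred_pos
    }, numeric(1))
  })
  # sensitivity tracks the fraction predicted positive under label shuffles
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("grid search maximizes the harmonic mean with deterministic tie-breaks", {
  d <- separable_data()
  one <- grid_search(d$fm, d$labels,
                     svm_config(sigma_grid = 2, c_grid = 8, folds = 4))
  expect_equal(one$sigma, 2)
  expect_equal(one$c, 8)
  expect_equal(nrow(one$table), 1)

  # a clearly superior point wins; verify against independent evaluation
  cfg <- svm_config(sigma_grid = c(1e-4, 1), c_grid = c(1e-4, 4), folds = 4,
                    seed = 2)
  gs <- grid_search(d$fm, d$labels, cfg)
  indep <- purrr::pmap_dbl(
    expand.grid(sigma = cfg$sigma_grid, c = cfg$c_grid), function(sigma, c) {
      cross_validated_metrics(d$fm, d$labels, sigma, c, folds = 4,
                              seed = 2)$harmonic_mean
    })
  best <- which.max(indep)
  expect_equal(gs$sigma, expand.grid(cfg$sigma_grid, cfg$c_grid)[best, 1])
  expect_equal(gs$c, expand.grid(cfg$sigma_grid, cfg$c_grid)[best, 2])

  # identical harmonic means: smaller C, then smaller sigma, wins;
  # and the result is invariant to grid ordering
  cfg_tie <- svm_config(sigma_grid = c(2, 1), c_grid = c(16, 4), folds = 4)
  tie <- grid_search(d$fm, d$labels, cfg_tie)
  cfg_tie2 <- svm_config(sigma_grid = c(1, 2), c_grid = c(4, 16), folds = 4)
  tie2 <- grid_search(d$fm, d$labels, cfg_tie2)
  expect_equal(tie[c("sigma", "c")], tie2[c("sigma", "c")])
  hm <- tie$table$harmonic_mean
  top <- tie$table[hm == max(hm), ]
  expect_equal(tie$c, min(top$c))
})

test_that("fitting is deterministic and interpolates separable training data", {
  d <- separable_data()
  m1 <- fit_association_model(d$fm, d$labels, sigma = 1, c = 4)
  m2 <- fit_association_model(d$fm, d$labels, sigma = 1, c = 4)
  probe <- separable_data(seed = 99)$fm
  expect_identical(predict(m1, probe, type = "decision"),
                   predict(m2, probe, type = "decision"))
  expect_equal(mean(predict(m1, d$fm) == (d$labels == "positive")), 1)
  expect_error(fit_association_model(d$fm, rep("positive", nrow(d$fm)),
                                     1, 1), "single-class")
  # model refuses feature-incomplete input
  expect_error(predict(m1, d$fm[, 1:3]), "lacks required")
})

test_that("external validation computes the confusion arithmetic and guards overlap", {
  # 1-d threshold model: decision boundary near 0.5
  train_fm <- tibble::tibble(gene_a = sprintf("t%02da", 1:40),
                             gene_b = sprintf("t%02db", 1:40),
                             f1 = rep(c(1, 0), each = 20))
  model <- fit_association_model(train_fm,
                                 rep(c("positive", "negative"), each = 20),
                                 sigma = 0.5, c = 10)
  # 10 positives (3 score high), 1000 negatives (10 score high)
  val_fm <- tibble::tibble(
    gene_a = sprintf("v%04da", 1:1010), gene_b = sprintf("v%04db", 1:1010),
    f1 = c(rep(1, 3), rep(0, 7), rep(1, 10), rep(0, 990))
  )
  labels <- rep(c("positive", "negative"), c(10, 1000))
  m <- external_validation(model, val_fm, labels)
  expect_equal(m$sensitivity, 0.30)
  expect_equal(m$specificity, 0.99)

  # all positives correct
  m2 <- external_validation(model, val_fm[c(1:3, 11:1010), ],
                            labels[c(1:3, 11:1010)])
  expect_equal(m2$sensitivity, 1)

  expect_error(external_validation(model, val_fm,
                                   rep("negative", 1010)), "no positives")
  expect_error(external_validation(model, train_fm,
                                   rep(c("positive", "negative"), each = 20)),
               "overlap")
})
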