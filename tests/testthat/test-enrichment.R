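# Gene-window intersection, hypergeometric/Fisher enrichment, length
# matching and nonparametric metric comparisons.

test_that("flanked gene loci intersect the window tiling correctly", {
  w <- make_windows(c(LG1 = 150000))
  g <- data.frame(chrom = "LG1",
                  start = c(10000, 49500, 0),
                  end = c(12000, 50500, 100),
                  gene_id = c("inner", "boundary", "edge"),
                  stringsAsFactors = FALSE)
  map <- intersect_genes_windows(g, w, flank = 2000)
  expect_equal(map$window_id[map$gene_id == "inner"], "LG1:0-50000")
  expect_setequal(map$window_id[map$gene_id == "boundary"],
                  c("LG1:0-50000", "LG1:50000-100000"))
  # flank clipped at zero, still one valid overlap
  expect_equal(map$window_id[map$gene_id == "edge"], "LG1:0-50000")
  # unknown contig excluded with a warning
  g2 <- rbind(g, data.frame(chrom = "LGX", start = 1, end = 2,
                            gene_id = "lost"))
  expect_warning(m2 <- intersect_genes_windows(g2, w), "excluded")
  expect_false("lost" %in% m2$gene_id)
})

test_that("hypergeometric test matches exhaustive enumeration", {
  u <- paste0("g", 1:10)
  res <- hypergeom_enrichment(paste0("g", 1:4), paste0("g", c(1:4, 9)), u)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  # overlap 0 -> p = 1
  expect_equal(hypergeom_enrichment(character(0), character(0), u)$p, 1)
  # odds ratio of table (3,2;1,4)
  res2 <- hypergeom_enrichment(paste0("g", 1:5), paste0("g", c(1, 2, 3, 6)),
                               u)
  expect_equal(res2$odds_ratio, 6)
  expect_error(hypergeom_enrichment("zz", u[1], u), "subsets")
  # exhaustive enumeration over all overlaps for a universe of <= 30
  withr::local_seed(81)
  for (rep in 1:20) {
    nu <- sample(10:30, 1)
    uu <- paste0("u", seq_len(nu))
    de <- sample(uu, sample(1:nu, 1))
    tg <- sample(uu, sample(1:nu, 1))
    k <- length(intersect(de, tg))
    # enumerate P(X >= k) by summing the point masses directly
    xs <- max(0, length(de) + length(tg) - nu):min(length(de), length(tg))
    pm <- vapply(xs, function(x)
      choose(length(tg), x) * choose(nu - length(tg), length(de) - x) /
        choose(nu, length(de)), numeric(1))
    p_enum <- sum(pm[xs >= k])
    expect_equal(hypergeom_enrichment(de, tg, uu)$p, p_enum,
                 tolerance = 1e-10)
  }
})

test_that("length-matched null sets track the DE length distribution", {
  withr::local_seed(82)
  de <- data.frame(gene_id = paste0("d", 1:100),
                   length = rlnorm(100, log(5000), 0.6))
  pool <- data.frame(gene_id = paste0("n", 1:2000),
                     length = rlnorm(2000, log(2000), 1))
  m1 <- length_matched_null(de, pool, seed = 7)
  expect_identical(m1, length_matched_null(de, pool, seed = 7))
  expect_length(m1, 100)
  # matched pool equals DE lengths exactly when the pool is a copy
  copy <- data.frame(gene_id = paste0("c", 1:100), length = de$length)
  mc <- length_matched_null(de, copy, seed = 1)
  expect_setequal(mc, copy$gene_id)
  # matching beats the raw pool in KS distance in nearly every draw
  ks <- function(a, b) suppressWarnings(ks.test(a, b)$statistic)
  wins <- vapply(1:100, function(s) {
    m <- length_matched_null(de, pool, seed = s)
    ks(de$length, pool$length[match(m, pool$gene_id)]) <
      ks(de$length, pool$length)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
  expect_error(length_matched_null(de, pool[1:50, ]), "not enough")
})

test_that("Kruskal-Wallis / Dunn arithmetic matches closed forms", {
  x <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  dt <- dunn_test(x, g)
  expect_equal(dt$kw$statistic, 7.2, tolerance = 1e-10)
  expect_equal(nrow(dt$dunn), 3)
  expect_equal(dt$dunn$padj, bh_adjust(dt$dunn$p))
  # permuting one sample across groups gives H ~ 0-ish, p large
  withr::local_seed(83)
  xs <- rnorm(30)
  dt0 <- dunn_test(xs, sample(rep(c("a", "b", "c"), 10)))
  expect_gt(dt0$kw$p, 0.05)
  # two groups: KW p equals the Wilcoxon rank-sum p (no ties)
  x2 <- c(rnorm(8), rnorm(8) + 0.5)
  g2 <- rep(c("a", "b"), each = 8)
  expect_equal(dunn_test(x2, g2)$kw$p,
               wilcox.test(x2 ~ factor(g2), correct = FALSE,
                           exact = FALSE)$p.value, tolerance = 1e-10)
})

test_that("metric comparison stratifies by inversion and flags small groups", {
  withr::local_seed(84)
  gm <- data.frame(gene_id = paste0("g", 1:120),
                   fst = c(rnorm(60, 0.3), rnorm(60, 0.02)))
  de <- rep(c("de", "non_de"), 60)
  inside <- rep(c(TRUE, FALSE), each = 60)
  mt <- metric_comparison(gm, de, inside, metrics = "fst")
  expect_equal(nrow(mt), 2)
  expect_setequal(mt$stratum, c("inside", "outside"))
  expect_true(all(is.finite(mt$H)))
  # permuted labels give uniform p-values
  ps <- vapply(1:200, function(i) {
    metric_comparison(gm, sample(de), inside, metrics = "fst")$p[1]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  # a stratum lacking two groups of two genes is reported missing
  mt2 <- metric_comparison(gm[1:3, ], c("de", "de", "de"),
                           c(TRUE, TRUE, TRUE), metrics = "fst")
  expect_true(is.na(mt2$H[mt2$stratum == "inside"]))
})

test_that("term enrichment enforces the minimum-size rules", {
  withr::local_seed(85)
  universe <- paste0("g", 1:500)
  g2t <- rbind(
    data.frame(gene_id = paste0("g", 1:25), term = "planted"),
    data.frame(gene_id = paste0("g", 26:29), term = "tiny"),     # 4 genes
    data.frame(gene_id = sample(universe, 50), term = "random"))
  study <- paste0("g", 1:30)
  res <- term_enrichment(study, g2t, universe)
  expect_equal(res$status, "ok")
  # the 4-gene term is excluded before testing
  expect_false("tiny" %in% res$results$term)
  # a term covering most of the study set but little of the universe wins
  expect_true("planted" %in% res$enriched)
  expect_lt(res$results$p[res$results$term == "planted"], 1e-6)
  # study sets below 20 genes are refused with explicit status
  res19 <- term_enrichment(paste0("g", 1:19), g2t, universe)
  expect_equal(res19$status, "skipped_small_study_set")
  expect_null(res19$results)
})

test_that("composite-outlier enrichment has nominal type-I error under null", {
  withr::local_seed(86)
  universe <- paste0("g", 1:2000)
  target <- paste0("g", 1:200)  # fixed 'outlier gene' set
  hits <- vapply(1:1000, function(i) {
    de <- sample(universe, 150)
    hypergeom_enrichment(de, target, universe)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})
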