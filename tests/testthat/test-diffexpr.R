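# NB dispersion estimation, GLM fitting, Cook's outliers, LFC shrinkage and
# s-value inference.

test_that("dispersion estimates are calibrated on Poisson and NB data", {
  withr::local_seed(31)
  n <- 200
  mu <- 200
  pois <- matrix(rpois(n * 12, mu), n, 12,
                 dimnames = list(paste0("g", 1:n), paste0("s", 1:12)))
  cond <- factor(rep("A", 12))
  dp <- estimate_dispersions(pois, rep(1, 12), cond)
  expect_gt(mean(dp$alpha <= 0.01, na.rm = TRUE), 0.9)
  nb <- matrix(rnbinom(n * 12, mu = mu, size = 5), n, 12,
               dimnames = dimnames(pois))
  dn <- estimate_dispersions(nb, rep(1, 12), cond)
  expect_gt(median(dn$alpha, na.rm = TRUE), 0.1)
  expect_lt(median(dn$alpha, na.rm = TRUE), 0.4)
  # constant counts give the lower clip; all-zero genes are flagged
  cm <- rbind(const = rep(50L, 12), zero = rep(0L, 12),
              ok = rpois(12, 100))
  colnames(cm) <- paste0("s", 1:12)
  dc <- estimate_dispersions(cm, rep(1, 12), cond)
  expect_lt(dc$alpha[["const"]], 1e-3)
  expect_true(dc$flagged[["zero"]])
  expect_true(is.na(dc$alpha[["zero"]]))
})

test_that("NB GLM reproduces group means and is offset-invariant", {
  ex <- small_counts(n_genes = 50, seed = 32)
  sf <- rep(1, 12)
  fit <- fit_nb_glm(ex$counts, sf, rep(0.1, 50), ex$condition)
  # with equal size factors the fitted group mean equals the plain group mean
  gm <- rowMeans(ex$counts[, ex$condition == "A"])
  expect_equal(unname(exp(fit$beta[, "A"])), unname(gm), tolerance = 1e-6)
  # scaling all size factors leaves the fold change unchanged
  fit2 <- fit_nb_glm(ex$counts, sf * 3, rep(0.1, 50), ex$condition)
  lfc1 <- fit$beta[, "A"] - fit$beta[, "B"]
  lfc2 <- fit2$beta[, "A"] - fit2$beta[, "B"]
  expect_equal(lfc1, lfc2, tolerance = 1e-6)
  # contrast antisymmetry is exact
  r_ab <- de_contrast(fit, c("A", "B"))
  r_ba <- de_contrast(fit, c("B", "A"))
  expect_equal(r_ab$lfc_mle, -r_ba$lfc_mle)
  # a group of all zeros lands at the expansion bound and is flagged
  cm <- ex$counts
  cm[1, ex$condition == "A"] <- 0L
  fit3 <- fit_nb_glm(cm, sf, rep(0.1, 50), ex$condition)
  expect_true(fit3$zero_group[1, "A"])
  expect_equal(unname(exp(fit3$beta[1, "A"])), 1e-3, tolerance = 1e-6)
  expect_error(de_contrast(fit, c("A", "Z")), "unknown treatment")
})

test_that("Cook's outlier replacement honours the replicate threshold", {
  ex <- small_counts(n_genes = 40, n_per = 10, seed = 33)
  sf <- rep(1, 20)
  # plant one gross outlier: 100x the group mean
  ex$counts[5, 1] <- as.integer(100 * mean(ex$counts[5, 2:10]))
  fit <- fit_nb_glm(ex$counts, sf, rep(0.1, 40), ex$condition)
  fit8 <- cooks_outliers(fit, min_replicates_for_replace = 8)
  expect_true(fit8$outlier[5, 1])
  expect_true(fit8$replaced[5, 1])
  expect_lt(fit8$counts[5, 1], ex$counts[5, 1])
  # refit pulled the group mean back toward the clean replicates
  expect_lt(exp(fit8$beta[5, "A"]), exp(fit$beta[5, "A"]))
  # with groups smaller than the threshold, flags happen, replacement not
  ex7 <- small_counts(n_genes = 40, n_per = 7, seed = 34)
  ex7$counts[3, 1] <- as.integer(100 * mean(ex7$counts[3, 2:7]))
  f7 <- cooks_outliers(fit_nb_glm(ex7$counts, rep(1, 14), rep(0.1, 40),
                                  ex7$condition), 8)
  expect_true(f7$outlier[3, 1])
  expect_false(any(f7$replaced))
  # no outliers -> refit is a no-op
  clean <- cooks_outliers(fit_nb_glm(small_counts(seed = 35)$counts,
                                     rep(1, 12), rep(0.1, 60),
                                     factor(rep(c("A", "B"), each = 6))), 8)
  expect_false(any(clean$replaced))
})

test_that("normal-prior shrinkage follows the conjugate arithmetic", {
  # lfc = 2, se = 1, tau = 1 -> posterior mean 1, sd sqrt(0.5)
  expect_equal(2 * 1 / (1 + 1), 1)
  sh <- shrink_lfc(c(2, 0), c(1, 1))  # moments: mean(lfc^2)=2, mean(se^2)=1
  expect_equal(sh$tau, 1)
  expect_equal(sh$lfc_shrunk[1], 1)
  expect_equal(sh$post_sd[1], sqrt(0.5))
  # se -> 0 limit: shrunk -> mle
  sh2 <- shrink_lfc(c(2, -1, 0.5), c(1e-6, 1e-6, 1e-6))
  expect_equal(sh2$lfc_shrunk, c(2, -1, 0.5), tolerance = 1e-6)
  # tau at floor with huge se: shrunk -> 0
  sh3 <- shrink_lfc(c(0.001, -0.001), c(100, 100))
  expect_equal(sh3$tau, 1e-3)
  expect_equal(sh3$lfc_shrunk, c(0, 0), tolerance = 1e-6)
  # contraction holds for every gene
  withr::local_seed(36)
  lfc <- rnorm(500); se <- rexp(500) + 0.05
  sh4 <- shrink_lfc(lfc, se)
  expect_true(all(abs(sh4$lfc_shrunk) <= abs(lfc) + 1e-12))
})

test_that("s-values are cumulative means of sorted lfsr", {
  z <- -qnorm(c(0.001, 0.01, 0.1))
  sv <- svalues(z, rep(1, 3))
  expect_equal(sv$lfsr, c(0.001, 0.01, 0.1))
  expect_equal(sv$svalue, c(0.001, 0.0055, 0.037))
  # zero effect -> lfsr 0.5
  expect_equal(svalues(0, 1)$lfsr, 0.5)
  # all-zero lfsr -> all-zero svalues
  sv0 <- svalues(c(10, 20), c(1e-4, 1e-4))
  expect_equal(sv0$svalue, c(0, 0))
  # monotone in lfsr rank and never above the gene's own lfsr
  withr::local_seed(37)
  svr <- svalues(rnorm(300), rexp(300) + 0.1)
  o <- order(svr$lfsr)
  expect_true(all(diff(svr$svalue[o]) >= -1e-12))
  expect_true(all(svr$svalue <= svr$lfsr + 1e-12))
})

test_that("pairwise contrasts partition by sign and are antisymmetric", {
  ex <- small_counts(n_genes = 150, n_de = 30, lfc = 2, seed = 38)
  sf <- size_factors(ex$counts + 1)
  disp <- estimate_dispersions(ex$counts, sf, ex$condition)
  fit <- fit_nb_glm(ex$counts, sf, disp, ex$condition)
  pc <- pairwise_contrast(fit, c("A", "B"))
  expect_gt(length(pc$up), 15)  # planted genes are up in A
  pc_rev <- pairwise_contrast(fit, c("B", "A"))
  expect_setequal(pc$up, pc_rev$down)
  expect_setequal(pc$down, pc_rev$up)
  # threshold zero -> empty sets
  pc0 <- pairwise_contrast(fit, c("A", "B"), s_threshold = 0)
  expect_length(pc0$up, 0)
  expect_length(pc0$down, 0)
})

test_that("shared_de enforces intersection and sign concordance", {
  mk <- function(genes, lfc, sv) {
    structure(data.frame(gene = genes, lfc_shrunk = lfc, svalue = sv),
              class = c("de_result", "data.frame"))
  }
  a <- mk(paste0("g", 1:6), c(1, 1, 1, 1, 1, -1), c(rep(1e-5, 5), 1e-5))
  b <- mk(paste0("g", 2:7), c(1, 1, 1, -1, -1, 1), rep(1e-5, 6))
  # shared: g2..g6; g5 (a:+ b:-) and g6 (a:- b:-? a has -1, b has -1) check
  expect_setequal(shared_de(a, b, require_sign_match = FALSE),
                  paste0("g", 2:6))
  expect_setequal(shared_de(a, b), c("g2", "g3", "g4", "g6"))
  # disjoint sets -> empty
  c2 <- mk(paste0("x", 1:3), c(1, 1, 1), rep(1e-5, 3))
  expect_length(shared_de(a, c2), 0)
  # identical sets, same signs -> identity
  expect_setequal(shared_de(a, a), a$gene)
})

test_that("adaptive plasticity recovers planted CH-plastic genes only", {
  eff <- effect_class_spec(constitutive_host = 0, ch_plastic = 0.05,
                           co_plastic = 0, reciprocal_plastic = 0,
                           stress = 0, lfc_location = 2, lfc_scale = 0.5)
  ex <- small_experiment(n_genes = 600, seed = 41, effects = eff)
  filt <- filter_genes(ex$counts)
  sf <- size_factors(filt)
  cond <- factor(ex$samples$treatment, levels = TREATMENTS)
  fit <- fit_nb_glm(filt, sf, estimate_dispersions(filt, sf, cond), cond)
  ch <- adaptive_plasticity_genes("CH", fit)
  co <- adaptive_plasticity_genes("CO", fit)
  planted <- ex$truth$gene_id[ex$truth$class == "ch_plastic"]
  expect_gt(length(intersect(ch, planted)) / length(planted), 0.5)
  # CH-plastic genes are HH-vs-HO responders, not OO-vs-OH responders
  expect_length(intersect(co, planted), 0)
  # null-only simulation yields (almost) no adaptive-plasticity genes
  ex0 <- small_experiment(n_genes = 600, seed = 42,
                          effects = effect_class_spec(0, 0, 0, 0, 0))
  filt0 <- filter_genes(ex0$counts)
  sf0 <- size_factors(filt0)
  fit0 <- fit_nb_glm(filt0, sf0, estimate_dispersions(filt0, sf0, cond),
                     cond)
  expect_lte(length(adaptive_plasticity_genes("CH", fit0)), 1)
})

test_that("empirical sign-error among s-value calls is controlled", {
  # null + signal simulation: 20% of genes carry a real fold change
  ex <- small_counts(n_genes = 1000, n_de = 200, lfc = 1.5, seed = 43)
  sf <- size_factors(ex$counts + 1)
  disp <- estimate_dispersions(ex$counts, sf, ex$condition)
  fit <- fit_nb_glm(ex$counts, sf, disp, ex$condition)
  res <- de_contrast(fit, c("A", "B"))
  true_sign <- c(rep(1, 200), rep(0, 800))
  calls <- res$svalue < 0.001 & true_sign != 0
  expect_gt(sum(calls), 50)
  err <- mean(sign(res$lfc_shrunk[calls]) != true_sign[calls])
  expect_lte(err, 0.005)
})
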