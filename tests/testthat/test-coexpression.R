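# Biweight midcorrelation, soft-threshold selection, TOM, module detection,
# eigengenes, merging and kME filtering.

test_that("bicor has the exact and distributional properties", {
  withr::local_seed(51)
  x <- rnorm(50)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  expect_error(bicor(x, x[1:10]), "length")
  # affine invariance (sign flips under decreasing transforms)
  y <- rnorm(50)
  r <- bicor(x, y)
  expect_equal(bicor(2 * x + 3, y), r, tolerance = 1e-12)
  expect_equal(bicor(-2 * x + 1, y), -r, tolerance = 1e-12)
  # close to Pearson on clean bivariate normal data
  n <- 1000
  a <- rnorm(n); b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n)
  expect_lt(abs(bicor(a, b) - cor(a, b)), 0.05)
  # constant vector falls back to Pearson centring without error
  expect_true(is.finite(bicor(rep(1, 10) + c(rep(0, 9), 1e-9), rnorm(10))))
  # matrix form matches the vector form
  m <- cbind(x, y, a = rnorm(50))
  bm <- bicor(m)
  expect_equal(bm["x", "y"], bicor(x, y))
  expect_true(isSymmetric(bm))
  expect_true(all(bm >= -1 & bm <= 1))
})

test_that("soft-threshold selection follows the first-to-target rule", {
  withr::local_seed(52)
  # single latent factor with continuous (exponential) loadings: the
  # connectivity distribution is heavy-tailed, hence scale-free-like
  f <- rnorm(40)
  w <- rexp(300, rate = 2)
  expr <- sapply(seq_along(w), function(i) w[i] * f + rnorm(40))
  colnames(expr) <- paste0("g", 1:300)
  st <- pick_soft_threshold(expr)
  expect_lte(st$power, 12)
  expect_gte(max(st$fit_table$fit, na.rm = TRUE), 0.8)
  expect_gte(st$fit_table$fit[st$fit_table$power == st$power], 0.8)
  # the selected power is the FIRST candidate reaching the target
  earlier <- st$fit_table$fit[st$fit_table$power < st$power]
  expect_true(all(earlier < 0.8, na.rm = TRUE))
  # mean connectivity decreases with the power
  expect_true(all(diff(st$fit_table$mean_k) < 0))
  # a data set whose fit never reaches the target falls back, with a
  # warning, to the best-fitting candidate
  fx <- network_fixture()
  expect_warning(st2 <- pick_soft_threshold(t(fx$norm)), "best-fitting")
  expect_equal(st2$power,
               st2$fit_table$power[which.max(st2$fit_table$fit)])
})

test_that("TOM matches its closed-form values and bounds", {
  a <- matrix(c(1, 0.5, 0.5,
                0.5, 1, 0,
                0.5, 0, 1), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  tom <- tom_similarity(a)
  expect_equal(tom["g2", "g3"], 0.25 / 1.5)
  expect_true(isSymmetric(tom))
  # fully connected block -> TOM 1
  ones <- matrix(1, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  expect_true(all(tom_similarity(ones) == 1))
  # empty off-diagonal -> zero off-diagonal
  eye <- diag(4); dimnames(eye) <- dimnames(ones)
  t0 <- tom_similarity(eye)
  expect_true(all(t0[upper.tri(t0)] == 0))
  # entries stay in [0, 1] on random signed adjacencies
  withr::local_seed(53)
  r <- bicor(matrix(rnorm(30 * 40), 30, 40,
                    dimnames = list(NULL, paste0("g", 1:40))))
  tt <- tom_similarity(signed_adjacency(r, 6))
  expect_true(all(tt >= 0 & tt <= 1))
  expect_error(tom_similarity(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("module detection separates planted blocks and dissolves noise", {
  withr::local_seed(54)
  n <- 120
  tom <- matrix(runif(n * n, 0, 0.02), n, n)
  tom[1:50, 1:50] <- runif(2500, 0.5, 0.7)
  tom[51:100, 51:100] <- runif(2500, 0.5, 0.7)
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("g", 1:n), paste0("g", 1:n))
  det <- detect_modules(tom)
  a <- det$assignment
  mode1 <- as.integer(names(which.max(table(a[1:50]))))
  mode2 <- as.integer(names(which.max(table(a[51:100]))))
  expect_gte(mean(a[1:50] == mode1), 0.9)
  expect_gte(mean(a[51:100] == mode2), 0.9)
  expect_false(mode1 == mode2)
  expect_true(mode1 > 0 && mode2 > 0)
  # the 20 unclustered genes cannot form a module
  expect_gte(mean(a[101:120] == 0), 0.9)
  # block of 20 (< 30) dissolves into module 0
  tom2 <- matrix(0, 40, 40,
                 dimnames = list(paste0("g", 1:40), paste0("g", 1:40)))
  tom2[1:20, 1:20] <- 0.6
  diag(tom2) <- 1
  expect_true(all(detect_modules(tom2)$assignment == 0))
  # all-zero off-diagonal TOM -> everything unassigned
  eye <- diag(60)
  dimnames(eye) <- list(paste0("g", 1:60), paste0("g", 1:60))
  expect_true(all(detect_modules(eye)$assignment == 0))
})

test_that("eigengenes are unit-norm, sign-oriented factor estimates", {
  withr::local_seed(55)
  f <- rnorm(30)
  expr <- sapply(1:25, function(i) f + rnorm(30, sd = 0.1))
  colnames(expr) <- paste0("g", 1:25)
  e <- module_eigengenes(expr, setNames(rep(1L, 25), colnames(expr)))
  expect_equal(colnames(e), "mod01")
  expect_equal(sum(e[, 1]^2), 1)
  expect_gte(abs(cor(e[, 1], f)), 0.99)
  # sign convention: positively correlated with the module mean
  z <- scale(expr)
  expect_gte(cor(e[, 1], rowMeans(z)), 0)
  # identical genes -> |cor| with the common profile is 1
  same <- sapply(1:5, function(i) f)
  colnames(same) <- paste0("g", 1:5)
  es <- module_eigengenes(same, setNames(rep(1L, 5), colnames(same)))
  expect_equal(abs(cor(es[, 1], f)), 1, tolerance = 1e-10)
  # single-gene module: the gene's own z-score (unit-normalised)
  one <- module_eigengenes(expr[, 1, drop = FALSE],
                           setNames(1L, colnames(expr)[1]))
  expect_equal(abs(cor(one[, 1], expr[, 1])), 1, tolerance = 1e-10)
})

test_that("merging joins same-factor modules and kME filtering prunes noise", {
  withr::local_seed(56)
  f1 <- rnorm(38); f2 <- rnorm(38)
  expr <- cbind(
    sapply(1:40, function(i) f1 + rnorm(38, sd = 0.3)),
    sapply(1:40, function(i) f1 + rnorm(38, sd = 0.3)),  # same driver
    sapply(1:40, function(i) f2 + rnorm(38, sd = 0.3)),
    matrix(rnorm(38 * 5), 38, 5))                        # pure noise genes
  colnames(expr) <- paste0("g", 1:125)
  assignment <- setNames(c(rep(1L, 40), rep(2L, 40), rep(3L, 40),
                           rep(3L, 5)), colnames(expr))
  ms <- merge_and_filter(assignment, expr)
  a <- ms$assignment
  # the two same-factor modules merged into one
  expect_equal(length(unique(a[1:80])), 1)
  expect_false(unique(a[1:80]) == unique(a[81:120]))
  # noise genes forced into module 3 fail the kME threshold
  expect_true(all(a[121:125] == 0))
  expect_true(all(ms$kme[a != 0] >= 0.5))
  # uncorrelated modules stay apart
  expect_equal(ms$n_modules, 2)
  expect_true(all(sort(unique(a)) == c(0L, 1L, 2L)))
  # eigengene matrix covers mod00 through the last module
  expect_equal(colnames(ms$eigengenes), c("mod00", "mod01", "mod02"))
})

test_that("planted modules are recovered from generated counts", {
  fx <- network_fixture()
  ms <- fx$ms
  truth <- fx$sim$truth$module[match(names(ms$assignment),
                                     fx$sim$truth$gene_id)]
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(truth, ms$assignment), 0.8)
  # assigned genes all meet the membership threshold
  expect_true(all(ms$kme[ms$assignment != 0] >= 0.5))
  # eigengene columns are unit norm
  expect_equal(unname(colSums(ms$eigengenes^2)),
               rep(1, ncol(ms$eigengenes)), tolerance = 1e-8)
})
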