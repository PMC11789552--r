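# Negative-binomial differential expression with empirical-Bayes fold-change
# shrinkage and s-value (false sign rate) inference.
#
# The design is a single treatment factor fitted as one log-scale mean per
# group with log size-factor offsets, so the IRLS reduces to a per-group
# Newton iteration that can be vectorised across all genes at once.

# One Newton update pass for the per-group log-mean of every gene.
# counts: n x k counts of one group; sf: k size factors; beta: n current
# log normalized means (natural log); alpha: n dispersions.
.newton_group <- function(counts, sf, beta, alpha, iter = 100,
                          tol = 1e-8, beta_min = log(1e-3)) {
  for (it in seq_len(iter)) {
    mu <- exp(beta) %o% sf
    denom <- 1 + alpha * mu
    score <- rowSums((counts - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    beta_new <- pmax(beta + step, beta_min)
    done <- abs(beta_new - beta) < tol * (abs(beta) + tol)
    beta <- beta_new
    if (all(done)) break
  }
  beta
}

# Fit all group means for a candidate dispersion vector; returns list(beta,
# loglik) with loglik the full NB log-likelihood per gene.
.fit_means <- function(counts, sf, cond, alpha, iter = 10) {
  groups <- levels(cond)
  n <- nrow(counts)
  beta <- matrix(NA_real_, n, length(groups),
                 dimnames = list(rownames(counts), groups))
  ll <- numeric(n)
  size <- 1 / alpha
  for (g in seq_along(groups)) {
    idx <- which(cond == groups[g])
    y <- counts[, idx, drop = FALSE]
    s <- sf[idx]
    init <- log(pmax(rowSums(y) / sum(s), 1e-3))
    b <- .newton_group(y, s, init, alpha, iter = iter)
    beta[, g] <- b
    mu <- exp(b) %o% s
    ll <- ll + rowSums(stats::dnbinom(y, mu = mu, size = size, log = TRUE))
  }
  list(beta = beta, loglik = ll)
}

# Parabolic refinement of a grid argmax (equally spaced x on the log scale).
.refine_grid <- function(loglik, grid_log) {
  j <- max.col(loglik, ties.method = "first")
  h <- grid_log[2] - grid_log[1]
  n <- nrow(loglik)
  out <- grid_log[j]
  interior <- j > 1 & j < length(grid_log)
  if (any(interior)) {
    i <- which(interior)
    y1 <- loglik[cbind(i, j[i] - 1L)]
    y2 <- loglik[cbind(i, j[i])]
    y3 <- loglik[cbind(i, j[i] + 1L)]
    den <- y1 - 2 * y2 + y3
    adj <- ifelse(abs(den) > 1e-12, 0.5 * h * (y1 - y3) / den, 0)
    out[i] <- grid_log[j[i]] + pmin(pmax(adj, -h), h)
  }
  out
}

#' Estimate per-gene NB dispersions with trend shrinkage
#'
#' Maximum-likelihood dispersions (group means profiled out of the NB
#' likelihood on a log-spaced grid with parabolic refinement) are shrunk
#' towards a mean-dispersion trend `alpha(mu) = a1 / mu + a0` fitted by
#' iterated weighted regression; the final estimate is the posterior mode of
#' `log alpha` under a normal prior centred on the log trend. Dispersions are
#' clipped to `[1e-8, 10]`; all-zero genes are flagged and excluded from
#' trend fitting.
#'
#' @param counts count matrix (genes x samples).
#' @param sf size factors.
#' @param condition factor of treatment labels per sample.
#' @param grid_size number of grid points for the profile likelihood.
#' @return List with `alpha` (final), `alpha_mle`, `trend`, `sigma_prior`,
#'   `base_mean` and logical `flagged` (all-zero genes, `alpha` = NA).
#' @export
estimate_dispersions <- function(counts, sf, condition, grid_size = 40) {
  stop_if_not_matrix(counts)
  cond <- droplevels(as.factor(condition))
  if (max(table(cond)) < 2) stop("need >= 2 replicates in >= 1 group")
  flagged <- rowSums(counts) == 0
  base_mean <- rowMeans(sweep(counts, 2, sf, `/`))
  n <- nrow(counts)
  grid_log <- seq(log(1e-8), log(10), length.out = grid_size)
  ll <- matrix(NA_real_, n, grid_size)
  use <- which(!flagged)
  y <- counts[use, , drop = FALSE]
  for (k in seq_len(grid_size)) {
    a <- rep(exp(grid_log[k]), length(use))
    ll[use, k] <- .fit_means(y, sf, cond, a, iter = 5)$loglik
  }
  alpha_mle <- rep(NA_real_, n)
  alpha_mle[use] <- exp(.refine_grid(ll[use, , drop = FALSE], grid_log))
  alpha_mle <- pmin(pmax(alpha_mle, 1e-8), 10)

  # mean-dispersion trend a1/mu + a0, iterated weighted least squares with
  # outlier down-weighting by exclusion
  fit_ok <- use[alpha_mle[use] > 2e-8 & alpha_mle[use] < 8 &
                  base_mean[use] > 0.5]
  # all estimates at the clip (e.g. Poisson-like data): flat trend fallback
  a0 <- if (length(fit_ok)) stats::median(alpha_mle[fit_ok], na.rm = TRUE)
        else max(stats::median(alpha_mle[use], na.rm = TRUE), 1e-6)
  a1 <- 0
  if (length(fit_ok) >= 10) {
    keep <- fit_ok
    for (it in 1:8) {
      tr <- pmax(a1 / base_mean[keep] + a0, 1e-8)
      w <- 1 / tr ^ 2
      X <- cbind(1, 1 / base_mean[keep])
      cf <- stats::lm.wfit(X, alpha_mle[keep], w)$coefficients
      a0 <- max(cf[1], 1e-8)
      a1 <- max(cf[2], 0)
      tr_all <- pmax(a1 / base_mean[fit_ok] + a0, 1e-8)
      ratio <- alpha_mle[fit_ok] / tr_all
      keep <- fit_ok[ratio > 1e-4 & ratio < 15]
      if (length(keep) < 10) { keep <- fit_ok; break }
    }
  }
  trend <- pmax(a1 / base_mean + a0, 1e-8)
  lr <- if (length(fit_ok)) log(alpha_mle[fit_ok]) - log(trend[fit_ok])
        else numeric(0)
  s_lr <- if (length(lr)) stats::mad(lr, na.rm = TRUE) else NA_real_
  sigma_prior <- if (!is.finite(s_lr) || s_lr < 0.1) 0.5 else s_lr

  pen <- outer(log(trend[use]), grid_log,
               function(m, g) -(g - m) ^ 2 / (2 * sigma_prior ^ 2))
  alpha <- rep(NA_real_, n)
  alpha[use] <- exp(.refine_grid(ll[use, , drop = FALSE] + pen, grid_log))
  alpha <- pmin(pmax(alpha, 1e-8), 10)
  alpha[flagged] <- NA_real_
  list(alpha = stats::setNames(alpha, rownames(counts)),
       alpha_mle = stats::setNames(alpha_mle, rownames(counts)),
       trend = trend, trend_coef = c(a0 = a0, a1 = a1),
       sigma_prior = sigma_prior, base_mean = base_mean, flagged = flagged)
}

#' Fit the per-gene NB GLM (one mean per treatment group)
#'
#' Log-link negative binomial regression with log size-factor offsets and one
#' coefficient per treatment, fitted by Newton iteration (Fisher scoring) to
#' relative tolerance 1e-8; standard errors come from the expected Fisher
#' information. Groups with all-zero counts sit at the expansion bound and
#' are flagged.
#'
#' @param counts count matrix (genes x samples).
#' @param sf size factors.
#' @param dispersions per-gene dispersion vector (or the list returned by
#'   [estimate_dispersions()]).
#' @param condition factor of treatment labels.
#' @return An object of class `de_fit`.
#' @export
fit_nb_glm <- function(counts, sf, dispersions, condition) {
  stop_if_not_matrix(counts)
  if (is.list(dispersions)) dispersions <- dispersions$alpha
  cond <- droplevels(as.factor(condition))
  groups <- levels(cond)
  n <- nrow(counts)
  alpha <- ifelse(is.na(dispersions), 1e-8, dispersions)
  beta <- matrix(NA_real_, n, length(groups),
                 dimnames = list(rownames(counts), groups))
  se <- beta
  zero_group <- beta == beta  # init FALSE matrix of right shape
  zero_group[] <- FALSE
  for (g in seq_along(groups)) {
    idx <- which(cond == groups[g])
    y <- counts[, idx, drop = FALSE]
    s <- sf[idx]
    init <- log(pmax(rowSums(y) / sum(s), 1e-3))
    b <- .newton_group(y, s, init, alpha, iter = 100, tol = 1e-8)
    mu <- exp(b) %o% s
    info <- rowSums(mu / (1 + alpha * mu))
    beta[, g] <- b
    se[, g] <- 1 / sqrt(pmax(info, 1e-12))
    zero_group[, g] <- rowSums(y) == 0
  }
  mu_fit <- exp(beta[, as.integer(cond), drop = FALSE])
  mu_fit <- sweep(mu_fit, 2, sf, `*`)
  colnames(mu_fit) <- colnames(counts)
  structure(list(beta = beta, se = se, mu = mu_fit,
                 base_mean = rowMeans(sweep(counts, 2, sf, `/`)),
                 dispersions = stats::setNames(alpha, rownames(counts)),
                 zero_group = zero_group, counts = counts, sf = sf,
                 condition = cond,
                 outlier = matrix(FALSE, n, ncol(counts),
                                  dimnames = dimnames(counts))),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat("NB GLM fit:", nrow(x$beta), "genes,", length(x$condition),
      "samples,", nlevels(x$condition), "treatment groups\n")
  cat("groups:", paste(levels(x$condition), collapse = ", "), "\n")
  if (any(x$outlier)) cat(sum(x$outlier), "count outliers flagged\n")
  invisible(x)
}

#' Flag and optionally replace count outliers by Cook's distance
#'
#' Computes the per-observation Cook's distance of the NB GLM fit and flags
#' observations exceeding the 99% quantile of `F(p, m - p)`. In treatment
#' groups with at least `min_replicates_for_replace` replicates, flagged
#' counts are replaced by the (20% trimmed) group mean of normalised counts
#' scaled back by the sample's size factor, and the affected genes are
#' refitted. With the default threshold of 8 and group sizes of at most 7,
#' flagging still happens but replacement never triggers.
#'
#' @param fit a `de_fit`.
#' @param min_replicates_for_replace minimum group size for replacement.
#' @param refit refit genes whose counts were replaced.
#' @return The updated `de_fit` with `cooks`, `outlier` and `replaced`
#'   fields.
#' @export
cooks_outliers <- function(fit, min_replicates_for_replace = 8,
                           refit = TRUE) {
  stopifnot(inherits(fit, "de_fit"))
  counts <- fit$counts
  mu <- fit$mu
  alpha <- fit$dispersions
  p <- nlevels(fit$condition)
  m <- ncol(counts)
  v <- mu * (1 + alpha * mu)
  rp2 <- (counts - mu) ^ 2 / pmax(v, 1e-12)
  w <- mu / (1 + alpha * mu)
  gw <- t(rowsum(t(w), fit$condition))  # n x groups sums of weights
  h <- w / pmax(gw[, as.integer(fit$condition), drop = FALSE], 1e-12)
  cooks <- rp2 * h / (p * (1 - h) ^ 2)
  thr <- stats::qf(0.99, p, m - p)
  outlier <- cooks > thr
  outlier[is.na(outlier)] <- FALSE
  fit$cooks <- cooks
  fit$outlier <- outlier
  fit$replaced <- outlier & FALSE
  group_n <- table(fit$condition)
  can_replace <- group_n[as.integer(fit$condition)] >=
    min_replicates_for_replace
  rep_obs <- outlier & matrix(can_replace, nrow(counts), m, byrow = TRUE)
  if (any(rep_obs)) {
    norm <- sweep(counts, 2, fit$sf, `/`)
    genes <- which(rowSums(rep_obs) > 0)
    for (i in genes) {
      for (g in levels(fit$condition)) {
        idx <- which(fit$condition == g)
        bad <- idx[rep_obs[i, idx]]
        if (length(bad)) {
          tm <- mean(norm[i, idx], trim = 0.2)
          counts[i, bad] <- as.integer(round(tm * fit$sf[bad]))
        }
      }
    }
    fit$replaced <- rep_obs
    fit$counts <- counts
    if (refit && length(genes)) {
      sub <- fit_nb_glm(counts[genes, , drop = FALSE], fit$sf,
                        fit$dispersions[genes], fit$condition)
      fit$beta[genes, ] <- sub$beta
      fit$se[genes, ] <- sub$se
      fit$mu[genes, ] <- sub$mu
      fit$base_mean[genes] <- sub$base_mean
    }
  }
  fit
}

#' Empirical-Bayes shrinkage of log2 fold changes
#'
#' Zero-centred normal prior with method-of-moments scale:
#' `tau^2 = max(mean(lfc^2) - mean(se^2), tau_min^2)` over the estimation
#' set, giving conjugate posterior mean `lfc * tau^2 / (tau^2 + se^2)` and
#' posterior sd `sqrt(tau^2 se^2 / (tau^2 + se^2))` per gene.
#'
#' @param lfc_mle,se per-gene maximum-likelihood log2 fold changes and
#'   standard errors (`se > 0`).
#' @param tau_min lower bound for the prior sd.
#' @param exclude optional logical vector of genes to leave out of the
#'   moment estimate (e.g. separation-flagged genes); they are still shrunk.
#' @return List with `lfc_shrunk`, `post_sd` and the prior sd `tau`.
#' @export
shrink_lfc <- function(lfc_mle, se, tau_min = 1e-3, exclude = NULL) {
  stopifnot(length(lfc_mle) == length(se), all(se > 0, na.rm = TRUE))
  est <- is.finite(lfc_mle) & is.finite(se)
  if (!is.null(exclude)) est <- est & !exclude
  tau2 <- max(mean(lfc_mle[est] ^ 2) - mean(se[est] ^ 2), tau_min ^ 2)
  shrunk <- lfc_mle * tau2 / (tau2 + se ^ 2)
  post_sd <- sqrt(tau2 * se ^ 2 / (tau2 + se ^ 2))
  list(lfc_shrunk = shrunk, post_sd = post_sd, tau = sqrt(tau2))
}

#' Local false sign rates and s-values
#'
#' The local false sign rate is the posterior probability that the effect
#' sign is wrong, `lfsr = Phi(-|lfc_shrunk| / post_sd)`. The s-value of a
#' gene is the running mean of `lfsr` over all genes at or below its `lfsr`:
#' the expected sign-error rate incurred by calling every gene at least as
#' confident as this one.
#'
#' @param lfc_shrunk,post_sd posterior means and sds (log2).
#' @return `data.frame` with columns `lfsr` and `svalue`.
#' @export
svalues <- function(lfc_shrunk, post_sd) {
  stopifnot(all(post_sd > 0, na.rm = TRUE))
  lfsr <- stats::pnorm(-abs(lfc_shrunk) / post_sd)
  ord <- order(lfsr)
  cm <- cumsum(lfsr[ord]) / seq_along(lfsr)
  sv <- cm[rank(lfsr, ties.method = "max")]
  data.frame(lfsr = lfsr, svalue = sv)
}

#' Differential expression results for one treatment contrast
#'
#' Extracts the MLE log2 fold change and its standard error for a pair of
#' treatments, applies normal-prior shrinkage (prior scale estimated from
#' this contrast, excluding separation-flagged genes) and s-value inference.
#'
#' @param fit a `de_fit`.
#' @param contrast character pair `c(A, B)`; positive fold changes mean
#'   higher expression in `A`.
#' @param s_threshold s-value threshold for significance calls.
#' @return A `data.frame` of class `de_result` with one row per gene:
#'   `gene`, `base_mean`, `lfc_mle`, `se`, `lfc_shrunk`, `post_sd`, `lfsr`,
#'   `svalue`, `outlier_flag`, `call` (-1/0/1 signed significance).
#' @export
de_contrast <- function(fit, contrast, s_threshold = 0.001) {
  stopifnot(inherits(fit, "de_fit"), length(contrast) == 2)
  if (!all(contrast %in% levels(fit$condition)))
    stop("unknown treatment label in contrast: ",
         paste(setdiff(contrast, levels(fit$condition)), collapse = ", "))
  a <- contrast[1]; b <- contrast[2]
  lfc <- (fit$beta[, a] - fit$beta[, b]) / log(2)
  se <- sqrt(fit$se[, a] ^ 2 + fit$se[, b] ^ 2) / log(2)
  sep <- fit$zero_group[, a] | fit$zero_group[, b]
  sh <- shrink_lfc(lfc, se, exclude = sep)
  sv <- svalues(sh$lfc_shrunk, sh$post_sd)
  out <- data.frame(gene = rownames(fit$beta), base_mean = fit$base_mean,
                    lfc_mle = lfc, se = se, lfc_shrunk = sh$lfc_shrunk,
                    post_sd = sh$post_sd, lfsr = sv$lfsr, svalue = sv$svalue,
                    outlier_flag = rowSums(fit$outlier) > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$call <- ifelse(out$svalue < s_threshold, sign(out$lfc_shrunk), 0)
  attr(out, "contrast") <- contrast
  attr(out, "s_threshold") <- s_threshold
  attr(out, "tau") <- sh$tau
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat("Contrast", ct[1], "vs", ct[2], "-", nrow(x), "genes; ",
      sum(x$call == 1), "up,", sum(x$call == -1), "down at s <",
      attr(x, "s_threshold"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Significant gene sets of a pairwise contrast
#'
#' @param fit a `de_fit` (or an existing `de_result`).
#' @param contrast treatment pair (ignored if `fit` is already a result).
#' @param s_threshold s-value threshold.
#' @return List with the `de_result` and character vectors `up` and `down`.
#' @export
pairwise_contrast <- function(fit, contrast = NULL, s_threshold = 0.001) {
  res <- if (inherits(fit, "de_result")) fit else
    de_contrast(fit, contrast, s_threshold)
  sig <- res$svalue < s_threshold
  list(result = res,
       up = res$gene[sig & res$lfc_shrunk > 0],
       down = res$gene[sig & res$lfc_shrunk < 0])
}

#' Genes differentially expressed in two contrasts
#'
#' Intersection of the significant genes of two contrasts, optionally
#' requiring the shrunken fold changes to agree in sign.
#'
#' @param res_a,res_b `de_result` objects.
#' @param s_threshold s-value threshold applied to both.
#' @param require_sign_match keep only sign-concordant genes.
#' @return Character vector of gene ids.
#' @export
shared_de <- function(res_a, res_b, s_threshold = 0.001,
                      require_sign_match = TRUE) {
  sig_a <- res_a$gene[res_a$svalue < s_threshold]
  sig_b <- res_b$gene[res_b$svalue < s_threshold]
  both <- intersect(sig_a, sig_b)
  if (require_sign_match && length(both)) {
    sa <- sign(res_a$lfc_shrunk[match(both, res_a$gene)])
    sb <- sign(res_b$lfc_shrunk[match(both, res_b$gene)])
    both <- both[sa == sb]
  }
  both
}

#' Candidate adaptively plastic genes for one host race
#'
#' A gene shows adaptive plasticity in the ancestral (CH) race if the
#' cross-fostering response (HH vs HO) matches the constitutive host-race
#' difference (HH vs OO): significant in both contrasts with the same sign.
#' For the derived (CO) race the contrasts are OO vs OH and OO vs HH.
#'
#' @param race `"CH"` or `"CO"`.
#' @param fit a `de_fit` covering the needed treatments.
#' @param s_threshold s-value threshold.
#' @return Character vector of gene ids.
#' @export
adaptive_plasticity_genes <- function(race = c("CH", "CO"), fit,
                                      s_threshold = 0.001) {
  race <- match.arg(race)
  cts <- if (race == "CH") list(c("HH", "HO"), c("HH", "OO"))
         else list(c("OO", "OH"), c("OO", "HH"))
  res1 <- de_contrast(fit, cts[[1]], s_threshold)
  res2 <- de_contrast(fit, cts[[2]], s_threshold)
  shared_de(res1, res2, s_threshold, require_sign_match = TRUE)
}
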