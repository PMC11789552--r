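#' Filter lowly expressed genes
#'
#' Keeps genes with at least `min_count` reads in at least `min_samples`
#' samples, preserving gene order. The defaults (5 reads in 6 samples)
#' correspond to one full treatment group at the smallest replicate number.
#'
#' @param counts integer matrix, genes in rows, samples in columns.
#' @param min_count,min_samples filtering thresholds (>= 0).
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, min_count = 5, min_samples = 6) {
  if (min_count < 0 || min_samples < 0) stop("thresholds must be >= 0")
  if (nrow(counts) == 0) return(counts)
  keep <- rowSums(counts >= min_count) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over usable genes (those
#' with positive counts in every sample) of the ratio of the gene's count to
#' its geometric mean across samples.
#'
#' @param counts count matrix (genes x samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable))
    stop("no gene has positive counts in all samples; ",
         "size factors need at least one such reference gene")
  lc <- log(counts[usable, , drop = FALSE])
  geo <- rowMeans(lc)
  # median taken on the log scale (the field's convention; identical to the
  # ratio-scale median except when interpolating between two middle genes)
  sf <- exp(apply(lc - geo, 2, stats::median))
  stats::setNames(sf, colnames(counts))
}

#' Moderated log2 transform of normalised counts
#'
#' `log2(count / size_factor + pseudocount)`: a monotone, everywhere-finite
#' variance-moderating transform of normalised counts used for ordination,
#' clustering and network construction.
#'
#' @param counts count matrix.
#' @param sf size factors (computed with [size_factors()] if `NULL`).
#' @param pseudocount added before taking logs.
#' @return Numeric matrix of the same shape, with `size_factors` attribute.
#' @export
moderated_log <- function(counts, sf = NULL, pseudocount = 1) {
  sf <- sf %||% size_factors(counts)
  if (any(sf <= 0)) stop("size factors must be positive")
  y <- log2(sweep(counts, 2, sf, `/`) + pseudocount)
  attr(y, "size_factors") <- sf
  y
}

#' PCA of the most variable genes
#'
#' Ranks genes by variance across samples, runs a centred (unscaled)
#' principal component analysis of the top `n_top`, and fixes each
#' component's sign so its largest-magnitude gene loading is positive.
#'
#' @param norm normalised expression matrix (genes x samples).
#' @param n_top number of top-variance genes (capped at the gene count with
#'   a warning).
#' @return List with `scores` (samples x components), `loadings`
#'   (genes x components) and `variance_fraction`.
#' @export
pca_top_variable <- function(norm, n_top = 5000) {
  if (ncol(norm) < 2) stop("PCA needs at least two samples")
  if (n_top > nrow(norm)) {
    warning("n_top exceeds the number of genes; using all genes")
    n_top <- nrow(norm)
  }
  v <- apply(norm, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  pc <- stats::prcomp(t(norm[top, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  vf <- pc$sdev ^ 2 / sum(apply(t(norm[top, , drop = FALSE]), 2,
                                stats::var))
  list(scores = scores, loadings = loadings,
       variance_fraction = vf[seq_len(ncol(scores))])
}

#' Hierarchical clustering of samples
#'
#' Euclidean distance on the transformed expression matrix with
#' average-linkage agglomeration.
#'
#' @param norm normalised expression matrix (genes x samples).
#' @return An [stats::hclust] object over samples.
#' @export
sample_clustering <- function(norm) {
  if (ncol(norm) < 2) stop("clustering needs at least two samples")
  stats::hclust(stats::dist(t(norm)), method = "average")
}
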