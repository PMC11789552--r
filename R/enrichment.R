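# Gene-interval intersection, hypergeometric/Fisher enrichment tests,
# length-matched null sets and nonparametric metric comparisons.

#' Intersect flanked gene loci with genomic windows
#'
#' Each gene interval is extended by `flank` bp on both sides (clipped at
#' zero), and overlap with the half-open window tiling is recorded. Genes on
#' contigs absent from the window table are excluded with a warning.
#'
#' @param genes a `gene_model` (BED-convention coordinates).
#' @param windows window `data.frame` from [make_windows()] or
#'   [window_stats()] (`chrom`, `start`, `end`, `window_id`).
#' @param flank flank in bp added to both gene ends (default 2000).
#' @return `data.frame` (gene-window pairs): `gene_id`, `window_id`.
#' @export
intersect_genes_windows <- function(genes, windows, flank = 2000) {
  known <- unique(windows$chrom)
  drop <- !(genes$chrom %in% known)
  if (any(drop)) {
    warning(sum(drop), " gene(s) on contigs without windows excluded")
    genes <- genes[!drop, , drop = FALSE]
  }
  if (!nrow(genes))
    return(data.frame(gene_id = character(0), window_id = character(0),
                      stringsAsFactors = FALSE))
  gs <- pmax(genes$start - flank, 0)
  ge <- genes$end + flank
  res <- lapply(seq_len(nrow(genes)), function(i) {
    w <- windows[windows$chrom == genes$chrom[i] &
                   windows$start < ge[i] & windows$end > gs[i], "window_id"]
    if (length(w)) data.frame(gene_id = genes$gene_id[i], window_id = w,
                              stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out %||% data.frame(gene_id = character(0), window_id = character(0),
                      stringsAsFactors = FALSE)
}

#' Flag genes overlapping composite-outlier windows
#'
#' @param map gene-window map from [intersect_genes_windows()].
#' @param stats `window_stats` with the `composite` column.
#' @return Character vector of gene ids overlapping at least one composite
#'   outlier window.
#' @export
outlier_genes <- function(map, stats) {
  hot <- stats$window_id[which(stats$composite)]
  unique(map$gene_id[map$window_id %in% hot])
}

#' Hypergeometric enrichment of one gene set in another
#'
#' Upper-tail hypergeometric probability of observing at least the realised
#' overlap between a study (e.g. DE) set and a target set drawn from a
#' common universe, plus the sample odds ratio of the 2x2 table.
#'
#' @param de_set,target_set character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe character vector of all eligible gene ids.
#' @return One-row `data.frame`: `overlap`, `de_only`, `target_only`,
#'   `neither`, `universe`, `p`, `odds_ratio`.
#' @export
hypergeom_enrichment <- function(de_set, target_set, universe) {
  de_set <- unique(de_set); target_set <- unique(target_set)
  universe <- unique(universe)
  if (!all(de_set %in% universe) || !all(target_set %in% universe))
    stop("gene sets must be subsets of the universe")
  k <- length(intersect(de_set, target_set))
  de_only <- length(de_set) - k
  target_only <- length(target_set) - k
  neither <- length(universe) - k - de_only - target_only
  p <- stats::phyper(k - 1, length(target_set),
                     length(universe) - length(target_set),
                     length(de_set), lower.tail = FALSE)
  orat <- if (de_only * target_only > 0) {
    (k * neither) / (de_only * target_only)
  } else if (k * neither > 0) Inf else NA_real_
  data.frame(overlap = k, de_only = de_only, target_only = target_only,
             neither = neither, universe = length(universe), p = p,
             odds_ratio = orat)
}

#' Length-matched null gene set
#'
#' Samples non-DE genes (without replacement) so their length distribution
#' matches the DE genes': bin edges are the deciles of the DE gene lengths
#' and each bin's DE count is matched from the non-DE pool (bins short of
#' candidates are collapsed into their neighbour with a warning).
#'
#' @param de_genes,non_de_genes `data.frame`s with `gene_id` and `length`.
#' @param n_bins number of length bins (default deciles).
#' @param seed integer seed; draws are deterministic given the seed.
#' @return Character vector of matched non-DE gene ids.
#' @export
length_matched_null <- function(de_genes, non_de_genes, n_bins = 10,
                                seed = 1) {
  if (nrow(non_de_genes) < nrow(de_genes))
    stop("not enough non-DE genes to match the DE set")
  br <- unique(stats::quantile(de_genes$length,
                               probs = seq(0, 1, length.out = n_bins + 1)))
  br[1] <- -Inf; br[length(br)] <- Inf
  bin_de <- cut(de_genes$length, br, labels = FALSE)
  bin_pool <- cut(non_de_genes$length, br, labels = FALSE)
  with_seed(seed, {
    picked <- character(0)
    avail <- rep(TRUE, nrow(non_de_genes))
    need_later <- 0L
    for (b in sort(unique(bin_de))) {
      need <- sum(bin_de == b) + need_later
      cand <- which(avail & bin_pool == b)
      if (length(cand) < need) {
        warning("length bin ", b, " short of candidates; ",
                "collapsing into neighbouring bin")
        need_later <- need - length(cand)
        take <- cand
      } else {
        take <- if (length(cand) == need) cand else sample(cand, need)
        need_later <- 0L
      }
      avail[take] <- FALSE
      picked <- c(picked, non_de_genes$gene_id[take])
    }
    if (need_later > 0) {
      cand <- which(avail)
      take <- sample(cand, min(need_later, length(cand)))
      picked <- c(picked, non_de_genes$gene_id[take])
    }
    picked
  })
}

#' Kruskal-Wallis H plus Dunn's pairwise z-tests
#'
#' @param x numeric metric values.
#' @param g grouping vector.
#' @return List with `kw` (`statistic`, `p`) and `dunn` (`data.frame`:
#'   `group1`, `group2`, `z`, `p`, `padj` with BH adjustment and the
#'   standard tie correction).
#' @export
dunn_test <- function(x, g) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok])
  kw <- stats::kruskal.test(x, g)
  n <- length(x)
  r <- rank(x)
  tie <- table(x)
  tie_term <- sum(tie ^ 3 - tie) / (12 * (n - 1))
  rbar <- tapply(r, g, mean)
  ng <- table(g)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ng[[a]] + 1 / ng[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  list(kw = list(statistic = unname(kw$statistic), p = kw$p.value),
       dunn = data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                         p = p, padj = bh_adjust(p),
                         stringsAsFactors = FALSE))
}

#' Compare window metrics between DE-status groups, by inversion stratum
#'
#' Each gene carries the unweighted mean of each metric over the windows it
#' overlaps. Within each stratum (inside / outside the inversion) a
#' Kruskal-Wallis test across DE-status groups is run per metric, followed
#' by Dunn's pairwise z-tests with BH adjustment. Strata with fewer than two
#' groups of two genes are reported missing.
#'
#' @param gene_metrics `data.frame`: `gene_id` plus one column per metric.
#' @param de_status factor-like DE status per gene (aligned to rows).
#' @param inside_inversion logical per gene.
#' @param metrics metric column names (default: every other column).
#' @return `data.frame` with one row per metric x stratum: `metric`,
#'   `stratum`, `H`, `p`, `n`, plus the Dunn tables in the
#'   `dunn` attribute (named list).
#' @export
metric_comparison <- function(gene_metrics, de_status, inside_inversion,
                              metrics = NULL) {
  metrics <- metrics %||% setdiff(colnames(gene_metrics), "gene_id")
  strata <- list(inside = inside_inversion, outside = !inside_inversion)
  rows <- list()
  dunns <- list()
  for (s in names(strata)) {
    sel <- strata[[s]]
    for (m in metrics) {
      x <- gene_metrics[[m]][sel]
      g <- de_status[sel]
      tab <- table(g[!is.na(x)])
      if (sum(tab >= 2) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          metric = m, stratum = s, H = NA_real_, p = NA_real_,
          n = sum(!is.na(x)), stringsAsFactors = FALSE)
        next
      }
      dt <- dunn_test(x, g)
      rows[[length(rows) + 1]] <- data.frame(
        metric = m, stratum = s, H = dt$kw$statistic, p = dt$kw$p,
        n = sum(!is.na(x)), stringsAsFactors = FALSE)
      dunns[[paste(m, s, sep = ".")]] <- dt$dunn
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "dunn") <- dunns
  out
}

#' Mean window metrics per gene
#'
#' @param map gene-window map from [intersect_genes_windows()].
#' @param stats `window_stats`.
#' @param metrics metric columns to average.
#' @return `data.frame`: `gene_id` plus mean metric columns.
#' @export
gene_window_metrics <- function(map, stats,
                                metrics = c("fst", "dxy", "delta_pi",
                                            "delta_d", "pi_pop1", "pi_pop2",
                                            "tajd_pop1", "tajd_pop2")) {
  idx <- match(map$window_id, stats$window_id)
  out <- data.frame(gene_id = unique(map$gene_id), stringsAsFactors = FALSE)
  for (m in metrics) {
    v <- tapply(stats[[m]][idx], map$gene_id, mean, na.rm = TRUE)
    out[[m]] <- as.numeric(v[out$gene_id])
    out[[m]][is.nan(out[[m]])] <- NA_real_
  }
  out
}

#' One-sided Fisher gene-set (term) enrichment
#'
#' Skips the analysis entirely (with an explicit status) when the study set
#' has fewer than `min_study` genes; drops terms annotating fewer than
#' `min_term` genes in the universe; tests each remaining term with a
#' one-sided (greater) Fisher's exact test and reports terms with
#' `p < alpha`.
#'
#' @param study_set character vector of study gene ids.
#' @param gene_to_terms `data.frame` with columns `gene_id`, `term`.
#' @param universe character vector of eligible genes.
#' @param min_study minimum study-set size to run at all.
#' @param min_term minimum genes per term.
#' @param alpha significance threshold.
#' @return List with `status` (`"ok"` or `"skipped_small_study_set"`),
#'   `results` (per-term `data.frame`) and `enriched` (terms with
#'   `p < alpha`).
#' @export
term_enrichment <- function(study_set, gene_to_terms, universe,
                            min_study = 20, min_term = 5, alpha = 0.01) {
  study_set <- unique(intersect(study_set, universe))
  if (length(study_set) < min_study)
    return(list(status = "skipped_small_study_set", results = NULL,
                enriched = character(0)))
  g2t <- gene_to_terms[gene_to_terms$gene_id %in% universe, , drop = FALSE]
  sizes <- table(g2t$term)
  terms <- names(sizes)[sizes >= min_term]
  rows <- lapply(terms, function(tm) {
    ann <- unique(g2t$gene_id[g2t$term == tm])
    k <- length(intersect(study_set, ann))
    tab <- matrix(c(k, length(ann) - k,
                    length(study_set) - k,
                    length(universe) - length(ann) -
                      length(study_set) + k), 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = tm, annotated = length(ann), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows) %||%
    data.frame(term = character(0), annotated = integer(0),
               overlap = integer(0), p = numeric(0))
  list(status = "ok", results = res,
       enriched = res$term[res$p < alpha])
}
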