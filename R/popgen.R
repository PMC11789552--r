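# Windowed population-genomic statistics from per-site sample allele
# frequencies: Bhatia/Hudson F_ST, d_XY, nucleotide diversity, Tajima's D,
# between-population contrasts, coverage filtering and 3-SD outlier calls.

#' Tile contigs into non-overlapping windows
#'
#' Half-open 0-based windows `[0, w), [w, 2w), ...`, the last truncated at
#' the contig end.
#'
#' @param lengths named numeric vector of contig lengths.
#' @param window_size window size in bp.
#' @return `data.frame` with `chrom`, `start`, `end`, `window_id`.
#' @export
make_windows <- function(lengths, window_size = 50000) {
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  out <- do.call(rbind, lapply(names(lengths), function(ch) {
    starts <- seq(0, lengths[[ch]] - 1, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, lengths[[ch]]),
               stringsAsFactors = FALSE)
  }))
  out$window_id <- sprintf("%s:%.0f-%.0f", out$chrom, out$start, out$end)
  rownames(out) <- NULL
  out
}

#' Bhatia (Hudson) F_ST for one window
#'
#' Per shared site, numerator
#' `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and denominator
#' `p1(1-p2) + p2(1-p1)`; the window estimate is the ratio of sums
#' ("ratio of averages"). Returns `NA` when the summed denominator is zero
#' (no shared polymorphic site).
#'
#' @param p1,p2 sample allele frequencies at shared sites.
#' @param n1,n2 haploid sample sizes (scalar or per-site, > 1).
#' @return Window F_ST (<= 1, may be negative), or `NA`.
#' @export
fst_bhatia <- function(p1, p2, n1, n2) {
  stopifnot(length(p1) == length(p2))
  if (!length(p1)) return(NA_real_)
  num <- (p1 - p2) ^ 2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(den) == 0) return(NA_real_)
  sum(num) / sum(den)
}

#' Absolute divergence d_XY for one window
#'
#' Site-wise expected between-population pairwise difference
#' `p1(1-p2) + p2(1-p1)`, summed and divided by the effective window length
#' (by default the number of covered sites). Identically monomorphic sites
#' contribute zero.
#'
#' @param p1,p2 sample allele frequencies at shared sites.
#' @param l_effective effective length (covered sites or window length).
#' @return d_XY per site (>= 0).
#' @export
dxy_window <- function(p1, p2, l_effective = length(p1)) {
  if (l_effective <= 0) stop("effective length must be positive")
  sum(p1 * (1 - p2) + p2 * (1 - p1)) / l_effective
}

#' Nucleotide diversity for one window
#'
#' Per site `2 p (1 - p) n / (n - 1)` (finite-sample corrected expected
#' heterozygosity), summed over sites and divided by the effective length.
#'
#' @param p sample allele frequencies of one population.
#' @param n haploid sample size (>= 2).
#' @param l_effective effective length.
#' @return Window nucleotide diversity (>= 0).
#' @export
pi_window <- function(p, n, l_effective = length(p)) {
  if (any(n < 2)) stop("need n >= 2 haploids")
  if (l_effective <= 0) stop("effective length must be positive")
  sum(2 * p * (1 - p) * n / (n - 1)) / l_effective
}

#' Tajima's D for one window
#'
#' Standardised difference between the absolute (unscaled) nucleotide
#' diversity and Watterson's theta `S / a1`, using Tajima's constants for
#' the haploid sample size. Returns `NA` when no site segregates.
#'
#' @param p sample allele frequencies of one population.
#' @param n haploid sample size (>= 4).
#' @return Tajima's D, or `NA` for S = 0.
#' @export
tajimas_d <- function(p, n) {
  if (n < 4) stop("Tajima's D needs n >= 4")
  s <- sum(p > 0 & p < 1)
  if (s == 0) return(NA_real_)
  pi_abs <- sum(2 * p * (1 - p) * n / (n - 1))
  cst <- tajima_constants(n)
  d_var <- cst$e1 * s + cst$e2 * s * (s - 1)
  if (d_var <= 0) return(NA_real_)
  (pi_abs - s / cst$a1) / sqrt(d_var)
}

#' Tajima's standard constants for haploid sample size n
#' @param n haploid sample size.
#' @return List with `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#' @export
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i ^ 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n ^ 2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1 ^ 2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1 ^ 2 + a2))
}

#' Drop windows below a coverage threshold
#'
#' @param windows window `data.frame` with a `coverage` column.
#' @param min_fraction minimum coverage fraction (default 0.2; a window at
#'   exactly the threshold is kept).
#' @return The filtered window `data.frame`.
#' @export
coverage_filter <- function(windows, min_fraction = 0.2) {
  if (!nrow(windows)) return(windows)
  if (any(windows$coverage < 0 | windows$coverage > 1))
    stop("coverage fractions must lie in [0, 1]")
  windows[windows$coverage >= min_fraction, , drop = FALSE]
}

#' Per-metric 3-SD outlier flags
#'
#' For each metric the mean and SD are taken over windows with a non-missing
#' value. F_ST and d_XY windows are flagged above `mean + n_sd * SD` only;
#' the between-population contrasts delta-pi and delta-D are flagged on both
#' sides. Missing values are never flagged.
#'
#' @param stats window statistics `data.frame` with columns `fst`, `dxy`,
#'   `delta_pi`, `delta_d`.
#' @param n_sd number of standard deviations (default 3).
#' @return The input with logical columns `out_fst`, `out_dxy`,
#'   `out_delta_pi`, `out_delta_d` added.
#' @export
outlier_windows <- function(stats, n_sd = 3) {
  flag <- function(x, two_sided) {
    ok <- !is.na(x)
    if (sum(ok) < 2) return(rep(FALSE, length(x)))
    m <- mean(x[ok]); s <- stats::sd(x[ok])
    if (s == 0) return(rep(FALSE, length(x)))
    up <- ok & x > m + n_sd * s
    if (!two_sided) return(up)
    up | (ok & x < m - n_sd * s)
  }
  stats$out_fst <- flag(stats$fst, FALSE)
  stats$out_dxy <- flag(stats$dxy, FALSE)
  stats$out_delta_pi <- flag(stats$delta_pi, TRUE)
  stats$out_delta_d <- flag(stats$delta_d, TRUE)
  stats
}

#' Composite outlier call (3 of 4 metrics)
#'
#' @param stats window statistics with the four `out_*` flag columns.
#' @param min_metrics minimum number of flagged metrics (default 3).
#' @return The input with a logical `composite` column added.
#' @export
composite_outliers <- function(stats, min_metrics = 3) {
  n <- stats$out_fst + stats$out_dxy + stats$out_delta_pi + stats$out_delta_d
  stats$composite <- n >= min_metrics
  stats
}

#' Windowed population-genomic scan
#'
#' Computes, per 50 kb window passing the coverage filter: Bhatia F_ST,
#' d_XY, nucleotide diversity and Tajima's D per population, the
#' between-population contrasts `delta_pi = pi_pop1 - pi_pop2` and
#' `delta_d = D_pop1 - D_pop2`, per-metric 3-SD outlier flags and the
#' composite (3-of-4) outlier call. Sites present in both populations drive
#' F_ST and d_XY; each population's own sites drive pi and D.
#'
#' @param sites site table (`pop`, `chrom`, `pos`, `freq`, `n_haploid`)
#'   with two populations.
#' @param lengths named contig lengths.
#' @param window_size window size in bp.
#' @param coverage optional per-window coverage `data.frame` (`chrom`,
#'   `start`, `coverage`); full coverage assumed when absent.
#' @param min_coverage coverage filter threshold.
#' @param l_effective `"covered"` (number of covered sites, default) or
#'   `"window"` (full window length) as denominator for pi and d_XY.
#' @param pops the two population labels (default the sorted unique labels).
#' @return Window statistics `data.frame` of class `window_stats`.
#' @export
window_stats <- function(sites, lengths, window_size = 50000,
                         coverage = NULL, min_coverage = 0.2,
                         l_effective = c("covered", "window"),
                         pops = NULL) {
  l_effective <- match.arg(l_effective)
  pops <- pops %||% sort(unique(sites$pop))
  if (length(pops) != 2) stop("need exactly two populations")
  win <- make_windows(lengths, window_size)
  if (!is.null(coverage)) {
    key <- paste(coverage$chrom, coverage$start)
    win$coverage <- coverage$coverage[match(paste(win$chrom, win$start), key)]
    win$coverage[is.na(win$coverage)] <- 0
  } else win$coverage <- 1
  win <- coverage_filter(win, min_coverage)
  if (!nrow(win)) return(win)

  s1 <- sites[sites$pop == pops[1], ]
  s2 <- sites[sites$pop == pops[2], ]
  key1 <- paste(s1$chrom, s1$pos)
  key2 <- paste(s2$chrom, s2$pos)
  shared <- intersect(key1, key2)
  i1 <- match(shared, key1)
  i2 <- match(shared, key2)

  assign_window <- function(chrom, pos)
    match(paste(chrom, floor(pos / window_size) * window_size),
          paste(win$chrom, win$start))
  w_sh <- assign_window(s1$chrom[i1], s1$pos[i1])
  w_1 <- assign_window(s1$chrom, s1$pos)
  w_2 <- assign_window(s2$chrom, s2$pos)

  nw <- nrow(win)
  out <- win
  out$n_sites <- tabulate(w_sh, nw)
  out$fst <- out$dxy <- out$pi_pop1 <- out$pi_pop2 <- NA_real_
  out$tajd_pop1 <- out$tajd_pop2 <- NA_real_
  index_by_window <- function(w_idx) {
    ix <- vector("list", nw)
    ok <- !is.na(w_idx)
    tmp <- split(which(ok), w_idx[ok])
    ix[as.integer(names(tmp))] <- tmp
    ix
  }
  ix_sh <- index_by_window(w_sh)
  ix_1 <- index_by_window(w_1)
  ix_2 <- index_by_window(w_2)
  for (w in seq_len(nw)) {
    sh <- ix_sh[[w]]
    leff_sh <- if (l_effective == "covered") length(sh) else
      out$end[w] - out$start[w]
    if (length(sh)) {
      out$fst[w] <- fst_bhatia(s1$freq[i1[sh]], s2$freq[i2[sh]],
                               s1$n_haploid[i1[sh]], s2$n_haploid[i2[sh]])
      out$dxy[w] <- dxy_window(s1$freq[i1[sh]], s2$freq[i2[sh]], leff_sh)
    }
    a <- ix_1[[w]]
    if (length(a)) {
      leff <- if (l_effective == "covered") length(a) else
        out$end[w] - out$start[w]
      out$pi_pop1[w] <- pi_window(s1$freq[a], s1$n_haploid[a][1], leff)
      out$tajd_pop1[w] <- tajimas_d(s1$freq[a], s1$n_haploid[a][1])
    }
    b <- ix_2[[w]]
    if (length(b)) {
      leff <- if (l_effective == "covered") length(b) else
        out$end[w] - out$start[w]
      out$pi_pop2[w] <- pi_window(s2$freq[b], s2$n_haploid[b][1], leff)
      out$tajd_pop2[w] <- tajimas_d(s2$freq[b], s2$n_haploid[b][1])
    }
  }
  out$delta_pi <- out$pi_pop1 - out$pi_pop2
  out$delta_d <- out$tajd_pop1 - out$tajd_pop2
  out <- composite_outliers(outlier_windows(out))
  class(out) <- c("window_stats", "data.frame")
  out
}

#' @export
print.window_stats <- function(x, ...) {
  cat("Window scan:", nrow(x), "windows;",
      sum(x$out_fst, na.rm = TRUE), "F_ST /",
      sum(x$out_dxy, na.rm = TRUE), "d_XY /",
      sum(x$out_delta_pi, na.rm = TRUE), "delta-pi /",
      sum(x$out_delta_d, na.rm = TRUE), "delta-D outliers;",
      sum(x$composite, na.rm = TRUE), "composite\n")
  invisible(x)
}
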