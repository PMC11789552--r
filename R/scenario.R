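# Eigengene-design scenario classification: correlate module eigengenes with
# the five binary variables encoding the cross-fostering design and label
# modules as host-race-, stress- or plasticity-associated.

#' Binary design vectors of the cross-fostering experiment
#'
#' Maps each sample's treatment to the five binary scenario variables:
#' * `host_race`: 1 = CH race (H, HH, HO), 0 = CO race (O, OO, OH);
#' * `stress`: 1 = cross-fostered (HH, HO, OO, OH), 0 = directly sampled;
#' * `reciprocal_plasticity`: 1 = feeding on *C. oleraceum* (O, OO, HO);
#' * `ch_plasticity`: 1 = CO host race or the HO treatment, 0 = CH feeding
#'   on *C. heterophyllum* (H, HH);
#' * `co_plasticity`: 1 = CH host race or the OH treatment, 0 = CO feeding
#'   on *C. oleraceum* (O, OO).
#'
#' @param samples sample metadata with a `treatment` column (or a character
#'   vector of treatments).
#' @return Integer matrix, samples x 5 variables.
#' @export
build_design_vectors <- function(samples) {
  tr <- if (is.data.frame(samples)) samples$treatment else samples
  bad <- setdiff(unique(tr), TREATMENTS)
  if (length(bad)) stop("unknown treatment label(s): ",
                        paste(bad, collapse = ", "))
  m <- cbind(
    host_race = as.integer(tr %in% c("H", "HH", "HO")),
    stress = as.integer(tr %in% c("HH", "HO", "OO", "OH")),
    reciprocal_plasticity = as.integer(tr %in% c("O", "OO", "HO")),
    ch_plasticity = as.integer(tr %in% c("O", "OO", "OH", "HO")),
    co_plasticity = as.integer(tr %in% c("H", "HH", "HO", "OH")))
  rownames(m) <- if (is.data.frame(samples)) samples$sample_id else NULL
  m
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (monotone, capped at 1); a thin wrapper around
#' [stats::p.adjust()] kept as the single adjustment entry point.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Correlate module eigengenes with the design variables
#'
#' Pearson correlation of every eigengene with every binary design variable,
#' two-sided p-values from the Student-t transform
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)`, BH adjustment across modules within
#' each variable, and significance flags under the joint rule
#' `|r| > r_threshold` and adjusted `p < p_threshold`.
#'
#' @param eigengenes samples x modules eigengene matrix (from a
#'   `module_set`, mod00 included).
#' @param design samples x variables binary matrix from
#'   [build_design_vectors()].
#' @param r_threshold,p_threshold the meaningful-and-significant rule
#'   (defaults 0.5 and 0.01).
#' @return `data.frame` of class `scenario_result`: `module`, `variable`,
#'   `r`, `p`, `padj`, `significant`.
#' @export
correlate_modules <- function(eigengenes, design, r_threshold = 0.5,
                              p_threshold = 0.01) {
  n <- nrow(eigengenes)
  if (n < 4) stop("need >= 4 samples")
  if (nrow(design) != n) stop("eigengenes and design disagree on samples")
  if (any(apply(design, 2, function(v) length(unique(v))) < 2))
    stop("design vectors must be non-constant")
  res <- expand.grid(module = colnames(eigengenes),
                     variable = colnames(design),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$r <- NA_real_
  for (i in seq_len(nrow(res))) {
    e <- eigengenes[, res$module[i]]
    if (stats::sd(e) > 0)
      res$r[i] <- stats::cor(e, design[, res$variable[i]])
  }
  tstat <- res$r * sqrt(n - 2) / sqrt(pmax(1 - res$r ^ 2, 1e-300))
  res$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  res$padj <- NA_real_
  for (v in unique(res$variable)) {
    idx <- res$variable == v
    res$padj[idx] <- bh_adjust(res$p[idx])
  }
  res$significant <- !is.na(res$r) & abs(res$r) > r_threshold &
    res$padj < p_threshold
  attr(res, "r_threshold") <- r_threshold
  attr(res, "p_threshold") <- p_threshold
  class(res) <- c("scenario_result", "data.frame")
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Module-design correlations:", length(unique(x$module)), "modules x",
      length(unique(x$variable)), "variables;", sum(x$significant),
      "significant at |r| >", attr(x, "r_threshold"), "and adj. p <",
      attr(x, "p_threshold"), "\n")
  sig <- x[x$significant, c("module", "variable", "r", "padj")]
  if (nrow(sig)) print.data.frame(sig, row.names = FALSE)
  invisible(x)
}

#' Classify modules by their significant design associations
#'
#' @param results a `scenario_result`.
#' @return List with `labels` (named list: variables flagged per module;
#'   modules may carry several labels) and `summary` (counts per variable).
#' @export
classify_modules <- function(results) {
  mods <- unique(results$module)
  labels <- lapply(mods, function(m) {
    results$variable[results$module == m & results$significant]
  })
  names(labels) <- mods
  vars <- unique(results$variable)
  summary <- stats::setNames(
    vapply(vars, function(v) sum(results$significant[results$variable == v]),
           numeric(1)), vars)
  list(labels = labels, summary = summary)
}
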