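#' Simulate a toy gene model with an annotated inversion
#'
#' Places genes uniformly along equal-length linkage groups, draws log-normal
#' gene lengths, and flags genes whose interval overlaps the inversion.
#' Coordinates follow the BED convention (0-based, half-open).
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return A `data.frame` of class `gene_model` with columns `chrom`,
#'   `start`, `end`, `gene_id`, `length`, `inside_inversion`.
#' @export
simulate_genome <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "genome_spec"))
  n <- spec$n_genes
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), gene_id = character(0),
                      length = numeric(0), inside_inversion = logical(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    class(empty) <- c("gene_model", "data.frame")
    attr(empty, "genome_spec") <- spec
    return(empty)
  }
  g <- with_seed(seed, {
    lg <- sample.int(spec$n_linkage_groups, n, replace = TRUE)
    len <- round(stats::rlnorm(n, spec$gene_length_meanlog,
                               spec$gene_length_sdlog))
    len <- pmin(pmax(len, 200), floor(spec$lg_length_bp / 10))
    start <- floor(stats::runif(n, 0, spec$lg_length_bp - len))
    data.frame(chrom = paste0("LG", lg), start = start, end = start + len,
               gene_id = sprintf("g%05d", seq_len(n)), length = len,
               stringsAsFactors = FALSE)
  })
  inv <- spec$inversion
  g$inside_inversion <- g$chrom == paste0("LG", inv$lg) &
    g$start < inv$end & g$end > inv$start
  class(g) <- c("gene_model", "data.frame")
  attr(g, "genome_spec") <- spec
  g
}

#' Linkage-group lengths of a simulated gene model
#' @param genes a `gene_model` (needs its attached `genome_spec`).
#' @return Named numeric vector of contig lengths.
#' @export
contig_lengths <- function(genes) {
  spec <- attr(genes, "genome_spec")
  if (is.null(spec)) stop("gene model carries no genome_spec attribute")
  stats::setNames(rep(spec$lg_length_bp, spec$n_linkage_groups),
                  paste0("LG", seq_len(spec$n_linkage_groups)))
}

# Solve the outside-inversion class probability q so that the expected
# overall constitutive fraction hits `target` while inside genes carry
# `odds` times the outside odds (independent-Bernoulli assignment, so the
# sample odds ratio is a consistent estimate of `odds`).
.solve_enrichment_prob <- function(target, odds, inside_fraction) {
  if (target == 0) return(0)
  f <- function(q) {
    p_in <- q * odds / (q * odds + 1 - q)
    (1 - inside_fraction) * q + inside_fraction * p_in - target
  }
  stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

#' Assign planted effect classes to genes
#'
#' Constitutive host-race genes are assigned by independent Bernoulli draws
#' with the odds of assignment multiplied by `inversion_enrichment_odds` for
#' genes inside the inversion (calibrated so the expected overall fraction
#' matches the spec). Remaining genes receive the other classes uniformly.
#' Each non-null gene gets a signed log2 effect
#' `|lfc| = lfc_location + Exp(mean = lfc_scale)` with a random sign
#' (always positive for stress genes, which are elevated when cross-fostered).
#'
#' @param genes a `gene_model`.
#' @param effects an [effect_class_spec()].
#' @param seed integer seed.
#' @return `data.frame` with columns `gene_id`, `class`, `lfc`.
#' @export
assign_effect_classes <- function(genes, effects, seed = 1) {
  with_seed(seed, assign_effect_classes_impl(genes, effects))
}

assign_effect_classes_impl <- function(genes, effects) {
  stopifnot(inherits(effects, "effect_class_spec"))
  n <- nrow(genes)
  fr <- effects$fractions
  cls <- rep("null", n)
  m_in <- mean(genes$inside_inversion)
  q <- .solve_enrichment_prob(fr[["constitutive_host"]],
                              effects$inversion_enrichment_odds, m_in)
  p_in <- q * effects$inversion_enrichment_odds /
    (q * effects$inversion_enrichment_odds + 1 - q)
  p_const <- ifelse(genes$inside_inversion, p_in, q)
  cls[stats::runif(n) < p_const] <- "constitutive_host"
  rest <- which(cls == "null")
  other <- fr[c("ch_plastic", "co_plastic", "reciprocal_plastic", "stress")]
  if (sum(other) > 0 && length(rest) > 0) {
    p_other <- other / max(1 - fr[["constitutive_host"]], 1e-12)
    u <- stats::runif(length(rest))
    edges <- cumsum(p_other)
    idx <- findInterval(u, c(0, edges), left.open = TRUE)
    hit <- idx >= 1 & idx <= length(other) & u < edges[length(edges)]
    cls[rest[hit]] <- names(other)[idx[hit]]
  }
  lfc <- numeric(n)
  nn <- cls != "null"
  mag <- effects$lfc_location + stats::rexp(sum(nn), 1 / effects$lfc_scale)
  sgn <- ifelse(stats::runif(sum(nn)) < 0.5, -1, 1)
  sgn[cls[nn] == "stress"] <- 1
  lfc[nn] <- mag * sgn
  data.frame(gene_id = genes$gene_id, class = cls, lfc = lfc,
             stringsAsFactors = FALSE)
}

# Per-treatment mean multipliers for one gene class with signed log2 effect.
class_multipliers <- function(class, lfc) {
  ind <- switch(class,
    null = rep(0, 6),
    constitutive_host = as.numeric(TREATMENT_RACE[TREATMENTS] == "CH"),
    ch_plastic = as.numeric(TREATMENTS %in% c("H", "HH")),
    co_plastic = as.numeric(TREATMENTS %in% c("O", "OO")),
    reciprocal_plastic = as.numeric(TREATMENTS %in% c("O", "OO", "HO")),
    stress = as.numeric(TREATMENTS %in% c("HH", "HO", "OO", "OH")),
    stop("unknown class: ", class))
  stats::setNames(2 ^ (lfc * ind), TREATMENTS)
}

#' Simulate a gene-by-sample count matrix with planted structure
#'
#' Counts are negative binomial with mean
#' `s_i * q_g * m_g(treatment_i) * 2^(loading_g * factor_m(i))` and
#' variance `mu + alpha_g * mu^2`: `s_i` are log-normal library-size factors
#' (sdlog 0.3), `q_g` log-normal baselines (median 200), `alpha_g` log-normal
#' dispersions (median 0.1), `m_g` the effect-class treatment multipliers and
#' the last term the planted coexpression-module signal (1 for unplanted
#' genes). Module genes are drawn from null-class genes so planted
#' effect-class and module structures stay disjoint.
#'
#' @param design a [design_spec()].
#' @param effects an [effect_class_spec()].
#' @param modules a [module_plant_spec()].
#' @param genes a `gene_model` from [simulate_genome()].
#' @param seed integer seed.
#' @return List with `counts` (integer matrix genes x samples), `samples`
#'   (metadata `data.frame`), `truth` (per-gene truth table with class,
#'   signed log2 effect, per-treatment multipliers, planted module and
#'   inversion flag).
#' @export
simulate_counts <- function(design, effects, modules, genes, seed = 1) {
  stopifnot(inherits(design, "design_spec"),
            inherits(modules, "module_plant_spec"))
  nrep <- design$n_replicates
  treatment <- rep(names(nrep), nrep)
  n_samp <- length(treatment)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samp)),
    treatment = treatment,
    host_race = unname(TREATMENT_RACE[treatment]),
    stringsAsFactors = FALSE)
  n <- nrow(genes)
  with_seed(seed, {
    classes <- assign_effect_classes_impl(genes, effects)
    mult <- t(vapply(seq_len(n),
                     function(i) class_multipliers(classes$class[i],
                                                   classes$lfc[i]),
                     numeric(6)))
    colnames(mult) <- TREATMENTS

    # planted modules: latent factor per sample, loadings per gene
    module_id <- rep(0L, n)
    signal <- matrix(0, n, n_samp)
    if (modules$n_modules > 0) {
      dv <- build_design_vectors(samples)
      pool <- which(classes$class == "null")
      sizes <- sample(seq(modules$size_range[1], modules$size_range[2]),
                      modules$n_modules, replace = TRUE)
      if (sum(sizes) > length(pool))
        stop("not enough null genes to plant the requested modules")
      for (m in seq_len(modules$n_modules)) {
        idx <- sample(pool, sizes[m])
        pool <- setdiff(pool, idx)
        module_id[idx] <- m
        drv <- modules$drivers[m]
        base <- if (drv == "none") stats::rnorm(n_samp) else {
          col <- switch(drv, host_race = "host_race", stress = "stress",
                        ch_plastic = "ch_plasticity",
                        co_plastic = "co_plasticity",
                        reciprocal = "reciprocal_plasticity")
          as.numeric(scale(dv[, col]))
        }
        f <- base + stats::rnorm(n_samp, 0, modules$factor_noise_sd)
        lambda <- stats::runif(length(idx), modules$loading_range[1],
                               modules$loading_range[2])
        signal[idx, ] <- outer(lambda, f)
      }
    }

    q <- stats::rlnorm(n, log(200), 1)
    alpha <- stats::rlnorm(n, log(0.1), 0.5)
    s <- stats::rlnorm(n_samp, 0, 0.3)
    mu <- (q * mult[, treatment, drop = FALSE]) * 2 ^ signal
    mu <- sweep(mu, 2, s, `*`)
    counts <- matrix(stats::rnbinom(n * n_samp, mu = mu,
                                    size = rep(1 / alpha, n_samp)),
                     n, n_samp)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(genes$gene_id, samples$sample_id)

    truth <- data.frame(gene_id = genes$gene_id, class = classes$class,
                        lfc = classes$lfc, stringsAsFactors = FALSE)
    truth <- cbind(truth,
                   stats::setNames(as.data.frame(mult),
                                   paste0("mult_", TREATMENTS)))
    truth$module <- module_id
    truth$inside_inversion <- genes$inside_inversion
    list(counts = counts, samples = samples, truth = truth,
         size_factors_true = stats::setNames(s, samples$sample_id))
  })
}

#' Simulate per-site allele frequencies under the Balding-Nichols model
#'
#' For each 50 kb window a coverage fraction is drawn, site numbers follow
#' `Poisson(sites_per_window * coverage)`, ancestral frequencies are uniform,
#' and the two populations' frequencies are Beta-distributed around the
#' ancestral value with divergence parameter `F` (`f_background` outside the
#' inversion; `f_inversion * inversion_f_split` per population inside).
#' Observed frequencies are binomial sample frequencies of `n1`/`n2`
#' haploids.
#'
#' @param popspec a [popsim_spec()].
#' @param genome a [genome_spec()].
#' @param seed integer seed.
#' @return List with `sites` (`data.frame`: `pop`, `chrom`, `pos`, `freq`,
#'   `n_haploid`) and `coverage` (per-window coverage fractions).
#' @export
simulate_allele_freqs <- function(popspec, genome, seed = 1) {
  stopifnot(inherits(popspec, "popsim_spec"), inherits(genome, "genome_spec"))
  lens <- stats::setNames(rep(genome$lg_length_bp, genome$n_linkage_groups),
                          paste0("LG", seq_len(genome$n_linkage_groups)))
  win <- make_windows(lens, popspec$window_size_bp)
  inv <- genome$inversion
  with_seed(seed, {
    nw <- nrow(win)
    coverage <- stats::rbeta(nw, popspec$coverage_shape[1],
                             popspec$coverage_shape[2])
    n_sites <- stats::rpois(nw, popspec$sites_per_window * coverage *
                              (win$end - win$start) / popspec$window_size_bp)
    tot <- sum(n_sites)
    wi <- rep.int(seq_len(nw), n_sites)
    pos <- floor(stats::runif(tot, win$start[wi], win$end[wi]))
    chrom <- win$chrom[wi]
    inside <- chrom == paste0("LG", inv$lg) & pos >= inv$start & pos < inv$end
    p <- stats::runif(tot, popspec$anc_freq_range[1],
                      popspec$anc_freq_range[2])
    f1 <- ifelse(inside, popspec$f_inversion * popspec$inversion_f_split[1],
                 popspec$f_background)
    f2 <- ifelse(inside, popspec$f_inversion * popspec$inversion_f_split[2],
                 popspec$f_background)
    bn <- function(p, f) stats::rbeta(length(p), p * (1 - f) / f,
                                      (1 - p) * (1 - f) / f)
    p1 <- bn(p, f1)
    p2 <- bn(p, f2)
    o1 <- stats::rbinom(tot, popspec$n1, p1) / popspec$n1
    o2 <- stats::rbinom(tot, popspec$n2, p2) / popspec$n2
    ord <- order(chrom, pos)
    sites <- rbind(
      data.frame(pop = "pop1", chrom = chrom[ord], pos = pos[ord],
                 freq = o1[ord], n_haploid = popspec$n1,
                 stringsAsFactors = FALSE),
      data.frame(pop = "pop2", chrom = chrom[ord], pos = pos[ord],
                 freq = o2[ord], n_haploid = popspec$n2,
                 stringsAsFactors = FALSE))
    win$coverage <- coverage
    list(sites = sites, coverage = win)
  })
}

#' Write simulated artefacts as plain-text fixtures
#'
#' Writes `counts.tsv`, `samples.tsv`, `genes.bed`, `truth.tsv`,
#' `sites.tsv`, `coverage.tsv` and `config.yaml` into `outdir` (created if
#' missing). All files round-trip losslessly through the `read_*` readers.
#'
#' @param outdir output directory.
#' @param counts,samples,genes,truth,sites,coverage simulated artefacts (any
#'   may be `NULL` to skip).
#' @param config optional configuration list written as YAML.
#' @return Invisibly, the vector of paths written.
#' @export
write_fixtures <- function(outdir, counts = NULL, samples = NULL,
                           genes = NULL, truth = NULL, sites = NULL,
                           coverage = NULL, config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wtsv <- function(df, file, rn = FALSE) {
    p <- file.path(outdir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = rn,
                       col.names = if (rn) NA else TRUE)
    p
  }
  if (!is.null(counts)) paths <- c(paths, wtsv(counts, "counts.tsv", TRUE))
  if (!is.null(samples)) paths <- c(paths, wtsv(samples, "samples.tsv"))
  if (!is.null(genes)) {
    p <- file.path(outdir, "genes.bed")
    utils::write.table(
      data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                 genes$length, as.integer(genes$inside_inversion)),
      p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(truth)) paths <- c(paths, wtsv(truth, "truth.tsv"))
  if (!is.null(sites)) paths <- c(paths, wtsv(sites, "sites.tsv"))
  if (!is.null(coverage)) paths <- c(paths, wtsv(coverage, "coverage.tsv"))
  if (!is.null(config)) {
    p <- file.path(outdir, "config.yaml")
    yaml::write_yaml(config, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_fixtures
#' @param path file path to read.
#' @export
read_counts <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  m
}

#' @rdname write_fixtures
#' @export
read_samples <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)

#' @rdname write_fixtures
#' @export
read_gene_bed <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "gene_id",
                                       "length", "inside_inversion"))
  g$inside_inversion <- as.logical(g$inside_inversion)
  class(g) <- c("gene_model", "data.frame")
  g
}

#' @rdname write_fixtures
#' @export
read_sites <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)

#' @rdname write_fixtures
#' @export
read_truth <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
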