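#' Treatment labels of the cross-fostering design
#'
#' Six treatments: `H` and `O` are larvae sampled directly from buds of the
#' ancestral (*C. heterophyllum*, CH race) and derived (*C. oleraceum*, CO
#' race) host plant; `HH`, `HO`, `OO`, `OH` are cross-fostered larvae, the
#' first letter giving the natal host race and the second the plant the larva
#' was moved onto.
#'
#' @export
TREATMENTS <- c("H", "O", "HH", "HO", "OO", "OH")

#' Host race of each treatment ("CH" or "CO")
#' @export
TREATMENT_RACE <- c(H = "CH", O = "CO", HH = "CH", HO = "CH",
                    OO = "CO", OH = "CO")

#' Experimental design specification
#'
#' Treatment labels and replicate numbers for the six-treatment
#' cross-fostering design. The default replicate numbers (7, 6, 7, 7, 5, 6
#' for H, O, HH, HO, OO, OH) are the usable sample sizes of the study design
#' this generator emulates: seven larvae per CH treatment, six per CO
#' treatment, with one OO larva dropped at quality control.
#'
#' @param n_replicates named integer vector of replicates per treatment.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_replicates = c(H = 7, O = 6, HH = 7, HO = 7,
                                         OO = 5, OH = 6)) {
  labels <- names(n_replicates)
  if (is.null(labels) || anyDuplicated(labels))
    stop("treatment labels must be unique and named")
  if (!all(labels %in% TREATMENTS))
    stop("unknown treatment label(s): ",
         paste(setdiff(labels, TREATMENTS), collapse = ", "))
  n_replicates <- as.integer(n_replicates)
  names(n_replicates) <- labels
  if (any(n_replicates < 2)) stop("every treatment needs >= 2 replicates")
  structure(list(n_replicates = n_replicates), class = "design_spec")
}

#' Effect-class specification for the count simulator
#'
#' Fractions of genes per planted effect class (the remainder is null).
#' `constitutive_host` genes differ between host races in every treatment
#' (split evenly between up-in-CH and up-in-CO); `ch_plastic` genes follow
#' the mod16-type pattern (one level in H/HH, the other in O/OO/OH/HO, i.e.
#' the ancestral race shifts to the derived race's level when fostered onto
#' the novel host); `co_plastic` is the mirror image (O/OO vs the rest);
#' `reciprocal_plastic` genes track only the plant fed upon; `stress` genes
#' are elevated in all four cross-fostered treatments.
#'
#' The default constitutive fraction (0.08) matches the roughly 8% of the
#' expressed transcriptome found constitutively differentially expressed
#' between the host races; plasticity defaults are minimal and asymmetric
#' (CH only), and no reciprocal plasticity is planted, mirroring the
#' biological findings the simulator is meant to emulate.
#'
#' @param constitutive_host,ch_plastic,co_plastic,reciprocal_plastic,stress
#'   class fractions in `[0, 1]`, summing to at most 1.
#' @param lfc_location,lfc_scale the per-gene absolute log2 fold change is
#'   `lfc_location + Exponential(mean = lfc_scale)`.
#' @param inversion_enrichment_odds odds multiplier for a constitutive gene
#'   lying inside the inversion relative to outside.
#' @return An object of class `effect_class_spec`.
#' @export
effect_class_spec <- function(constitutive_host = 0.08,
                              ch_plastic = 0.005,
                              co_plastic = 0,
                              reciprocal_plastic = 0,
                              stress = 0.02,
                              lfc_location = 0.5,
                              lfc_scale = 0.75,
                              inversion_enrichment_odds = 3.0) {
  fr <- c(constitutive_host = constitutive_host, ch_plastic = ch_plastic,
          co_plastic = co_plastic, reciprocal_plastic = reciprocal_plastic,
          stress = stress)
  if (any(fr < 0) || any(fr > 1)) stop("class fractions must lie in [0, 1]")
  if (sum(fr) > 1) stop("class fractions sum to more than 1")
  if (inversion_enrichment_odds <= 0)
    stop("inversion_enrichment_odds must be positive")
  if (lfc_location < 0 || lfc_scale <= 0)
    stop("invalid |log2FC| distribution parameters")
  structure(list(fractions = fr, lfc_location = lfc_location,
                 lfc_scale = lfc_scale,
                 inversion_enrichment_odds = inversion_enrichment_odds),
            class = "effect_class_spec")
}

#' Planted coexpression-module specification
#'
#' Each planted module is driven by one latent factor per sample: the
#' standardised binary design vector named by `drivers` plus Gaussian noise
#' (`factor_noise_sd`), or pure noise for driver `"none"`. Gene loadings are
#' drawn uniformly from `loading_range` and enter the count mean as
#' `2^(loading * factor)`.
#'
#' The default `factor_noise_sd = 1.2` attenuates the eigengene-design
#' correlation of a planted module to about 0.64, inside the 0.55-0.75 band
#' of module-trait correlations typical of this design (see the methods
#' vignette).
#'
#' @param n_modules number of planted modules.
#' @param size_range integer `(min, max)` module size; minimum 30 so planted
#'   modules remain detectable under the minimum-module-size rule.
#' @param drivers character vector (recycled to `n_modules`) from
#'   `host_race`, `stress`, `ch_plastic`, `co_plastic`, `reciprocal`, `none`.
#' @param loading_range range of per-gene factor loadings.
#' @param factor_noise_sd standard deviation of per-sample factor noise.
#' @return An object of class `module_plant_spec`.
#' @export
module_plant_spec <- function(n_modules = 4,
                              size_range = c(40, 60),
                              drivers = c("host_race", "stress",
                                          "ch_plastic", "none"),
                              loading_range = c(0.8, 1.2),
                              factor_noise_sd = 1.2) {
  if (n_modules < 0) stop("n_modules must be non-negative")
  if (n_modules > 0) {
    if (size_range[1] < 30)
      stop("planted module sizes must be >= 30 to be detectable")
    if (size_range[2] < size_range[1]) stop("invalid size_range")
    drivers <- rep_len(drivers, n_modules)
    ok <- c("host_race", "stress", "ch_plastic", "co_plastic",
            "reciprocal", "none")
    if (!all(drivers %in% ok))
      stop("drivers must be one of: ", paste(ok, collapse = ", "))
  } else drivers <- character(0)
  structure(list(n_modules = as.integer(n_modules),
                 size_range = as.integer(size_range), drivers = drivers,
                 loading_range = loading_range,
                 factor_noise_sd = factor_noise_sd),
            class = "module_plant_spec")
}

#' Toy genome specification
#'
#' Linkage-group layout for the simulated gene model, including one annotated
#' inversion interval (BED convention: 0-based, half-open). The default shape
#' emulates, at desk scale, a genome with one large inversion on the third
#' linkage group.
#'
#' @param n_linkage_groups number of linkage groups (equal lengths).
#' @param lg_length_bp length of each linkage group in bp.
#' @param inversion list or vector `(lg, start, end)` for the inversion.
#' @param n_genes number of genes to place.
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene length
#'   parameters (default median 5 kb).
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_linkage_groups = 6,
                        lg_length_bp = 5e7,
                        inversion = c(lg = 3, start = 1e7, end = 3e7),
                        n_genes = 10000,
                        gene_length_meanlog = log(5000),
                        gene_length_sdlog = 0.6) {
  inversion <- as.numeric(inversion)
  if (length(inversion) != 3) stop("inversion must be (lg, start, end)")
  if (inversion[1] < 1 || inversion[1] > n_linkage_groups)
    stop("inversion linkage group out of range")
  if (inversion[2] < 0 || inversion[3] > lg_length_bp ||
      inversion[3] <= inversion[2])
    stop("inversion interval must lie within its linkage group")
  if (n_genes < 0) stop("n_genes must be non-negative")
  structure(list(n_linkage_groups = as.integer(n_linkage_groups),
                 lg_length_bp = lg_length_bp,
                 inversion = list(lg = as.integer(inversion[1]),
                                  start = inversion[2], end = inversion[3]),
                 n_genes = as.integer(n_genes),
                 gene_length_meanlog = gene_length_meanlog,
                 gene_length_sdlog = gene_length_sdlog),
            class = "genome_spec")
}

#' Population allele-frequency simulation specification
#'
#' Sites are simulated under the Balding-Nichols model: an ancestral
#' frequency `p` is drawn uniformly, then each population's frequency comes
#' from `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` and is observed as a
#' binomial sample frequency of `n1` (pop1) or `n2` (pop2) haploids.
#'
#' Outside the inversion both populations use `f_background`. Inside it, the
#' divergence parameter averages `f_inversion` but is split asymmetrically
#' between the populations (`f_inversion * inversion_f_split`): the derived
#' population (pop2) has drifted/swept harder, which reproduces the
#' elevated F_ST, positive delta-pi and strong delta-D contrasts of a
#' divergent inversion while keeping the expected Hudson/Bhatia F_ST inside
#' the inversion equal to `f_inversion` exactly.
#'
#' @param window_size_bp window size used downstream (for coverage records).
#' @param sites_per_window Poisson mean number of sites per full-coverage
#'   window.
#' @param n1,n2 haploid sample sizes (>= 4).
#' @param f_background,f_inversion divergence parameters in (0, 1).
#' @param inversion_f_split length-2 multiplier splitting `f_inversion`
#'   between pop1 and pop2 (mean must be 1).
#' @param anc_freq_range uniform range of ancestral frequencies.
#' @param coverage_shape Beta shape parameters of per-window coverage
#'   fractions; the default gives a low-coverage tail so the 20% coverage
#'   filter is exercised.
#' @return An object of class `popsim_spec`.
#' @export
popsim_spec <- function(window_size_bp = 50000,
                        sites_per_window = 100,
                        n1 = 20, n2 = 20,
                        f_background = 0.02,
                        f_inversion = 0.30,
                        inversion_f_split = c(0.5, 1.5),
                        anc_freq_range = c(0.05, 0.95),
                        coverage_shape = c(2, 0.5)) {
  if (n1 < 4 || n2 < 4) stop("haploid sample sizes must be >= 4")
  for (f in c(f_background, f_inversion))
    if (f <= 0 || f >= 1) stop("F parameters must lie in (0, 1)")
  if (length(inversion_f_split) != 2 ||
      abs(mean(inversion_f_split) - 1) > 1e-8)
    stop("inversion_f_split must be two multipliers with mean 1")
  fi <- f_inversion * inversion_f_split
  if (any(fi <= 0) || any(fi >= 1))
    stop("split inversion F values must stay in (0, 1)")
  structure(list(window_size_bp = window_size_bp,
                 sites_per_window = sites_per_window,
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 f_background = f_background, f_inversion = f_inversion,
                 inversion_f_split = inversion_f_split,
                 anc_freq_range = anc_freq_range,
                 coverage_shape = coverage_shape),
            class = "popsim_spec")
}

#' Coexpression network parameters
#'
#' @param powers candidate soft-threshold powers.
#' @param scale_free_target scale-free topology fit index to reach (R^2).
#' @param min_module_size minimum module size; smaller clusters dissolve into
#'   module 0 (unassigned, "mod00").
#' @param merge_correlation eigengene correlation above which two modules are
#'   merged ("over 70% related").
#' @param kme_threshold module-membership threshold below which genes are
#'   unassigned.
#' @param cut_quantile quantile of merge heights used for the static tree
#'   cut.
#' @return An object of class `network_params`.
#' @export
network_params <- function(powers = 1:20,
                           scale_free_target = 0.8,
                           min_module_size = 30,
                           merge_correlation = 0.70,
                           kme_threshold = 0.5,
                           cut_quantile = 0.99) {
  stopifnot(all(powers > 0), scale_free_target >= 0, scale_free_target <= 1,
            min_module_size >= 1, merge_correlation > 0,
            merge_correlation < 1, kme_threshold >= 0, kme_threshold <= 1,
            cut_quantile > 0, cut_quantile <= 1)
  structure(list(powers = powers, scale_free_target = scale_free_target,
                 min_module_size = as.integer(min_module_size),
                 merge_correlation = merge_correlation,
                 kme_threshold = kme_threshold, cut_quantile = cut_quantile),
            class = "network_params")
}
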