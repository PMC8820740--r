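#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every generator
#' in the synthetic-data module. Defaults encode the study design the pipeline
#' was built for: four TRAP/RNA-seq replicates and five CLIP replicates per
#' compartment, two compartments (cell bodies, neuropil), two genotypes,
#' negative-binomial counts, and a neuropil CLIP library roughly one tenth
#' the size of the cell-body library.
#'
#' @param n_genes number of simulated genes.
#' @param frac_multi_utr fraction of genes carrying more than one polyA site.
#' @param frac_ur_apa fraction of multi-UTR genes whose extra site lies in an
#'   upstream intron (UR-APA, CDS-altering); a further `frac_both_apa` carry
#'   both a tandem 3'UTR site and an intronic site.
#' @param frac_both_apa fraction of multi-UTR genes with both event types.
#' @param frac_enriched fraction of genes truly dendrite-enriched.
#' @param frac_present_only fraction of genes dendrite-present but not
#'   enriched over cell bodies.
#' @param frac_bound fraction of genes truly FMRP-bound.
#' @param bound_expression_quantile FMRP-bound genes are drawn from genes
#'   above this baseline-expression quantile, reflecting the observed
#'   greater abundance of dendritic FMRP targets.
#' @param expr_log2_mean,expr_log2_sd mean and sd of baseline log2
#'   expression across genes.
#' @param frac_localized_isoform fraction of multi-UTR genes whose distal
#'   isoform is truly shifted toward the neuropil.
#' @param n_replicates TRAP/RNA-seq replicates per (assay, compartment,
#'   genotype) group.
#' @param n_clip_replicates CLIP replicates per compartment.
#' @param library_size_mean mean sequencing-library size in counts.
#' @param library_size_cv coefficient of variation of per-sample library
#'   sizes (log-normal).
#' @param nb_dispersion negative-binomial dispersion of all read/tag counts.
#' @param localization_lfc true log2 fold change of dendrite-enriched genes
#'   (neuropil TRAP over each comparator).
#' @param usage_shift_np distal-isoform usage in neuropil for localized
#'   isoforms; cell-body usage is its complement.
#' @param clip_enrichment_log10 spiked log10 CLIP enrichment of bound genes.
#' @param clip_rep_sd log-normal replicate noise (sd, log10 units) on CLIP
#'   expression.
#' @param clip_np_lib_ratio neuropil/cell-body CLIP library-size ratio;
#'   default 80749/746827, the tag totals of the experiment emulated.
#' @param fish_boundary_coeffs polynomial coefficients (intercept first, µm)
#'   of the cell-body-layer boundary y = f(x).
#' @param fish_width_um,fish_height_um image frame in µm.
#' @param fish_n_nuclei,fish_n_spots nuclei and FISH spots per field.
#' @param fish_neuropil_weight mixture weight of the neuropil spot component.
#' @param fish_decay_um exponential decay length (µm) of neuropil spot
#'   density with distance from the boundary.
#' @param fish_layer_um thickness (µm) of the cell-body layer.
#' @param spot_noise_sd isotropic Gaussian noise (µm) added to spot
#'   coordinates.
#' @param um_per_px pixel size of the nuclei mask, µm per pixel.
#' @param seed integer seed; the seed fully determines every generator's
#'   output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       frac_multi_utr = 0.4,
                       frac_ur_apa = 0.22,
                       frac_both_apa = 0.10,
                       frac_enriched = 0.20,
                       frac_present_only = 0.15,
                       frac_bound = 0.15,
                       bound_expression_quantile = 0.9,
                       expr_log2_mean = 7,
                       expr_log2_sd = 1.5,
                       frac_localized_isoform = 0.5,
                       n_replicates = 4L,
                       n_clip_replicates = 5L,
                       library_size_mean = 2e5,
                       library_size_cv = 0.15,
                       nb_dispersion = 0.05,
                       localization_lfc = 2,
                       usage_shift_np = 0.8,
                       clip_enrichment_log10 = 1,
                       clip_rep_sd = 0.15,
                       clip_np_lib_ratio = 80749 / 746827,
                       fish_boundary_coeffs = c(90, 0.25, -8e-4),
                       fish_width_um = 300,
                       fish_height_um = 300,
                       fish_n_nuclei = 400L,
                       fish_n_spots = 2000L,
                       fish_neuropil_weight = 0.4,
                       fish_decay_um = 30,
                       fish_layer_um = 35,
                       spot_noise_sd = 0.3,
                       um_per_px = 0.14,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_genes", "n_replicates", "n_clip_replicates",
              "fish_n_nuclei", "fish_n_spots")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0 ||
        cfg[[f]] != round(cfg[[f]]))
      stop("sim_config: '", f, "' must be a positive integer", call. = FALSE)
  }
  props <- c("frac_multi_utr", "frac_ur_apa", "frac_both_apa",
             "frac_enriched", "frac_present_only", "frac_bound",
             "frac_localized_isoform", "fish_neuropil_weight",
             "bound_expression_quantile")
  for (f in props) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config: '", f, "' must lie in [0, 1]", call. = FALSE)
  }
  pos <- c("library_size_mean", "nb_dispersion", "usage_shift_np",
           "clip_np_lib_ratio", "fish_width_um", "fish_height_um",
           "fish_decay_um", "fish_layer_um", "um_per_px")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("sim_config: '", f, "' must be positive", call. = FALSE)
  }
  if (cfg$library_size_cv < 0)
    stop("sim_config: 'library_size_cv' must be non-negative",
         call. = FALSE)
  if (cfg$spot_noise_sd < 0)
    stop("sim_config: 'spot_noise_sd' must be non-negative", call. = FALSE)
  if (cfg$frac_ur_apa + cfg$frac_both_apa > 1)
    stop("sim_config: UR-APA fractions exceed 1", call. = FALSE)
  if (cfg$frac_enriched + cfg$frac_present_only > 1)
    stop("sim_config: localization class fractions exceed 1", call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop("sim_config: 'seed' must be a single integer", call. = FALSE)
  # boundary must stay inside the image frame
  x <- seq(0, cfg$fish_width_um, length.out = 101)
  y <- poly_eval(cfg$fish_boundary_coeffs, x)
  if (any(y <= 0) || any(y >= cfg$fish_height_um))
    stop("sim_config: boundary curve leaves the image frame", call. = FALSE)
  cfg
}

#' Evaluate a polynomial with coefficients in increasing-degree order
#' @param coeffs numeric coefficients, intercept first.
#' @param x numeric vector.
#' @return numeric vector of the same length as `x`.
#' @export
poly_eval <- function(coeffs, x) {
  y <- numeric(length(x))
  for (k in seq_along(coeffs)) y <- y + coeffs[k] * x^(k - 1)
  y
}
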