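#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the seeded generator that emulates the inputs of
#' the co-prescription / network-proximity analysis: a longitudinal
#' multi-visit prescription table with typo-corrupted drug names and planted
#' co-prescribed pairs, a drug catalog with ATC codes, targets, mechanism
#' genes and abstract fingerprint bit sets, a scale-free background
#' interaction network with a planted connected disease module, a noisy DEG
#' list, and gene-set collections overlapping the module. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param seed Integer master seed; every generator draws from seeds derived
#'   from it.
#' @param n_patients Number of patients.
#' @param n_drugs Number of catalog drugs.
#' @param n_genes Number of network genes.
#' @param ppi_attachment Edges added per node during preferential-attachment
#'   growth of the background network.
#' @param weighted_edges Draw edge weights uniformly from `[0.5, 1.5]`
#'   instead of unit weights.
#' @param module_size Size of the planted connected disease module.
#' @param n_degs Number of reported DEGs.
#' @param deg_noise Fraction of DEGs planted outside the module (noise).
#' @param frac_proximal_drugs Fraction of drugs whose targets are drawn from
#'   the module neighborhood ("proximal" ground truth).
#' @param typo_rate Per-record probability that the raw drug name is
#'   corrupted by 1-2 character edits.
#' @param mean_visits Mean number of prescription points per patient
#'   (shifted Poisson, so at least one).
#' @param mean_interval_days Mean gap between consecutive visits
#'   (exponential).
#' @param planted_pairs Number of drug pairs forced to co-occur at the same
#'   visits with probability >= 0.9.
#' @param n_pathways Number of synthetic pathway gene sets.
#' @param pathway_size_range Length-2 integer vector: min/max pathway size.
#' @param prevalence_dispersion Beta shape2 of the per-drug start
#'   probability; larger values skew prescription prevalence toward rare
#'   drugs so only a minority exceed 30% patient prevalence.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_patients = 150L,
                         n_drugs = 60L,
                         n_genes = 500L,
                         ppi_attachment = 2L,
                         weighted_edges = FALSE,
                         module_size = 30L,
                         n_degs = 15L,
                         deg_noise = 0.2,
                         frac_proximal_drugs = 0.2,
                         typo_rate = 0.1,
                         mean_visits = 9,
                         mean_interval_days = 85,
                         planted_pairs = 5L,
                         n_pathways = 50L,
                         pathway_size_range = c(10L, 40L),
                         prevalence_dispersion = 8) {
  cfg <- list(seed = as.integer(seed),
              n_patients = as.integer(n_patients),
              n_drugs = as.integer(n_drugs),
              n_genes = as.integer(n_genes),
              ppi_attachment = as.integer(ppi_attachment),
              weighted_edges = isTRUE(weighted_edges),
              module_size = as.integer(module_size),
              n_degs = as.integer(n_degs),
              deg_noise = as.numeric(deg_noise),
              frac_proximal_drugs = as.numeric(frac_proximal_drugs),
              typo_rate = as.numeric(typo_rate),
              mean_visits = as.numeric(mean_visits),
              mean_interval_days = as.numeric(mean_interval_days),
              planted_pairs = as.integer(planted_pairs),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              prevalence_dispersion = as.numeric(prevalence_dispersion))
  counts <- c("n_patients", "n_drugs", "n_genes", "ppi_attachment",
              "module_size", "n_degs", "planted_pairs", "n_pathways")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L) stop(f, " must be a positive count")
  }
  for (f in c("deg_noise", "frac_proximal_drugs", "typo_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  for (f in c("mean_visits", "mean_interval_days", "prevalence_dispersion")) {
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  }
  if (cfg$module_size > cfg$n_genes) stop("module_size exceeds n_genes")
  if (cfg$n_degs > cfg$n_genes) stop("n_degs exceeds n_genes")
  if (length(cfg$pathway_size_range) != 2L ||
      any(cfg$pathway_size_range <= 0L) ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2]) {
    stop("pathway_size_range must be an increasing pair of positive counts")
  }
  structure(cfg, class = "synth_config")
}

# sub-seed derivation: distinct, reproducible streams per generator stage
.sub_seed <- function(cfg, offset) {
  as.integer((abs(as.numeric(cfg$seed)) * 131 + offset) %% 2147483629)
}
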