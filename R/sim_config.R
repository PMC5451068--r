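#' Simulation configuration
#'
#' Builds and validates the configuration that drives every synthetic-data
#' generator in the package.  Defaults mirror the scale of the original study
#' design (three cases and three controls, each with two technical
#' replicates; four planted co-expression modules over a developmental time
#' course; a multi-tissue median-expression panel with a brain subset) while
#' staying small enough that the full pipeline runs in minutes.
#'
#' @param seed integer master seed; every generator derives its own
#'   sub-stream from it, so outputs are bit-reproducible given `(seed, cfg)`.
#' @param n_genes total number of genes in the simulated annotation.
#' @param n_lncRNAs how many of those genes carry a lncRNA biotype.
#' @param n_case,n_control biological replicates per group.
#' @param n_tech_reps technical replicates per biological sample.
#' @param de_fraction fraction of genes with planted differential expression.
#' @param de_log2fc planted absolute effect size in log2 units.
#' @param nb_dispersion negative-binomial dispersion `alpha`
#'   (variance = mu + alpha * mu^2).
#' @param module_sizes integer vector of planted module sizes.
#' @param module_strength latent-factor loading in \[0, 1\]; the fraction of a
#'   module gene's standardized variance explained by the module trajectory.
#' @param n_dev_samples number of developmental (time-course) samples.
#' @param age_range_months length-2 numeric, min/max age in months
#'   post-conception; ages are drawn log-uniformly, mimicking dense prenatal
#'   sampling.
#' @param n_dev_background number of unstructured but variable genes in the
#'   developmental matrix (the rest of the genes get low variance so the
#'   standard variance filter removes them).
#' @param n_tissues,n_brain_tissues tissue-panel dimensions.
#' @param n_small_tissues how many non-brain tissues get fewer than 50
#'   samples (to exercise the panel filter).
#' @param brain_inflation multiplicative boost applied to brain-tissue means
#'   of planted brain-selective genes.
#' @param n_cnvs total CNV records emitted.
#' @param genome_length coordinate span of each artificial chromosome (bp).
#' @param n_chroms number of artificial chromosomes.
#' @param n_module_lnc lncRNAs planted inside the first (risk) module.
#' @param n_risk_genes protein-coding risk genes planted inside the first
#'   module.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$module_sizes
sim_config <- function(seed = 1L,
                       n_genes = 1200L,
                       n_lncRNAs = 120L,
                       n_case = 3L,
                       n_control = 3L,
                       n_tech_reps = 2L,
                       de_fraction = 0.05,
                       de_log2fc = 2,
                       nb_dispersion = 0.05,
                       module_sizes = c(100L, 80L, 60L, 40L),
                       module_strength = 0.7,
                       n_dev_samples = 100L,
                       age_range_months = c(2, 12),
                       n_dev_background = 320L,
                       n_tissues = 25L,
                       n_brain_tissues = 5L,
                       n_small_tissues = 3L,
                       brain_inflation = 20,
                       n_cnvs = 60L,
                       genome_length = 2e6,
                       n_chroms = 5L,
                       n_module_lnc = 10L,
                       n_risk_genes = 25L) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_lncRNAs = as.integer(n_lncRNAs), n_case = as.integer(n_case),
    n_control = as.integer(n_control), n_tech_reps = as.integer(n_tech_reps),
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    nb_dispersion = nb_dispersion, module_sizes = as.integer(module_sizes),
    module_strength = module_strength,
    n_dev_samples = as.integer(n_dev_samples),
    age_range_months = as.numeric(age_range_months),
    n_dev_background = as.integer(n_dev_background),
    n_tissues = as.integer(n_tissues),
    n_brain_tissues = as.integer(n_brain_tissues),
    n_small_tissues = as.integer(n_small_tissues),
    brain_inflation = brain_inflation,
    n_cnvs = as.integer(n_cnvs), genome_length = as.numeric(genome_length),
    n_chroms = as.integer(n_chroms),
    n_module_lnc = as.integer(n_module_lnc),
    n_risk_genes = as.integer(n_risk_genes)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, !is.na(cfg$seed),
    cfg$n_genes > 0L, cfg$n_lncRNAs >= 0L, cfg$n_lncRNAs <= cfg$n_genes,
    cfg$n_case > 0L, cfg$n_control > 0L, cfg$n_tech_reps > 0L,
    cfg$n_dev_samples > 1L, cfg$n_tissues > 0L, cfg$n_cnvs >= 0L,
    cfg$n_chroms > 0L, cfg$genome_length > 0
  )
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop("de_fraction must lie in [0, 1]")
  }
  if (cfg$module_strength < 0 || cfg$module_strength > 1) {
    stop("module_strength must lie in [0, 1]")
  }
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    stop("sum(module_sizes) exceeds n_genes")
  }
  if (any(cfg$module_sizes <= 0L)) stop("module_sizes must be positive")
  if (sum(cfg$module_sizes) + cfg$n_dev_background > cfg$n_genes) {
    stop("module genes plus developmental background exceed n_genes")
  }
  if (cfg$n_brain_tissues > cfg$n_tissues) {
    stop("n_brain_tissues cannot exceed n_tissues")
  }
  if (length(cfg$age_range_months) != 2L ||
      cfg$age_range_months[1] <= 0 ||
      cfg$age_range_months[2] <= cfg$age_range_months[1]) {
    stop("age_range_months must be an increasing positive pair")
  }
  if (cfg$n_module_lnc > cfg$n_lncRNAs) {
    stop("n_module_lnc exceeds n_lncRNAs")
  }
  if (length(cfg$module_sizes) > 0L &&
      cfg$n_module_lnc + cfg$n_risk_genes > cfg$module_sizes[1]) {
    stop("first module too small for planted lncRNAs plus risk genes")
  }
  invisible(cfg)
}
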