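#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators into a validated
#' configuration object.  The defaults describe the study conditions the
#' package is tested under: a common-variant reference panel (minor-allele
#' frequency floor 0.05) with block-structured linkage disequilibrium, Hi-C
#' contacts from four blood cell lines, fifteen immune cell types, an outcome
#' GWAS whose effective sample size matches a 3,305-case / 9,196-control
#' case-control design, and one GWAS-catalog trait planted at ten-fold
#' enrichment among the regulatory SNPs of the causal genes.
#'
#' @param n_snps number of panel SNPs.
#' @param n_genes number of simulated genes.
#' @param n_ref_individuals reference-panel individuals (diploid).
#' @param ld_block_size SNPs per LD block.
#' @param within_block_r2 target pairwise dosage r-squared within a block,
#'   in `[0, 1)`.
#' @param maf_min minor-allele-frequency floor, in `(0, 0.5)`.
#' @param n_instruments_per_gene length-2 integer range; each gene draws its
#'   true instrument count uniformly from this range.
#' @param frac_causal_genes proportion of genes given a nonzero causal effect
#'   on the outcome.
#' @param theta_causal causal effect per unit expression (log-odds scale).
#' @param pleiotropy_frac proportion of instruments given a direct
#'   (horizontal-pleiotropy) outcome effect.
#' @param pleiotropy_mean mean of the direct effects.
#' @param pleiotropy_sd standard deviation of the direct effects.
#' @param n_celltypes number of immune cell types emulated.
#' @param n_traits number of GWAS-catalog traits.
#' @param n_planted_traits how many traits are planted as enriched.
#' @param planted_enrichment_factor fold enrichment of catalog SNPs among the
#'   designated genes' regulatory SNPs (must be >= 1).
#' @param n_catalog_snps_per_trait catalog SNPs drawn per trait.
#' @param decoy_frac decoy SNP-gene pairs as a fraction of true pairs.
#' @param n_gwas_effective effective sample size used for all outcome
#'   standard errors; the default `9725` is `4/(1/3305 + 1/9196)`.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output tables.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_snps = 100, n_genes = 20, seed = 1)
#' cfg$maf_min
#' @export
sim_config <- function(n_snps = 900,
                       n_genes = 360,
                       n_ref_individuals = 500,
                       ld_block_size = 4,
                       within_block_r2 = 0.9,
                       maf_min = 0.05,
                       n_instruments_per_gene = c(1L, 3L),
                       frac_causal_genes = 0.017,
                       theta_causal = 0.5,
                       pleiotropy_frac = 0,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0.1,
                       n_celltypes = 15,
                       n_traits = 30,
                       n_planted_traits = 1,
                       planted_enrichment_factor = 10,
                       n_catalog_snps_per_trait = 200,
                       decoy_frac = 0.3,
                       n_gwas_effective = 9725,
                       seed = 1) {
  cfg <- list(
    n_snps = n_snps, n_genes = n_genes,
    n_ref_individuals = n_ref_individuals,
    ld_block_size = ld_block_size, within_block_r2 = within_block_r2,
    maf_min = maf_min,
    n_instruments_per_gene = as.integer(n_instruments_per_gene),
    frac_causal_genes = frac_causal_genes, theta_causal = theta_causal,
    pleiotropy_frac = pleiotropy_frac, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd,
    n_celltypes = n_celltypes, n_traits = n_traits,
    n_planted_traits = n_planted_traits,
    planted_enrichment_factor = planted_enrichment_factor,
    n_catalog_snps_per_trait = n_catalog_snps_per_trait,
    decoy_frac = decoy_frac, n_gwas_effective = n_gwas_effective,
    seed = seed)
  validate_sim_config(cfg)
  # canonical storage modes so configurations round-trip identically
  # through JSON serialization
  for (f in c("n_snps", "n_genes", "n_ref_individuals", "ld_block_size",
              "n_celltypes", "n_traits", "n_planted_traits",
              "n_catalog_snps_per_trait", "n_gwas_effective"))
    cfg[[f]] <- as.integer(cfg[[f]])
  for (f in c("within_block_r2", "maf_min", "frac_causal_genes",
              "theta_causal", "pleiotropy_frac", "pleiotropy_mean",
              "pleiotropy_sd", "planted_enrichment_factor", "decoy_frac",
              "seed"))
    cfg[[f]] <- as.double(cfg[[f]])
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  pos_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v))
      stop_config(field, "must be a single positive integer")
  }
  for (f in c("n_snps", "n_genes", "n_ref_individuals", "ld_block_size",
              "n_celltypes", "n_traits", "n_planted_traits",
              "n_catalog_snps_per_trait", "n_gwas_effective"))
    pos_count(f)
  prop <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop_config(field, "must be a proportion in [0, 1]")
  }
  for (f in c("frac_causal_genes", "pleiotropy_frac", "decoy_frac"))
    prop(f)
  if (cfg$within_block_r2 < 0 || cfg$within_block_r2 >= 1)
    stop_config("within_block_r2", "must lie in [0, 1)")
  if (cfg$maf_min <= 0 || cfg$maf_min >= 0.5)
    stop_config("maf_min", "must lie in (0, 0.5)")
  if (length(cfg$n_instruments_per_gene) != 2 ||
      any(cfg$n_instruments_per_gene < 1) ||
      cfg$n_instruments_per_gene[1] > cfg$n_instruments_per_gene[2])
    stop_config("n_instruments_per_gene",
                "must be an increasing pair of positive counts")
  if (cfg$pleiotropy_sd < 0)
    stop_config("pleiotropy_sd", "must be non-negative")
  if (cfg$planted_enrichment_factor < 1)
    stop_config("planted_enrichment_factor", "must be >= 1")
  if (cfg$n_planted_traits > cfg$n_traits)
    stop_config("n_planted_traits", "cannot exceed n_traits")
  if (cfg$n_snps %% cfg$ld_block_size != 0)
    stop_config("ld_block_size", "must divide n_snps evenly")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    stop_config("seed", "must be a single integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-study configuration\n")
  cat(sprintf("  panel: %d SNPs x %d individuals; LD blocks of %d (target r2 %.2f); MAF floor %.2f\n",
              x$n_snps, x$n_ref_individuals, x$ld_block_size,
              x$within_block_r2, x$maf_min))
  cat(sprintf("  genes: %d (%.0f%% causal, theta = %.2f); instruments per gene %d-%d\n",
              x$n_genes, 100 * x$frac_causal_genes, x$theta_causal,
              x$n_instruments_per_gene[1], x$n_instruments_per_gene[2]))
  cat(sprintf("  gwas: effective n = %d; pleiotropy frac %.2f (mean %.2f, sd %.2f)\n",
              x$n_gwas_effective, x$pleiotropy_frac, x$pleiotropy_mean,
              x$pleiotropy_sd))
  cat(sprintf("  catalog: %d traits (%d planted at %gx), %d SNPs/trait; %d cell types; seed %s\n",
              x$n_traits, x$n_planted_traits, x$planted_enrichment_factor,
              x$n_catalog_snps_per_trait, x$n_celltypes,
              format(x$seed)))
  invisible(x)
}
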