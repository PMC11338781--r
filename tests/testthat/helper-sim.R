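# Small study configurations used throughout the suite.

tiny_cfg <- function(seed = 1, ...) {
  args <- list(n_snps = 120, n_genes = 20, n_ref_individuals = 150,
               ld_block_size = 4, frac_causal_genes = 0.15, n_traits = 8,
               n_catalog_snps_per_trait = 40, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# harmonised-instrument frame straight from effect sizes (already aligned)
h_frame <- function(beta_exposure, beta_outcome, se_outcome,
                    se_exposure = rep(0.05, length(beta_exposure))) {
  n <- length(beta_exposure)
  h <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    effect_allele = "A", other_allele = "G",
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    p_exposure = 1e-8, eaf = 0.3,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    risk_allele = ifelse(beta_outcome >= 0, "effect", "other"),
    orientation_sign = ifelse(beta_outcome >= 0, 1, -1),
    stringsAsFactors = FALSE)
  class(h) <- c("harmonised_instruments", "data.frame")
  h
}

# panel stub with explicit dosage columns
panel_from_dosage <- function(dosage, eaf = colMeans(dosage) / 2,
                              pos = seq_len(ncol(dosage)) * 50L - 25L) {
  n <- ncol(dosage)
  snps <- data.frame(
    snp_id = colnames(dosage) %||% sprintf("rs%03d", seq_len(n)),
    chrom = "chr1", pos = pos,
    ref = "A", alt = "G", eaf = eaf, block = 1L,
    stringsAsFactors = FALSE)
  colnames(dosage) <- snps$snp_id
  structure(list(snps = snps, dosage = dosage, maf_min = 0),
            class = "genotype_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
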