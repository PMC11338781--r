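#' Simulate outcome GWAS summary statistics
#'
#' Draws case-control (log-odds) summary statistics for every panel SNP under
#' the generative model the MR estimators assume: for instrument j of gene g,
#' `beta_outcome = theta_g * beta_exposure_j + alpha_j + noise`, where
#' `alpha_j` is zero for valid instruments and
#' `Normal(pleiotropy_mean, pleiotropy_sd^2)` for the configured pleiotropic
#' fraction; non-instrument SNPs receive pure null effects.  Direct effects
#' are expressed per exposure-increasing allele (the orientation MR-Egger
#' regresses on), so a nonzero `pleiotropy_mean` is genuinely directional:
#' on the panel's alt-allele scale the contribution is
#' `sign(beta_exposure_j) * alpha_j`.  All standard
#' errors derive from the single configured effective sample size,
#' `se_j = 1 / sqrt(n_eff * 2 * eaf_j * (1 - eaf_j))`, and the sampling noise
#' added to each beta has exactly that standard deviation, so Wald z-scores
#' are standard normal under the null.  Roughly half of the rows report their
#' effect on the panel's reference allele (with beta and frequency flipped)
#' so harmonisation is exercised end to end.
#'
#' @param cfg a [sim_config()] object.
#' @param panel a `genotype_panel`.
#' @param eqtl the exposure eQTL table (instrument SNPs must appear here).
#' @param theta named numeric vector mapping gene ids to causal effects;
#'   genes absent from `eqtl` raise an error.
#' @return a data frame in GWAS-SSF-like columns: `rsid`, `chromosome`,
#'   `base_pair_location`, `effect_allele`, `other_allele`,
#'   `effect_allele_frequency`, `beta`, `standard_error`, `p_value`, plus a
#'   `pleiotropic` truth flag.
#' @export
simulate_outcome_gwas <- function(cfg, panel, eqtl, theta) {
  validate_sim_config(cfg)
  if (is.null(names(theta)) && length(theta) > 0)
    stop("'theta' must be a named gene -> effect map", call. = FALSE)
  unknown <- setdiff(names(theta), unique(eqtl$gene_id))
  if (length(unknown))
    stop(sprintf("unknown gene(s) in causal-effect map: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)

  with_seed(seed_for(cfg, 4L), {
    snps <- panel$snps
    se <- 1 / sqrt(cfg$n_gwas_effective * 2 * snps$eaf * (1 - snps$eaf))

    # mediated effect through expression, summed over a SNP's target genes
    effect <- numeric(nrow(snps))
    th <- theta[match(eqtl$gene_id, names(theta))]
    th[is.na(th)] <- 0
    med <- tapply(th * eqtl$beta, eqtl$snp_id, sum)
    hit <- match(names(med), snps$snp_id)
    effect[hit] <- as.numeric(med)

    # horizontal pleiotropy on a configured fraction of instrument SNPs;
    # drawn per exposure-increasing allele, then mapped to the alt-allele
    # scale through the sign of the SNP's exposure beta
    alpha <- numeric(nrow(snps))
    pleio <- logical(nrow(snps))
    iv_snps <- unique(eqtl$snp_id)
    n_pleio <- floor(cfg$pleiotropy_frac * length(iv_snps))
    if (n_pleio > 0) {
      chosen <- sample(iv_snps, n_pleio)
      j <- match(chosen, snps$snp_id)
      exp_sign <- sign(tapply(eqtl$beta, eqtl$snp_id, function(x) x[1]))
      alpha[j] <- as.numeric(exp_sign[chosen]) *
        stats::rnorm(n_pleio, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
      pleio[j] <- TRUE
    }

    beta <- effect + alpha + stats::rnorm(nrow(snps), 0, se)
    flip <- stats::runif(nrow(snps)) < 0.5
    out <- data.frame(
      rsid = snps$snp_id,
      chromosome = snps$chrom,
      base_pair_location = snps$pos,
      effect_allele = ifelse(flip, snps$ref, snps$alt),
      other_allele = ifelse(flip, snps$alt, snps$ref),
      effect_allele_frequency = ifelse(flip, 1 - snps$eaf, snps$eaf),
      beta = ifelse(flip, -beta, beta),
      standard_error = se,
      p_value = 2 * stats::pnorm(-abs(beta / se)),
      pleiotropic = pleio,
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

# which genes carry a causal effect; a pure function of the configuration
# so the regulatory-world generator and the truth map agree on the set
causal_gene_ids <- function(cfg) {
  n_causal <- round(cfg$frac_causal_genes * cfg$n_genes)
  if (n_causal == 0) return(character(0))
  with_seed(seed_for(cfg, 5L),
            sample(sprintf("G%03d", seq_len(cfg$n_genes)), n_causal))
}

#' Draw the causal-gene truth map
#'
#' Samples `round(frac_causal_genes * n_genes)` genes and assigns them the
#' configured causal effect; all other genes are null.  The sampled set is a
#' pure function of the configuration, and coincides with the genes whose
#' instruments [simulate_regulatory_world()] places in exclusive LD blocks.
#'
#' @param cfg a [sim_config()] object.
#' @param genes gene table (needs `gene_id`).
#' @return named numeric vector over all genes (0 for nulls).
#' @export
simulate_causal_truth <- function(cfg, genes) {
  validate_sim_config(cfg)
  theta <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  causal <- intersect(causal_gene_ids(cfg), genes$gene_id)
  theta[causal] <- cfg$theta_causal
  theta
}
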