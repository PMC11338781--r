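#' Simulate a block-LD genotype reference panel
#'
#' Generates a diploid reference panel with block-diagonal linkage
#' disequilibrium by a haplotype-copying scheme: each block is seeded by one
#' ancestral haplotype per sampled chromosome, and every site in the block
#' copies the ancestral allele with probability `within_block_r2^(1/4)`
#' (otherwise drawing a fresh allele at the block frequency).  Under this
#' scheme every pair of distinct sites in a block has dosage correlation
#' `within_block_r2^(1/2)`, i.e. pairwise r-squared at the configured target,
#' while sites in different blocks are independent.  Blocks are regenerated
#' until every site's folded minor-allele frequency clears `cfg$maf_min`, so
#' the emitted panel never violates the common-variant floor.
#'
#' Ref/alt allele pairs are drawn from the non-complementary nucleotide pairs,
#' mirroring the usual practice of excluding strand-ambiguous (palindromic)
#' variants from instrument panels; palindromic edge cases are exercised by
#' constructing them explicitly.
#'
#' @param cfg a [sim_config()] object.
#' @return an object of class `genotype_panel`: a list with `snps` (data frame
#'   with `snp_id`, `chrom`, `pos`, `ref`, `alt`, `eaf` (alt-allele
#'   frequency), `block`) and `dosage` (individuals x SNPs integer matrix of
#'   alt-allele counts in 0..2, columns named by `snp_id`).
#' @examples
#' p <- simulate_panel(sim_config(n_snps = 40, n_ref_individuals = 100))
#' dim(p$dosage)
#' @export
simulate_panel <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(seed_for(cfg, 1L), {
    n_blocks <- cfg$n_snps %/% cfg$ld_block_size
    b <- cfg$ld_block_size
    n_hap <- 2L * cfg$n_ref_individuals
    copy_p <- cfg$within_block_r2^(1 / 4)

    dosage <- matrix(0L, nrow = cfg$n_ref_individuals, ncol = cfg$n_snps)
    eaf <- numeric(cfg$n_snps)
    for (blk in seq_len(n_blocks)) {
      idx <- (blk - 1L) * b + seq_len(b)
      for (try in 1:100) {
        p_blk <- stats::runif(1, 0.15, 0.45)
        anc <- stats::rbinom(n_hap, 1L, p_blk)
        haps <- matrix(0L, nrow = n_hap, ncol = b)
        for (j in seq_len(b)) {
          keep <- stats::rbinom(n_hap, 1L, copy_p) == 1L
          fresh <- stats::rbinom(n_hap, 1L, p_blk)
          haps[, j] <- ifelse(keep, anc, fresh)
        }
        dos <- haps[seq_len(cfg$n_ref_individuals), , drop = FALSE] +
          haps[cfg$n_ref_individuals + seq_len(cfg$n_ref_individuals), ,
               drop = FALSE]
        f <- colMeans(dos) / 2
        if (all(pmin(f, 1 - f) >= cfg$maf_min)) {
          dosage[, idx] <- dos
          eaf[idx] <- f
          break
        }
        if (try == 100)
          stop("could not satisfy the minor-allele-frequency floor; ",
               "lower maf_min or increase n_ref_individuals", call. = FALSE)
      }
    }

    # non-palindromic ref/alt pairs: for each ref the two alts that are
    # neither identical nor the strand complement
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, cfg$n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) {
      sample(setdiff(bases, c(r, dna_complement(r))), 1L)
    }, character(1))

    # genomic layout: one SNP per 10 kb, LD blocks separated by 300 kb
    # gaps, so block membership and physical distance agree the way they
    # do in real data (distance-windowed clumping, default window 250 kb,
    # then never compares SNPs from different blocks)
    block_idx <- rep(seq_len(n_blocks), each = b)
    within_idx <- rep(seq_len(b), times = n_blocks)
    block_span <- b * 10000L
    snps <- data.frame(
      snp_id = sprintf("rs%05d", seq_len(cfg$n_snps)),
      chrom = "chr1",
      pos = (block_idx - 1L) * (block_span + 300000L) +
        (within_idx - 1L) * 10000L + 25L,
      ref = ref, alt = unname(alt), eaf = eaf,
      block = block_idx,
      stringsAsFactors = FALSE)
    colnames(dosage) <- snps$snp_id
    structure(list(snps = snps, dosage = dosage, maf_min = cfg$maf_min),
              class = "genotype_panel")
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype reference panel: %d SNPs x %d individuals (%d LD blocks)\n",
              nrow(x$snps), nrow(x$dosage), length(unique(x$snps$block))))
  invisible(x)
}

#' Pairwise LD (r-squared) between two panel SNPs
#'
#' Squared Pearson correlation of alt-allele dosages across the reference
#' individuals.
#'
#' @param panel a `genotype_panel`.
#' @param snp_a,snp_b SNP identifiers present in the panel.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(panel, snp_a, snp_b) {
  for (s in c(snp_a, snp_b))
    if (!s %in% colnames(panel$dosage))
      stop(sprintf("SNP '%s' is not in the reference panel", s), call. = FALSE)
  a <- panel$dosage[, snp_a]
  b <- panel$dosage[, snp_b]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("LD is undefined for a monomorphic SNP", call. = FALSE)
  stats::cor(a, b)^2
}

# r-squared matrix for a set of panel SNPs (internal; vectorised cor)
ld_r2_matrix <- function(panel, snps) {
  d <- panel$dosage[, snps, drop = FALSE]
  v <- apply(d, 2, stats::var)
  if (any(v == 0))
    stop(sprintf("LD is undefined for monomorphic SNP(s): %s",
                 paste(snps[v == 0], collapse = ", ")), call. = FALSE)
  stats::cor(d)^2
}
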