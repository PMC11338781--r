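#' Look up instrument SNP-gene pairs in per-cell-type eQTL tables
#'
#' Restricts the cell-type analysis to exactly the SNP-gene relationships
#' that served as MR instruments: only exact (SNP, gene) matches are
#' returned, so a different gene regulated by the same SNP is excluded.
#' Within each cell type, the looked-up pairs form one Benjamini-Hochberg
#' family; pairs absent from a cell type are simply missing there.
#'
#' @param iv_pairs data frame with `snp_id`, `gene_id` (the surviving MR
#'   instruments).
#' @param celltype_tables either a single eQTL table with a `context` column
#'   holding cell-type labels, or a named list of per-cell-type tables.
#' @return data frame `snp_id`, `gene_id`, `cell_type`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`, `adj_pval` (only matched rows).
#' @export
lookup_iv_effects <- function(iv_pairs, celltype_tables) {
  assert_cols(iv_pairs, c("snp_id", "gene_id"), "instrument pair list")
  if (nrow(iv_pairs) == 0)
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      cell_type = character(0), effect_allele = character(0),
                      other_allele = character(0), beta = numeric(0),
                      se = numeric(0), pval = numeric(0),
                      adj_pval = numeric(0)))
  if (is.data.frame(celltype_tables)) {
    assert_cols(celltype_tables, "context", "cell-type eQTL table")
    celltype_tables <- split(celltype_tables, celltype_tables$context)
  }
  iv_key <- paste(iv_pairs$snp_id, iv_pairs$gene_id)
  out <- lapply(names(celltype_tables), function(ct) {
    tab <- celltype_tables[[ct]]
    assert_cols(tab, c("snp_id", "gene_id", "beta", "se", "pval"),
                sprintf("eQTL table for '%s'", ct))
    hit <- tab[paste(tab$snp_id, tab$gene_id) %in% iv_key, , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    data.frame(snp_id = hit$snp_id, gene_id = hit$gene_id, cell_type = ct,
               effect_allele = hit$effect_allele %||% NA_character_,
               other_allele = hit$other_allele %||% NA_character_,
               beta = hit$beta, se = hit$se, pval = hit$pval,
               adj_pval = bh_adjust(hit$pval), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(snp_id = character(0), gene_id = character(0),
                      cell_type = character(0), effect_allele = character(0),
                      other_allele = character(0), beta = numeric(0),
                      se = numeric(0), pval = numeric(0),
                      adj_pval = numeric(0))
  rownames(out) <- NULL
  out
}

#' Orient cell-type eQTL effects to the risk allele
#'
#' Re-signs every reported cell-type effect so that its direction refers to
#' the risk allele established during harmonisation: if a table reports its
#' beta against the non-risk allele the sign is flipped, so "up" always means
#' up-regulation by the risk allele.  The alignment is allele-aware (label
#' swap or strand complement both resolve), which makes the oriented matrix
#' invariant under arbitrary ref/alt relabelling of the inputs.
#'
#' @param raw_effects output of [lookup_iv_effects()].
#' @param harmonised `harmonised_instruments` (with `gene_id` column, as
#'   stored in an `mr_scan`) supplying the risk allele per pair.
#' @return list with `beta` (pairs x cell types matrix of oriented betas,
#'   rownames `"snp_gene"`, missing cells `NA`), `significant` (logical
#'   matrix, `adj_pval <= 0.05`), and `long` (the oriented long table).
#' @export
orient_to_risk <- function(raw_effects, harmonised) {
  assert_cols(harmonised, c("snp_id", "gene_id", "effect_allele",
                            "other_allele", "risk_allele"),
              "harmonised instruments")
  if (nrow(raw_effects) == 0)
    return(list(beta = matrix(numeric(0), 0, 0),
                significant = matrix(logical(0), 0, 0),
                long = raw_effects))
  hkey <- paste(harmonised$snp_id, harmonised$gene_id)
  idx <- match(paste(raw_effects$snp_id, raw_effects$gene_id), hkey)
  if (anyNA(idx))
    stop(sprintf("pair(s) lack a harmonisation record: %s",
                 paste(unique(paste(raw_effects$snp_id,
                                    raw_effects$gene_id)[is.na(idx)]),
                       collapse = ", ")), call. = FALSE)
  risk_base <- ifelse(harmonised$risk_allele[idx] == "effect",
                      harmonised$effect_allele[idx],
                      harmonised$other_allele[idx])
  rep_ea <- toupper(raw_effects$effect_allele)
  rep_oa <- toupper(raw_effects$other_allele)
  sign_align <- ifelse(
    rep_ea == risk_base | dna_complement(rep_ea) == risk_base, 1,
    ifelse(rep_oa == risk_base | dna_complement(rep_oa) == risk_base, -1,
           NA_real_))
  if (anyNA(sign_align))
    stop("reported alleles incompatible with the harmonised pair for: ",
         paste(unique(raw_effects$snp_id[is.na(sign_align)]),
               collapse = ", "), call. = FALSE)

  long <- raw_effects
  long$beta_oriented <- sign_align * raw_effects$beta
  long$significant <- long$adj_pval <= 0.05
  pairs <- sort(unique(paste(long$snp_id, long$gene_id, sep = "_")))
  cts <- sort(unique(long$cell_type))
  beta <- matrix(NA_real_, length(pairs), length(cts),
                 dimnames = list(pairs, cts))
  sig <- matrix(NA, length(pairs), length(cts),
                dimnames = list(pairs, cts))
  pk <- paste(long$snp_id, long$gene_id, sep = "_")
  beta[cbind(match(pk, pairs), match(long$cell_type, cts))] <-
    long$beta_oriented
  sig[cbind(match(pk, pairs), match(long$cell_type, cts))] <-
    long$significant
  list(beta = beta, significant = sig, long = long)
}
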