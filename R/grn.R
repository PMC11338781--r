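#' Assign SNPs and genes to restriction fragments
#'
#' Maps every SNP to its unique containing fragment and every gene to the set
#' of fragments overlapping its body.  Coordinates are 0-based half-open
#' throughout (BED convention): a SNP at position p lies in fragment
#' `[start, end)` iff `start <= p < end`, and a gene `[gstart, gend)` overlaps
#' a fragment iff `gstart < end` and `gend > start`.
#'
#' @param snps data frame with `snp_id`, `chrom`, `pos`.
#' @param genes data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param fragments data frame with `chrom`, `start`, `end`, `fragment_id`;
#'   fragments must be non-overlapping within a chromosome.
#' @return list with `snp_map` (`snp_id`, `fragment_id`) and `gene_map`
#'   (`gene_id`, `fragment_id`, one row per overlapped fragment).
#' @examples
#' frags <- data.frame(chrom = "chr1", start = c(100, 200, 300),
#'                     end = c(200, 300, 400), fragment_id = c("F1", "F2", "F3"))
#' snps <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 150)
#' genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 180, end = 320)
#' assign_fragments(snps, genes, frags)
#' @export
assign_fragments <- function(snps, genes, fragments) {
  assert_cols(snps, c("snp_id", "chrom", "pos"), "SNP table")
  assert_cols(genes, c("gene_id", "chrom", "start", "end"), "gene table")
  assert_cols(fragments, c("chrom", "start", "end", "fragment_id"),
              "fragment map")

  snp_map <- data.frame(snp_id = snps$snp_id,
                        fragment_id = NA_character_,
                        stringsAsFactors = FALSE)
  gene_rows <- list()
  for (chr in unique(fragments$chrom)) {
    fr <- fragments[fragments$chrom == chr, ]
    fr <- fr[order(fr$start), ]
    si <- which(snps$chrom == chr)
    if (length(si)) {
      # findInterval against sorted starts, then verify half-open containment
      j <- findInterval(snps$pos[si], fr$start)
      ok <- j >= 1 & ifelse(j >= 1, snps$pos[si] < fr$end[pmax(j, 1)], FALSE)
      snp_map$fragment_id[si[ok]] <- fr$fragment_id[j[ok]]
    }
    gi <- which(genes$chrom == chr)
    for (g in gi) {
      hit <- fr$fragment_id[genes$start[g] < fr$end & genes$end[g] > fr$start]
      if (length(hit))
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = genes$gene_id[g], fragment_id = hit,
          stringsAsFactors = FALSE)
    }
  }
  uncovered <- snp_map$snp_id[is.na(snp_map$fragment_id)]
  if (length(uncovered))
    stop(sprintf("SNP(s) outside all fragments: %s",
                 paste(uncovered, collapse = ", ")), call. = FALSE)
  gene_map <- if (length(gene_rows)) do.call(rbind, gene_rows)
              else data.frame(gene_id = character(0),
                              fragment_id = character(0))
  rownames(gene_map) <- NULL
  list(snp_map = snp_map, gene_map = gene_map)
}

#' Find candidate spatial SNP-gene pairs from Hi-C contacts
#'
#' A cell line supports a (SNP, gene) pair if any fragment of the gene is in
#' contact with the SNP's fragment in that cell line.  Contacts are treated
#' as unordered and deduplicated per cell line (Hi-C matrices are symmetric);
#' pairs with zero supporting cell lines are not emitted.
#'
#' @param contacts data frame with `frag_a`, `frag_b`, `cell_line`.
#' @param assignments list from [assign_fragments()].
#' @return data frame `snp_id`, `gene_id`, `n_cell_lines`.
#' @export
find_spatial_pairs <- function(contacts, assignments) {
  assert_cols(contacts, c("frag_a", "frag_b", "cell_line"), "contact table")
  if (nrow(contacts) == 0)
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      n_cell_lines = integer(0)))
  a <- pmin(contacts$frag_a, contacts$frag_b)
  b <- pmax(contacts$frag_a, contacts$frag_b)
  cl <- contacts$cell_line
  dedup <- !duplicated(paste(a, b, cl))
  # both orientations so SNP fragments can sit on either side
  dir <- data.frame(fa = c(a[dedup], b[dedup]), fb = c(b[dedup], a[dedup]),
                    cell_line = c(cl[dedup], cl[dedup]),
                    stringsAsFactors = FALSE)
  m1 <- merge(dir, assignments$snp_map, by.x = "fa", by.y = "fragment_id")
  if (nrow(m1) == 0 || nrow(assignments$gene_map) == 0)
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      n_cell_lines = integer(0)))
  m2 <- merge(m1, assignments$gene_map, by.x = "fb", by.y = "fragment_id")
  if (nrow(m2) == 0)
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      n_cell_lines = integer(0)))
  key <- paste(m2$snp_id, m2$gene_id)
  support <- tapply(m2$cell_line, key, function(x) length(unique(x)))
  parts <- strsplit(names(support), " ", fixed = TRUE)
  out <- data.frame(
    snp_id = vapply(parts, `[`, character(1), 1L),
    gene_id = vapply(parts, `[`, character(1), 2L),
    n_cell_lines = as.integer(support),
    stringsAsFactors = FALSE)
  out <- out[order(out$snp_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving, capped at 1.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Build the spatially constrained gene regulatory network
#'
#' Joins candidate contact-supported SNP-gene pairs to eQTL summary rows,
#' applies a single Benjamini-Hochberg correction across all joined pairs,
#' and retains pairs with adjusted p <= `fdr`.  Candidates without an eQTL
#' row are dropped (the physical contact alone is not evidence of
#' regulation); the eQTL join is not restricted to a cis window — the contact
#' requirement is the spatial constraint.
#'
#' @param candidates data frame from [find_spatial_pairs()].
#' @param eqtl eQTL table with `snp_id`, `gene_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`.
#' @param fdr adjusted-p retention threshold (default 0.05).
#' @return an object of class `spatial_grn`; its `edges` element holds
#'   `snp_id`, `gene_id`, `n_cell_lines`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pval`, `adj_pval`.
#' @export
build_grn <- function(candidates, eqtl, fdr = 0.05) {
  assert_cols(candidates, c("snp_id", "gene_id", "n_cell_lines"),
              "candidate table")
  assert_cols(eqtl, c("snp_id", "gene_id", "effect_allele", "other_allele",
                      "beta", "se", "pval"), "eQTL table")
  joined <- merge(candidates, eqtl[c("snp_id", "gene_id", "effect_allele",
                                     "other_allele", "beta", "se", "pval")],
                  by = c("snp_id", "gene_id"))
  if (nrow(joined) == 0) {
    warning("no candidate pair had an eQTL record; the network is empty")
    edges <- data.frame(snp_id = character(0), gene_id = character(0),
                        n_cell_lines = integer(0),
                        effect_allele = character(0),
                        other_allele = character(0), beta = numeric(0),
                        se = numeric(0), pval = numeric(0),
                        adj_pval = numeric(0))
    return(new_spatial_grn(edges, fdr, 0L))
  }
  joined <- joined[order(joined$snp_id, joined$gene_id), ]
  joined$adj_pval <- bh_adjust(joined$pval)
  edges <- joined[joined$adj_pval <= fdr, ]
  rownames(edges) <- NULL
  new_spatial_grn(edges, fdr, nrow(joined))
}

new_spatial_grn <- function(edges, fdr, n_tested) {
  structure(list(edges = edges, fdr = fdr, n_tested = n_tested,
                 by_gene = split(seq_len(nrow(edges)), edges$gene_id),
                 by_snp = split(seq_len(nrow(edges)), edges$snp_id)),
            class = "spatial_grn")
}

#' SNPs regulating a gene, and genes regulated by a SNP
#'
#' Index helpers over a `spatial_grn`.
#'
#' @param grn a `spatial_grn`.
#' @param gene_id,snp_id identifier to look up.
#' @return character vector (empty if absent).
#' @export
grn_snps <- function(grn, gene_id) {
  idx <- grn$by_gene[[gene_id]]
  if (is.null(idx)) character(0) else grn$edges$snp_id[idx]
}

#' @rdname grn_snps
#' @export
grn_genes <- function(grn, snp_id) {
  idx <- grn$by_snp[[snp_id]]
  if (is.null(idx)) character(0) else grn$edges$gene_id[idx]
}

#' @export
print.spatial_grn <- function(x, ...) {
  cat(sprintf(paste0("Spatial eQTL gene regulatory network: %d SNP-gene ",
                     "edges (%d SNPs, %d genes)\n"),
              nrow(x$edges), length(x$by_snp), length(x$by_gene)))
  cat(sprintf("  retained at BH-adjusted p <= %g out of %d tested pairs\n",
              x$fdr, x$n_tested))
  invisible(x)
}

#' @export
summary.spatial_grn <- function(object, ...) {
  e <- object$edges
  cat(sprintf("Edges: %d; genes: %d; SNPs: %d; tested pairs: %d (FDR %g)\n",
              nrow(e), length(object$by_gene), length(object$by_snp),
              object$n_tested, object$fdr))
  if (nrow(e)) {
    cat("Cell-line support:\n")
    print(table(e$n_cell_lines))
    cat(sprintf("Instruments per gene: median %g, max %d\n",
                stats::median(lengths(object$by_gene)),
                max(lengths(object$by_gene))))
  }
  invisible(object)
}

#' @export
as.data.frame.spatial_grn <- function(x, ...) x$edges
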