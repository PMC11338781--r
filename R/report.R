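#' Gene-by-trait evidence matrix for one expansion level
#'
#' Cells hold `log10(count + 1)` of the distinct catalog SNPs for a trait
#' that are credited to a gene: a catalog SNP is credited to gene g when it
#' belongs to the LD-expanded set of g's spatial eQTLs (the eQTL itself or
#' any partner at the configured r-squared).  A SNP credited to several genes
#' counts once per gene; a zero count stays exactly 0 under the log1p-style
#' convention.
#'
#' @param enrich a `trait_enrichment` from [trait_enrichment_scan()] (must
#'   carry provenance).
#' @param level which expansion level (0-based).
#' @param catalog the trait catalog used in the scan.
#' @param traits columns to include; defaults to the traits significant at
#'   this level.
#' @return numeric matrix, rows = the level's genes, columns = traits.
#' @export
gene_trait_matrix <- function(enrich, level, catalog, traits = NULL) {
  if (is.null(enrich$provenance))
    stop("this trait_enrichment carries no provenance; rerun the scan",
         call. = FALSE)
  prov <- enrich$provenance[[paste0("level", level)]]
  if (is.null(prov))
    stop(sprintf("no provenance for level %s", level), call. = FALSE)
  if (is.null(traits)) {
    t <- enrich$table
    traits <- sort(t$trait[t$level == level & t$significant])
  }
  catalog <- catalog[!duplicated(catalog[c("snp_id", "trait")]), ]
  catalog <- catalog[catalog$trait %in% traits, ]
  genes <- prov$genes
  m <- matrix(0, length(genes), length(traits),
              dimnames = list(genes, traits))
  if (nrow(prov$pairs) == 0 || length(traits) == 0) return(m)
  # expanded SNP -> source eQTL -> gene; count distinct catalog SNPs per cell
  link <- merge(prov$expansion, prov$pairs,
                by.x = "source_snp", by.y = "snp_id")
  hits <- merge(link[c("snp_id", "gene_id")], catalog,
                by = "snp_id")
  if (nrow(hits) == 0) return(m)
  hits <- hits[!duplicated(hits[c("snp_id", "gene_id", "trait")]), ]
  counts <- unclass(table(factor(hits$gene_id, levels = genes),
                          factor(hits$trait, levels = traits)))
  m <- log10(counts + 1)
  dimnames(m) <- list(genes, traits)
  m
}

#' Agglomerative hierarchical clustering of an evidence matrix
#'
#' Standard agglomerative clustering (via [stats::hclust()]) of rows and,
#' when requested, columns.  Rows are ordered lexicographically by label
#' before clustering so merge order is deterministic under ties; missing
#' cells are imputed per row (row mean, or zero) for the distance
#' computation only — the matrix itself is returned untouched.
#'
#' @param m numeric matrix (rownames and colnames required).
#' @param distance distance metric passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param missing imputation policy for `NA` cells: `"row_mean"` or
#'   `"zero"`.
#' @param cluster_cols also cluster columns (default TRUE when >= 2).
#' @return list with `rows` and `cols` (`hclust` objects or `NULL` when an
#'   axis has fewer than 2 entries).
#' @export
hcluster_matrix <- function(m, distance = "euclidean", linkage = "complete",
                            missing = c("row_mean", "zero"),
                            cluster_cols = TRUE) {
  missing <- match.arg(missing)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("the matrix must have row and column names", call. = FALSE)
  all_na <- rownames(m)[rowSums(!is.na(m)) == 0]
  if (length(all_na))
    stop(sprintf("row(s) with no observed cells cannot be clustered: %s",
                 paste(all_na, collapse = ", ")), call. = FALSE)
  imp <- m[order(rownames(m)), , drop = FALSE]
  if (anyNA(imp)) {
    if (missing == "row_mean") {
      rm_ <- rowMeans(imp, na.rm = TRUE)
      idx <- which(is.na(imp), arr.ind = TRUE)
      imp[idx] <- rm_[idx[, 1]]
    } else imp[is.na(imp)] <- 0
  }
  cluster_axis <- function(x) {
    if (nrow(x) < 2) return(NULL)
    stats::hclust(stats::dist(x, method = distance), method = linkage)
  }
  rows <- cluster_axis(imp)
  cols <- if (cluster_cols)
    cluster_axis(t(imp)[order(colnames(imp)), , drop = FALSE]) else NULL
  list(rows = rows, cols = cols)
}

#' Write publication-style result tables
#'
#' Emits deterministic TSVs: the MR causal-gene table (gene, instruments,
#' method, odds ratio, p), the risk-allele-oriented cell-type matrix with
#' cluster-derived row/column orders, per-level trait-enrichment tables, and
#' per-level gene-by-trait matrices; dendrograms are serialized as newick.
#'
#' @param mr an `mr_scan`.
#' @param oriented output of [orient_to_risk()] (or `NULL`).
#' @param enrich a `trait_enrichment` (or `NULL`).
#' @param matrices named list of gene-trait matrices (or `NULL`).
#' @param outdir output directory (created if needed).
#' @param distance,linkage clustering parameters forwarded to
#'   [hcluster_matrix()].
#' @return invisibly, the vector of files written.
#' @export
write_reports <- function(mr, oriented = NULL, enrich = NULL,
                          matrices = NULL, outdir,
                          distance = "euclidean", linkage = "complete") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv(df, path)
    written <<- c(written, path)
  }
  ivs <- tapply(mr$harmonised$snp_id, mr$harmonised$gene_id,
                function(s) paste(sort(s), collapse = ", "))
  res <- mr$results
  mr_tab <- data.frame(
    gene = res$gene_id,
    instrumental_variables = as.character(ivs[res$gene_id]),
    method = res$method,
    odds_ratio = res$odds_ratio,
    mr_pval = res$pval,
    significant = res$significant,
    stringsAsFactors = FALSE)
  emit(mr_tab, "mr_causal_genes.tsv")
  emit(res, "mr_full_results.tsv")

  emit_matrix <- function(mat, stem) {
    df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    emit(df, paste0(stem, ".tsv"))
    if (nrow(mat) >= 2) {
      cl <- hcluster_matrix(mat, distance = distance, linkage = linkage)
      ord <- data.frame(
        row_order = paste(rownames(mat)[order(rownames(mat))][cl$rows$order],
                          collapse = ","),
        col_order = if (!is.null(cl$cols))
          paste(colnames(mat)[order(colnames(mat))][cl$cols$order],
                collapse = ",") else NA_character_)
      emit(ord, paste0(stem, "_order.tsv"))
      nwk <- file.path(outdir, paste0(stem, "_rows.nwk"))
      ape::write.tree(ape::as.phylo(cl$rows), file = nwk)
      written <<- c(written, nwk)
    }
  }
  if (!is.null(oriented) && nrow(oriented$beta) > 0) {
    emit_matrix(oriented$beta, "celltype_oriented_beta")
    sig <- oriented$significant
    emit(data.frame(id = rownames(sig), sig, check.names = FALSE),
         "celltype_significance.tsv")
  }
  if (!is.null(enrich))
    emit(as.data.frame(enrich), "trait_enrichment.tsv")
  for (nm in names(matrices))
    if (!is.null(matrices[[nm]]) && length(matrices[[nm]]) > 0)
      emit_matrix(matrices[[nm]], paste0("gene_trait_", nm))
  invisible(written)
}
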