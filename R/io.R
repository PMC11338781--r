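# Readers and writers for the pipeline's plain-text exchange formats.
# Everything is tab-separated with a header, except the fragment map (BED)
# and the panel VCF.

#' Read and write the pipeline's table formats
#'
#' Fragment maps travel as BED (0-based half-open, fragment id in column 4);
#' contacts, eQTL, GWAS (GWAS-SSF naming accepted), catalog and interaction
#' edges as TSV with a header; the reference panel as either a GT-only VCF
#' or a dosage TSV (both readers provided).
#'
#' @param path file path.
#' @param df,fragments,panel object to write.
#' @return readers return data frames (or a `genotype_panel`); writers
#'   return the path invisibly.
#' @name grnmr_io
NULL

#' @rdname grnmr_io
#' @export
write_fragments_bed <- function(fragments, path) {
  utils::write.table(fragments[c("chrom", "start", "end", "fragment_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname grnmr_io
#' @export
read_fragments_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "fragment_id")
  df
}

#' @rdname grnmr_io
#' @export
write_contacts <- function(df, path) write_tsv(df, path)

#' @rdname grnmr_io
#' @export
read_contacts <- function(path) read_tsv(path)

#' @rdname grnmr_io
#' @export
write_eqtl <- function(df, path) write_tsv(df, path)

#' @rdname grnmr_io
#' @export
read_eqtl <- function(path) read_tsv(path)

#' @rdname grnmr_io
#' @export
write_gwas <- function(df, path) write_tsv(df, path)

#' @rdname grnmr_io
#' @export
read_gwas <- function(path) normalise_gwas_columns(read_tsv(path))

#' @rdname grnmr_io
#' @export
write_catalog <- function(df, path) write_tsv(df, path)

#' @rdname grnmr_io
#' @export
read_catalog <- function(path) read_tsv(path)

#' @rdname grnmr_io
#' @export
write_edges <- function(df, path) write_tsv(df, path)

#' @rdname grnmr_io
#' @export
read_edges <- function(path) read_tsv(path)

#' @rdname grnmr_io
#' @export
write_panel_dosage <- function(panel, path) {
  meta <- panel$snps[c("snp_id", "chrom", "pos", "ref", "alt", "block")]
  dos <- t(panel$dosage)
  colnames(dos) <- sprintf("ind_%04d", seq_len(nrow(panel$dosage)))
  write_tsv(cbind(meta, as.data.frame(dos)), path)
}

#' @rdname grnmr_io
#' @export
read_panel_dosage <- function(path) {
  df <- read_tsv(path)
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt", "block")
  assert_cols(df, meta_cols, "dosage panel")
  dos <- t(as.matrix(df[setdiff(names(df), meta_cols)]))
  colnames(dos) <- df$snp_id
  rownames(dos) <- NULL
  snps <- df[meta_cols]
  snps$eaf <- colMeans(dos) / 2
  snps <- snps[c("snp_id", "chrom", "pos", "ref", "alt", "eaf", "block")]
  structure(list(snps = snps, dosage = dos,
                 maf_min = min(pmin(snps$eaf, 1 - snps$eaf))),
            class = "genotype_panel")
}

#' @rdname grnmr_io
#' @export
write_panel_vcf <- function(panel, path) {
  n_ind <- nrow(panel$dosage)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=grnmr synthetic reference panel",
               "##INFO=<ID=LDB,Number=1,Type=Integer,Description=\"LD block index\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT",
                     sprintf("ind_%04d", seq_len(n_ind))),
                   collapse = "\t"), con)
  # unphased GT from dosage: 0 -> 0/0, 1 -> 0/1, 2 -> 1/1
  gt <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(panel$snps))) {
    s <- panel$snps[i, ]
    writeLines(paste(c(s$chrom, s$pos + 1L, s$snp_id, s$ref, s$alt, ".",
                       "PASS", sprintf("LDB=%d", s$block), "GT",
                       gt[panel$dosage[, i] + 1L]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname grnmr_io
#' @export
read_panel_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(v)
    block <- as.integer(sub(".*LDB=([0-9]+).*", "\\1",
                            vcfR::getINFO(v)))
    dos <- t(matrix(vapply(strsplit(gt, "[/|]"),
                           function(x) sum(as.integer(x)), integer(1)),
                    nrow = nrow(gt)))
    snps <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                       pos = as.integer(fix$POS) - 1L,
                       ref = fix$REF, alt = fix$ALT, block = block,
                       stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "##")]
    parts <- strsplit(body, "\t", fixed = TRUE)
    header <- parts[[1]]
    parts <- parts[-1]
    n_ind <- length(header) - 9L
    snps <- data.frame(
      snp_id = vapply(parts, `[`, character(1), 3),
      chrom = vapply(parts, `[`, character(1), 1),
      pos = as.integer(vapply(parts, `[`, character(1), 2)) - 1L,
      ref = vapply(parts, `[`, character(1), 4),
      alt = vapply(parts, `[`, character(1), 5),
      block = as.integer(sub(".*LDB=([0-9]+).*", "\\1",
                             vapply(parts, `[`, character(1), 8))),
      stringsAsFactors = FALSE)
    dos <- t(vapply(parts, function(p) {
      g <- p[10:(9 + n_ind)]
      vapply(strsplit(g, "[/|]"), function(x) sum(as.integer(x)),
             integer(1))
    }, integer(n_ind)))
    dos <- t(dos)
  }
  colnames(dos) <- snps$snp_id
  rownames(dos) <- NULL
  snps$eaf <- colMeans(dos) / 2
  snps <- snps[c("snp_id", "chrom", "pos", "ref", "alt", "eaf", "block")]
  structure(list(snps = snps, dosage = dos,
                 maf_min = min(pmin(snps$eaf, 1 - snps$eaf))),
            class = "genotype_panel")
}

#' Write a complete fixture bundle
#'
#' Simulates a full study under `cfg` and writes every pipeline input in its
#' exchange format, plus ground-truth manifests and the configuration, into
#' `outdir`.  The bundle round-trips through [read_fixture_bundle()].
#'
#' @param outdir output directory (created if needed).
#' @param cfg a [sim_config()] object.
#' @return invisibly, the `synthetic_study` that was written.
#' @export
write_fixture_bundle <- function(outdir, cfg) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(cfg)
  p <- function(name) file.path(outdir, name)
  write_fragments_bed(study$world$fragments, p("fragments.bed"))
  write_contacts(study$world$contacts, p("contacts.tsv"))

  panel <- study$panel
  idx <- match(study$world$eqtl$snp_id, panel$snps$snp_id)
  eqtl_out <- cbind(study$world$eqtl[1:2],
                    chrom = panel$snps$chrom[idx],
                    pos = panel$snps$pos[idx],
                    study$world$eqtl[3:4],
                    eaf = panel$snps$eaf[idx],
                    study$world$eqtl[5:8])
  write_eqtl(eqtl_out, p("eqtl_blood.tsv"))
  write_eqtl(study$celltype_eqtl, p("eqtl_celltype.tsv"))
  gwas_cols <- setdiff(names(study$gwas), "pleiotropic")
  write_gwas(study$gwas[gwas_cols], p("gwas.tsv"))
  write_panel_vcf(panel, p("panel.vcf"))
  write_panel_dosage(panel, p("panel_dosage.tsv"))
  write_catalog(study$catalog, p("catalog.tsv"))
  write_edges(study$edges, p("ppi_edges.tsv"))
  write_tsv(study$world$genes, p("genes.tsv"))
  write_tsv(study$truth$genes, p("truth_genes.tsv"))
  write_tsv(study$truth$pairs, p("truth_pairs.tsv"))
  write_tsv(study$truth$traits, p("truth_traits.tsv"))
  write_tsv(study$truth$ppi_levels, p("truth_ppi_levels.tsv"))
  write_tsv(study$gwas[c("rsid", "pleiotropic")], p("truth_pleiotropy.tsv"))
  jsonlite::write_json(unclass(study$cfg), p("config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(study)
}

#' Read a fixture bundle back
#'
#' @param outdir directory written by [write_fixture_bundle()].
#' @param panel_format `"dosage"` (default) or `"vcf"`.
#' @return list with the configuration and every table, panel reconstructed
#'   as a `genotype_panel`.
#' @export
read_fixture_bundle <- function(outdir, panel_format = c("dosage", "vcf")) {
  panel_format <- match.arg(panel_format)
  p <- function(name) file.path(outdir, name)
  cfg_list <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
  cfg <- do.call(sim_config, cfg_list)
  list(cfg = cfg,
       fragments = read_fragments_bed(p("fragments.bed")),
       contacts = read_contacts(p("contacts.tsv")),
       eqtl = read_eqtl(p("eqtl_blood.tsv")),
       celltype_eqtl = read_eqtl(p("eqtl_celltype.tsv")),
       gwas = read_gwas(p("gwas.tsv")),
       panel = if (panel_format == "dosage")
         read_panel_dosage(p("panel_dosage.tsv"))
       else read_panel_vcf(p("panel.vcf")),
       catalog = read_catalog(p("catalog.tsv")),
       edges = read_edges(p("ppi_edges.tsv")),
       genes = read_tsv(p("genes.tsv")),
       truth = list(genes = read_tsv(p("truth_genes.tsv")),
                    pairs = read_tsv(p("truth_pairs.tsv")),
                    traits = read_tsv(p("truth_traits.tsv")),
                    ppi_levels = read_tsv(p("truth_ppi_levels.tsv")),
                    pleiotropy = read_tsv(p("truth_pleiotropy.tsv"))))
}
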