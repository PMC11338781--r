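#' Simulate the regulatory world: fragments, Hi-C contacts and eQTLs
#'
#' Lays out a simulated chromosome (restriction fragments of 50 bp tiling a
#' SNP zone followed by fixed-length 150 bp gene bodies), assigns every gene a
#' drawn number of true instrument SNPs from distinct LD blocks, and emits the
#' three tables the network builder consumes: a fragment map, a
#' fragment-contact table over four blood cell lines, and an eQTL summary
#' table.  True SNP-gene pairs get a fragment contact in at least one cell
#' line and a strongly significant eQTL row (p below 1e-6 by construction).
#' A controlled number of decoy pairs each violate exactly one retention
#' requirement: `no_contact` decoys have a significant eQTL but no supporting
#' contact; `weak_eqtl` decoys have a contact but a non-significant eQTL.
#' Ground-truth labels for every pair are returned alongside.
#'
#' @param cfg a [sim_config()] object.
#' @param panel a `genotype_panel` from [simulate_panel()].
#' @return a list of class `regulatory_world` with elements `snps`, `genes`,
#'   `fragments` (BED-like data frame), `assignments` (from
#'   [assign_fragments()]), `contacts` (`frag_a`, `frag_b`, `cell_line`),
#'   `eqtl` (summary rows for true pairs and decoys), `truth_pairs`
#'   (`snp_id`, `gene_id`, `label`) and `cell_lines`.
#' @export
simulate_regulatory_world <- function(cfg, panel) {
  validate_sim_config(cfg)
  if (!inherits(panel, "genotype_panel"))
    stop("'panel' must come from simulate_panel()", call. = FALSE)
  n_blocks <- length(unique(panel$snps$block))
  if (cfg$n_instruments_per_gene[2] > n_blocks)
    stop(sprintf(paste0("cannot place %d instruments per gene in distinct LD",
                        " blocks: only %d blocks available"),
                 cfg$n_instruments_per_gene[2], n_blocks), call. = FALSE)

  with_seed(seed_for(cfg, 2L), {
    # restriction fragments of 10 kb tile the SNP zone (one SNP per
    # fragment given the panel's 10 kb SNP spacing); the gene zone that
    # follows is tiled by 200 bp fragments holding one 150 bp gene body
    # each, so no two genes share a fragment
    snp_frag_len <- 10000L
    gene_frag_len <- 200L
    gene_len <- 150L
    snp_zone_end <- as.integer(
      ceiling((max(panel$snps$pos) + 1L) / snp_frag_len) * snp_frag_len)
    genes <- data.frame(
      gene_id = sprintf("G%03d", seq_len(cfg$n_genes)),
      chrom = "chr1",
      start = snp_zone_end + (seq_len(cfg$n_genes) - 1L) * gene_frag_len,
      end = snp_zone_end + (seq_len(cfg$n_genes) - 1L) * gene_frag_len +
        gene_len,
      stringsAsFactors = FALSE)
    starts <- c(seq(0L, snp_zone_end - snp_frag_len, by = snp_frag_len),
                seq(snp_zone_end,
                    snp_zone_end + (cfg$n_genes - 1L) * gene_frag_len,
                    by = gene_frag_len))
    ends <- c(starts[-1], snp_zone_end + cfg$n_genes * gene_frag_len)
    fragments <- data.frame(
      chrom = "chr1", start = as.integer(starts), end = as.integer(ends),
      fragment_id = sprintf("F%05d", seq_along(starts)),
      stringsAsFactors = FALSE)
    assignments <- assign_fragments(panel$snps, genes, fragments)

    # true instrument pairs: per gene, instruments drawn from distinct LD
    # blocks so downstream clumping at r2 <= 0.001 keeps them all
    iv_range <- cfg$n_instruments_per_gene
    n_iv <- if (iv_range[1] == iv_range[2]) rep(iv_range[1], cfg$n_genes)
            else sample(seq(iv_range[1], iv_range[2]), cfg$n_genes,
                        replace = TRUE)
    # instruments are drawn without replacement across the whole world, so
    # each true eQTL SNP instruments exactly one gene and truth labels stay
    # interpretable (real data can share instruments across genes; that
    # behaviour is exercised separately in tests).  Causal genes are placed
    # first and retire their LD blocks entirely: at genome scale a random
    # gene set's eQTLs are essentially never in LD with the causal loci,
    # and block-exclusive placement preserves that property in the
    # compressed simulated genome.
    pools <- split(panel$snps$snp_id, panel$snps$block)
    if (sum(n_iv) > cfg$n_snps)
      stop(sprintf("requested %d instruments but only %d SNPs available",
                   sum(n_iv), cfg$n_snps), call. = FALSE)
    causal <- causal_gene_ids(cfg)
    ord <- order(!(genes$gene_id %in% causal))
    true_list <- vector("list", cfg$n_genes)
    for (g in ord) {
      open <- which(lengths(pools) > 0)
      if (length(open) < n_iv[g])
        stop(sprintf(paste0("cannot place %d instruments for gene %s in ",
                            "distinct non-exhausted LD blocks"),
                     n_iv[g], genes$gene_id[g]), call. = FALSE)
      blocks <- if (length(open) == 1) open else sample(open, n_iv[g])
      is_causal <- genes$gene_id[g] %in% causal
      snp <- vapply(blocks, function(bl) {
        pool <- pools[[bl]]
        pick <- pool[sample.int(length(pool), 1L)]
        pools[[bl]] <<- if (is_causal) character(0) else setdiff(pool, pick)
        pick
      }, character(1))
      true_list[[g]] <- data.frame(snp_id = snp, gene_id = genes$gene_id[g],
                                   stringsAsFactors = FALSE)
    }
    true_pairs <- do.call(rbind, true_list)
    true_pairs$label <- "true_pair"

    # decoys split between the two single-violation classes
    n_decoy <- round(cfg$decoy_frac * nrow(true_pairs))
    decoys <- NULL
    if (n_decoy > 0) {
      key <- paste(true_pairs$snp_id, true_pairs$gene_id)
      rows <- list()
      while (length(rows) < n_decoy) {
        s <- panel$snps$snp_id[sample.int(cfg$n_snps, 1L)]
        g <- genes$gene_id[sample.int(cfg$n_genes, 1L)]
        k <- paste(s, g)
        if (!(k %in% key)) {
          key <- c(key, k)
          rows[[length(rows) + 1L]] <- data.frame(
            snp_id = s, gene_id = g, stringsAsFactors = FALSE)
        }
      }
      decoys <- do.call(rbind, rows)
      decoys$label <- rep(c("no_contact", "weak_eqtl"),
                          length.out = n_decoy)
    }
    truth <- rbind(true_pairs, decoys)

    # eQTL summary rows; true and no_contact pairs are strongly significant
    strong <- truth$label %in% c("true_pair", "no_contact")
    n_pair <- nrow(truth)
    beta <- numeric(n_pair); se <- numeric(n_pair); pval <- numeric(n_pair)
    z_strong <- stats::runif(sum(strong), 5.5, 15)
    b_strong <- stats::runif(sum(strong), 0.3, 0.6) *
      sample(c(-1, 1), sum(strong), replace = TRUE)
    beta[strong] <- b_strong
    se[strong] <- abs(b_strong) / z_strong
    pval[strong] <- 2 * stats::pnorm(-z_strong)
    if (any(!strong)) {
      p_weak <- stats::runif(sum(!strong), 0.2, 0.95)
      se_weak <- stats::runif(sum(!strong), 0.03, 0.06)
      z_weak <- stats::qnorm(1 - p_weak / 2) *
        sample(c(-1, 1), sum(!strong), replace = TRUE)
      beta[!strong] <- z_weak * se_weak
      se[!strong] <- se_weak
      pval[!strong] <- p_weak
    }
    snp_idx <- match(truth$snp_id, panel$snps$snp_id)
    eqtl <- data.frame(
      snp_id = truth$snp_id, gene_id = truth$gene_id,
      effect_allele = panel$snps$alt[snp_idx],
      other_allele = panel$snps$ref[snp_idx],
      beta = beta, se = se, pval = pval,
      context = "whole_blood", stringsAsFactors = FALSE)

    cell_lines <- c("T_cell", "B_cell", "monocyte", "neutrophil")
    with_contact <- truth$label %in% c("true_pair", "weak_eqtl")
    snp_frag <- assignments$snp_map$fragment_id[
      match(truth$snp_id, assignments$snp_map$snp_id)]
    gene_frags <- split(assignments$gene_map$fragment_id,
                        assignments$gene_map$gene_id)
    contact_rows <- lapply(which(with_contact), function(i) {
      gf <- gene_frags[[truth$gene_id[i]]]
      target <- gf[sample.int(length(gf), 1L)]
      cls <- sample(cell_lines, sample.int(4L, 1L))
      data.frame(frag_a = snp_frag[i], frag_b = target, cell_line = cls,
                 stringsAsFactors = FALSE)
    })
    # background SNP-zone contacts; these never touch gene fragments so no
    # decoy can gain accidental support
    snp_frags_all <- unique(assignments$snp_map$fragment_id)
    bg <- data.frame(
      frag_a = sample(snp_frags_all, 20L, replace = TRUE),
      frag_b = sample(snp_frags_all, 20L, replace = TRUE),
      cell_line = sample(cell_lines, 20L, replace = TRUE),
      stringsAsFactors = FALSE)
    contacts <- rbind(do.call(rbind, contact_rows), bg)
    contacts <- contacts[contacts$frag_a != contacts$frag_b, ]
    key <- paste(pmin(contacts$frag_a, contacts$frag_b),
                 pmax(contacts$frag_a, contacts$frag_b), contacts$cell_line)
    contacts <- contacts[!duplicated(key), ]
    rownames(contacts) <- NULL
    rownames(truth) <- NULL
    rownames(eqtl) <- NULL

    structure(list(snps = panel$snps, genes = genes, fragments = fragments,
                   assignments = assignments, contacts = contacts,
                   eqtl = eqtl, truth_pairs = truth,
                   cell_lines = cell_lines),
              class = "regulatory_world")
  })
}

#' Simulate per-cell-type eQTL tables
#'
#' Re-expresses the true instrument SNP-gene pairs across `cfg$n_celltypes`
#' immune cell types, emulating a per-cell-type immune eQTL resource.
#' Each pair is observed in a random subset of cell types; the cell-type beta
#' is the blood beta modulated by a cell-type factor, so some pairs flip sign
#' or lose significance in some contexts.  A few rows pairing an instrument
#' SNP with a different gene are added so exact-pair join semantics are
#' exercised downstream.
#'
#' @param cfg a [sim_config()] object.
#' @param world a `regulatory_world`.
#' @return an eQTL table with a `context` column holding cell-type labels.
#' @export
simulate_celltype_eqtls <- function(cfg, world) {
  validate_sim_config(cfg)
  with_seed(seed_for(cfg, 3L), {
    celltypes <- sprintf("celltype_%02d", seq_len(cfg$n_celltypes))
    base <- world$eqtl[world$truth_pairs$label == "true_pair", ]
    rows <- lapply(seq_len(nrow(base)), function(i) {
      present <- stats::runif(cfg$n_celltypes) < 0.75
      if (!any(present)) present[sample.int(cfg$n_celltypes, 1L)] <- TRUE
      mod <- stats::rnorm(sum(present), mean = 1, sd = 0.4)
      flip <- stats::runif(sum(present)) < 0.1
      mod[flip] <- -mod[flip]
      b <- base$beta[i] * mod
      s <- rep(base$se[i] * 1.5, sum(present))
      data.frame(snp_id = base$snp_id[i], gene_id = base$gene_id[i],
                 effect_allele = base$effect_allele[i],
                 other_allele = base$other_allele[i],
                 beta = b, se = s, pval = 2 * stats::pnorm(-abs(b / s)),
                 context = celltypes[present], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    # off-target rows: same SNP, different gene
    n_extra <- min(10L, nrow(base))
    extra_idx <- sample.int(nrow(base), n_extra)
    other_gene <- vapply(base$gene_id[extra_idx], function(g)
      sample(setdiff(world$genes$gene_id, g), 1L), character(1))
    extra <- base[extra_idx, ]
    extra$gene_id <- unname(other_gene)
    extra$beta <- stats::rnorm(n_extra, 0, 0.1)
    extra$se <- 0.08
    extra$pval <- 2 * stats::pnorm(-abs(extra$beta / extra$se))
    extra$context <- sample(celltypes, n_extra, replace = TRUE)
    out <- rbind(out, extra)
    out <- out[!duplicated(out[c("snp_id", "gene_id", "context")]), ]
    rownames(out) <- NULL
    out
  })
}
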