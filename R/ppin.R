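#' Expand seed genes through a score-filtered interaction network
#'
#' Breadth-first shells on the subgraph of edges with score strictly above
#' `score_min`: level 0 is the seed set, and level k holds the neighbours of
#' level k-1 not already assigned to an earlier level.  Level sets are
#' therefore pairwise disjoint, and every level-k gene has at least one
#' supra-threshold edge to a level-(k-1) gene.  Sets are returned
#' lexicographically sorted, so output is deterministic.
#'
#' @param seeds non-empty character vector of seed genes (level 0).
#' @param edges data frame with `gene_a`, `gene_b`, `score` in `[0, 1]`.
#' @param score_min strict score threshold (default 0.9, i.e. edges must
#'   exceed 0.9 to count).
#' @param n_levels number of expansion shells beyond the seeds (default 2).
#' @return object of class `ppin_levels`: list of character vectors
#'   `level0`, ..., `level<n_levels>`.
#' @examples
#' edges <- data.frame(gene_a = c("a", "b", "a"), gene_b = c("b", "c", "d"),
#'                     score = c(0.95, 0.92, 0.5))
#' expand_levels("a", edges)
#' @export
expand_levels <- function(seeds, edges, score_min = 0.9, n_levels = 2) {
  if (length(seeds) == 0) stop("seed gene set is empty", call. = FALSE)
  assert_cols(edges, c("gene_a", "gene_b", "score"), "edge table")
  keep <- edges$score > score_min
  adj <- split(c(edges$gene_b[keep], edges$gene_a[keep]),
               c(edges$gene_a[keep], edges$gene_b[keep]))
  levels <- vector("list", n_levels + 1L)
  levels[[1]] <- sort(unique(seeds))
  assigned <- levels[[1]]
  for (k in seq_len(n_levels)) {
    nb <- unique(unlist(adj[levels[[k]]], use.names = FALSE))
    # as.character() guards the empty case (sort(NULL) would drop the slot)
    levels[[k + 1L]] <- as.character(sort(setdiff(nb, assigned)))
    assigned <- c(assigned, levels[[k + 1L]])
  }
  names(levels) <- paste0("level", 0:n_levels)
  structure(levels, class = "ppin_levels")
}

#' @export
print.ppin_levels <- function(x, ...) {
  cat("Interaction-network expansion shells:\n")
  for (nm in names(x))
    cat(sprintf("  %s: %d gene(s)\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Spatial eQTLs regulating a gene set
#'
#' Union of the network's SNPs targeting any gene in the set; genes absent
#' from the network contribute nothing.
#'
#' @param genes character vector of gene ids.
#' @param grn a `spatial_grn`.
#' @return data frame `snp_id`, `gene_id` (one row per network edge into the
#'   set); `unique(x$snp_id)` is the level's SNP set.
#' @export
level_eqtls <- function(genes, grn) {
  e <- grn$edges[grn$edges$gene_id %in% genes, c("snp_id", "gene_id")]
  e <- e[order(e$snp_id, e$gene_id), ]
  rownames(e) <- NULL
  e
}

#' Expand a SNP set with its LD partners
#'
#' Adds every panel SNP whose r-squared with any input SNP meets `r2_min`
#' (inclusive).  Input SNPs are always retained; inputs absent from the
#' panel pass through unexpanded with a logged count.
#'
#' @param snps character vector of SNP ids.
#' @param panel a `genotype_panel`.
#' @param r2_min inclusive r-squared threshold (default 0.8).
#' @param partner_map optional precomputed partner map from
#'   [ld_partner_map()]; supplying one avoids recomputing LD in repeated
#'   calls (e.g. across bootstrap replicates).
#' @return data frame `snp_id`, `source_snp`, `r2` (input SNPs appear as
#'   their own source with r2 1); `unique(x$snp_id)` is the expanded set.
#' @export
ld_expand <- function(snps, panel, r2_min = 0.8, partner_map = NULL) {
  snps <- unique(snps)
  if (length(snps) == 0)
    return(data.frame(snp_id = character(0), source_snp = character(0),
                      r2 = numeric(0)))
  if (is.null(partner_map))
    partner_map <- ld_partner_map(panel, snps, r2_min)
  known <- snps[snps %in% names(partner_map)]
  unknown <- setdiff(snps, known)
  if (length(unknown))
    message(length(unknown),
            " SNP(s) not in the reference panel pass through unexpanded")
  p_list <- partner_map[known]
  n_part <- lengths(p_list)
  out <- data.frame(
    snp_id = c(known, unlist(lapply(p_list, names), use.names = FALSE),
               unknown),
    source_snp = c(known, rep(known, n_part), unknown),
    r2 = c(rep(1, length(known)), unlist(p_list, use.names = FALSE),
           rep(NA_real_, length(unknown))),
    stringsAsFactors = FALSE)
  out <- out[order(out$snp_id, out$source_snp), ]
  rownames(out) <- NULL
  out
}

#' Precompute LD partners for a SNP set
#'
#' @param panel a `genotype_panel`.
#' @param snps SNPs to index (default: every panel SNP).
#' @param r2_min inclusive r-squared threshold.
#' @return named list: for each indexed SNP, a named numeric vector of
#'   partner r-squared values (self excluded).
#' @export
ld_partner_map <- function(panel, snps = panel$snps$snp_id, r2_min = 0.8) {
  snps <- intersect(unique(snps), colnames(panel$dosage))
  if (length(snps) == 0) return(stats::setNames(list(), character(0)))
  d <- panel$dosage[, snps, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(d, panel$dosage))^2
  out <- lapply(seq_along(snps), function(i) {
    v <- r2[i, ]
    v <- v[!is.na(v) & v >= r2_min]
    v[names(v) != snps[i]]
  })
  stats::setNames(out, snps)
}

#' Hypergeometric trait-enrichment test
#'
#' For each trait, tests whether the expanded SNP set over-represents the
#' trait's catalog SNPs.  The sampling frame is the catalog itself:
#' `N` = distinct SNPs in the catalog, `K` = distinct catalog SNPs for the
#' trait, `n` = expanded-set members present in the catalog, `k` = expanded
#' members associated with the trait; the p-value is the upper tail
#' `P(X >= k)` under Hypergeometric(N, K, n).  LD partners never
#' multiply-count: overlap is counted over distinct catalog SNPs.
#'
#' @param snps expanded SNP set (character vector).
#' @param catalog data frame with `snp_id`, `trait`.
#' @return data frame `trait`, `N`, `K`, `n`, `k`, `pval`.
#' @export
hypergeom_enrich <- function(snps, catalog) {
  assert_cols(catalog, c("snp_id", "trait"), "trait catalog")
  if (nrow(catalog) == 0) stop("the trait catalog is empty", call. = FALSE)
  catalog <- catalog[!duplicated(catalog[c("snp_id", "trait")]), ]
  all_snps <- unique(catalog$snp_id)
  N <- length(all_snps)
  snps <- unique(snps)
  member <- all_snps %in% snps
  n <- sum(member)
  traits <- sort(unique(catalog$trait))
  K <- as.integer(table(factor(catalog$trait, levels = traits)))
  in_set <- catalog$snp_id %in% snps
  k <- as.integer(table(factor(catalog$trait[in_set], levels = traits)))
  if (n == 0) {
    warning("no expanded SNP is present in the catalog; all traits p = 1")
    p <- rep(1, length(traits))
  } else {
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  }
  data.frame(trait = traits, N = N, K = K, n = n, k = k, pval = p,
             stringsAsFactors = FALSE)
}

# one observed pass of the enrichment chain: expansion shells -> per-level
# eQTL sets -> LD expansion -> per-level hypergeometric test with BH across
# traits within each level
enrichment_pipeline <- function(seeds, edges, grn, catalog, panel,
                                score_min = 0.9, n_levels = 2, r2_min = 0.8,
                                partner_map = NULL, keep_provenance = FALSE) {
  levels <- expand_levels(seeds, edges, score_min = score_min,
                          n_levels = n_levels)
  per_level <- vector("list", length(levels))
  prov <- if (keep_provenance) vector("list", length(levels)) else NULL
  for (li in seq_along(levels)) {
    pairs <- level_eqtls(levels[[li]], grn)
    expansion <- ld_expand(unique(pairs$snp_id), panel, r2_min = r2_min,
                           partner_map = partner_map)
    enr <- hypergeom_enrich(unique(expansion$snp_id), catalog)
    enr$level <- li - 1L
    enr$adj_pval <- if (nrow(enr)) bh_adjust(enr$pval) else numeric(0)
    per_level[[li]] <- enr
    if (keep_provenance)
      prov[[li]] <- list(genes = levels[[li]], pairs = pairs,
                         expansion = expansion)
  }
  out <- do.call(rbind, per_level)
  rownames(out) <- NULL
  if (keep_provenance) {
    names(prov) <- names(levels)
    attr(out, "provenance") <- prov
    attr(out, "levels") <- levels
  }
  out
}

#' Bootstrap null for trait enrichment by gene-set randomization
#'
#' For each replicate, draws `seed_set_size` genes uniformly without
#' replacement from `gene_universe` and reruns the whole enrichment chain
#' (network expansion, per-level eQTL collection, LD expansion,
#' hypergeometric test, BH within level).  A trait's bootstrap p-value at a
#' level is `(count + 1) / (n_boot + 1)`, where `count` is the number of
#' replicates in which the trait's adjusted p-value at that level was at or
#' below `alpha`.  One replicate stream is drawn per run and reused across
#' levels.
#'
#' @param gene_universe genes eligible for random seed sets (typically the
#'   genes present in the network).
#' @param seed_set_size size of each random seed set (the observed seed
#'   count).
#' @param edges,grn,catalog,panel pipeline inputs as in
#'   [trait_enrichment_scan()].
#' @param n_boot number of replicates (default 240).
#' @param seed RNG seed for the replicate stream.
#' @param score_min,n_levels,r2_min,alpha pipeline parameters.
#' @param partner_map optional precomputed [ld_partner_map()] covering the
#'   panel (computed once here otherwise).
#' @return data frame `trait`, `level`, `boot_count`, `boot_pval`.
#' @export
bootstrap_null <- function(gene_universe, seed_set_size, edges, grn, catalog,
                           panel, n_boot = 240, seed = 1, score_min = 0.9,
                           n_levels = 2, r2_min = 0.8, alpha = 0.05,
                           partner_map = NULL) {
  gene_universe <- unique(gene_universe)
  if (length(gene_universe) < seed_set_size)
    stop(sprintf("gene universe (%d) is smaller than the seed set size (%d)",
                 length(gene_universe), seed_set_size), call. = FALSE)
  if (is.null(partner_map))
    partner_map <- ld_partner_map(panel, r2_min = r2_min)
  catalog <- catalog[!duplicated(catalog[c("snp_id", "trait")]), ]
  traits <- sort(unique(catalog$trait))
  counts <- matrix(0L, nrow = length(traits), ncol = n_levels + 1L,
                   dimnames = list(traits, paste0("level", 0:n_levels)))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      rand_seeds <- sample(gene_universe, seed_set_size)
      # replicates with empty outer levels legitimately have zero overlap;
      # their per-call warnings would only repeat that n_boot times
      enr <- suppressWarnings(
        enrichment_pipeline(rand_seeds, edges, grn, catalog, panel,
                            score_min = score_min, n_levels = n_levels,
                            r2_min = r2_min, partner_map = partner_map))
      hit <- enr[enr$adj_pval <= alpha, c("trait", "level")]
      if (nrow(hit))
        counts[cbind(match(hit$trait, traits), hit$level + 1L)] <-
          counts[cbind(match(hit$trait, traits), hit$level + 1L)] + 1L
    }
  })
  out <- data.frame(
    trait = rep(traits, n_levels + 1L),
    level = rep(0:n_levels, each = length(traits)),
    boot_count = as.integer(counts),
    stringsAsFactors = FALSE)
  out$boot_pval <- (out$boot_count + 1) / (n_boot + 1)
  out
}

#' Combine observed enrichment with the bootstrap null
#'
#' Joins the observed per-level enrichment table with the bootstrap table,
#' (re)computes BH-adjusted p-values within each level, and applies the dual
#' significance rule: a trait is significant at a level iff its adjusted
#' hypergeometric p and its bootstrap p are both at or below `alpha`.
#'
#' @param enrichments observed table from [hypergeom_enrich()] runs (with
#'   `level` column; `adj_pval` recomputed here).
#' @param boot bootstrap table from [bootstrap_null()].
#' @param alpha dual-rule threshold (default 0.05).
#' @return object of class `trait_enrichment` wrapping the full table
#'   (`trait`, `level`, `N`, `K`, `n`, `k`, `pval`, `adj_pval`,
#'   `boot_count`, `boot_pval`, `significant`), including non-significant
#'   rows.
#' @export
significant_traits <- function(enrichments, boot, alpha = 0.05) {
  assert_cols(enrichments, c("trait", "level", "pval"), "enrichment table")
  assert_cols(boot, c("trait", "level", "boot_pval"), "bootstrap table")
  merged <- merge(enrichments, boot, by = c("trait", "level"))
  if (nrow(merged) != nrow(enrichments))
    stop("trait/level keys of the enrichment and bootstrap tables disagree",
         call. = FALSE)
  merged <- merged[order(merged$level, merged$trait), ]
  merged$adj_pval <- stats::ave(merged$pval, merged$level,
                                FUN = bh_adjust)
  merged$significant <- merged$adj_pval <= alpha & merged$boot_pval <= alpha
  rownames(merged) <- NULL
  structure(list(table = merged, alpha = alpha,
                 universe = "distinct SNPs in the trait catalog"),
            class = "trait_enrichment")
}

#' Full trait-enrichment scan with bootstrap null
#'
#' Runs the observed enrichment chain from the given seed genes, then the
#' gene-set randomization bootstrap, and combines both under the dual
#' significance rule.  Provenance (per-level genes, SNP-gene pairs and LD
#' expansions) is retained for downstream gene-by-trait matrices.
#'
#' @param seeds observed seed genes (level 0).
#' @param edges scored interaction edge table.
#' @param grn a `spatial_grn`.
#' @param catalog trait-association catalog (`snp_id`, `trait`).
#' @param panel a `genotype_panel`.
#' @param score_min,n_levels,r2_min,alpha pipeline parameters (strict
#'   `score > score_min`; inclusive `r2 >= r2_min`).
#' @param n_boot bootstrap replicates (default 240).
#' @param seed bootstrap RNG seed.
#' @param gene_universe universe for random seed sets (default: genes in the
#'   network).
#' @return a `trait_enrichment` object with `provenance` attached.
#' @export
trait_enrichment_scan <- function(seeds, edges, grn, catalog, panel,
                                  score_min = 0.9, n_levels = 2,
                                  r2_min = 0.8, alpha = 0.05, n_boot = 240,
                                  seed = 1,
                                  gene_universe = names(grn$by_gene)) {
  partner_map <- ld_partner_map(panel, r2_min = r2_min)
  observed <- enrichment_pipeline(seeds, edges, grn, catalog, panel,
                                  score_min = score_min,
                                  n_levels = n_levels, r2_min = r2_min,
                                  partner_map = partner_map,
                                  keep_provenance = TRUE)
  boot <- bootstrap_null(gene_universe, length(unique(seeds)), edges, grn,
                         catalog, panel, n_boot = n_boot, seed = seed,
                         score_min = score_min, n_levels = n_levels,
                         r2_min = r2_min, alpha = alpha,
                         partner_map = partner_map)
  out <- significant_traits(as.data.frame(observed), boot, alpha = alpha)
  out$provenance <- attr(observed, "provenance")
  out$levels <- attr(observed, "levels")
  out$params <- list(score_min = score_min, n_levels = n_levels,
                     r2_min = r2_min, n_boot = n_boot, seed = seed)
  out
}

#' @export
print.trait_enrichment <- function(x, ...) {
  t <- x$table
  cat(sprintf("Trait enrichment: %d trait-level tests; universe = %s\n",
              nrow(t), x$universe))
  for (l in sort(unique(t$level))) {
    sig <- t[t$level == l & t$significant, "trait"]
    cat(sprintf("  level %d: %d significant trait(s)%s\n", l, length(sig),
                if (length(sig))
                  paste0(" (", paste(utils::head(sig, 5), collapse = ", "),
                         if (length(sig) > 5) ", ..." else "", ")")
                else ""))
  }
  invisible(x)
}

#' @export
summary.trait_enrichment <- function(object, ...) {
  t <- object$table
  cat(sprintf("Dual rule: BH-adjusted hypergeometric p <= %g and bootstrap p <= %g\n",
              object$alpha, object$alpha))
  print(stats::aggregate(significant ~ level, t, sum))
  invisible(object)
}

#' @export
as.data.frame.trait_enrichment <- function(x, ...) x$table
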