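#' Simulate a trait-association catalog and a scored interaction network
#'
#' Builds the two remaining pipeline inputs with planted structure.
#'
#' Catalog: each trait draws `cfg$n_catalog_snps_per_trait` distinct SNPs from
#' the panel.  Background traits draw uniformly; planted traits draw with
#' sampling weight `cfg$planted_enrichment_factor` on the designated genes'
#' regulatory SNPs (their true eQTLs and LD partners at r-squared >= 0.8), so
#' the trait's catalog over-represents exactly the SNP set the enrichment
#' stage should recover.
#'
#' Interaction network: designated level-1 genes attach to the designated
#' (seed) genes, and level-2 genes to level-1 genes, through edges scored
#' above 0.9; decoy genes attach to seeds only through sub-threshold edges,
#' and background edges among the remaining genes stay below the threshold.
#' Level-1/2 genes are therefore reachable from the seeds only through
#' edges that survive the score filter.
#'
#' @param cfg a [sim_config()] object.
#' @param panel a `genotype_panel`.
#' @param world a `regulatory_world`.
#' @param designated_genes character vector of genes (typically the causal
#'   genes) whose regulatory SNPs carry the planted enrichment and which act
#'   as PPI seeds.
#' @return a list with `catalog` (`snp_id`, `trait`, `study`), `edges`
#'   (`gene_a`, `gene_b`, `score`), `truth_traits` (`trait`, `planted`,
#'   `enrichment_factor`) and `truth_ppi` (`gene_id`, `level` in 0..2, decoy
#'   genes labelled `NA`).
#' @export
simulate_catalog_and_ppi <- function(cfg, panel, world, designated_genes) {
  validate_sim_config(cfg)
  if (cfg$planted_enrichment_factor < 1)
    stop_config("planted_enrichment_factor", "must be >= 1")
  with_seed(seed_for(cfg, 6L), {
    # planted SNP pool: true eQTLs of the designated genes plus LD partners
    truth <- world$truth_pairs
    seed_eqtls <- unique(truth$snp_id[truth$label == "true_pair" &
                                        truth$gene_id %in% designated_genes])
    enriched <- if (length(seed_eqtls))
      unique(ld_expand(seed_eqtls, panel, r2_min = 0.8)$snp_id)
    else character(0)

    traits <- c(sprintf("trait_planted_%02d", seq_len(cfg$n_planted_traits)),
                sprintf("trait_bg_%02d",
                        seq_len(cfg$n_traits - cfg$n_planted_traits)))
    planted <- seq_along(traits) <= cfg$n_planted_traits
    all_snps <- panel$snps$snp_id
    n_draw <- min(cfg$n_catalog_snps_per_trait, length(all_snps))
    catalog <- do.call(rbind, lapply(seq_along(traits), function(i) {
      w <- rep(1, length(all_snps))
      if (planted[i])
        w[all_snps %in% enriched] <- cfg$planted_enrichment_factor
      data.frame(snp_id = sample(all_snps, n_draw, prob = w),
                 trait = traits[i],
                 study = sprintf("SIMSTUDY_%03d", i),
                 stringsAsFactors = FALSE)
    }))
    catalog <- catalog[!duplicated(catalog[c("snp_id", "trait")]), ]
    rownames(catalog) <- NULL

    # scored interaction graph with a strict >0.9 designated chain
    pool <- setdiff(world$genes$gene_id, designated_genes)
    n_l1 <- min(8L, max(0L, length(pool) - 15L))
    l1 <- if (n_l1 > 0) sample(pool, n_l1) else character(0)
    pool <- setdiff(pool, l1)
    n_l2 <- min(10L, max(0L, length(pool) - 5L))
    l2 <- if (n_l2 > 0) sample(pool, n_l2) else character(0)
    pool <- setdiff(pool, l2)
    n_decoy <- min(5L, length(pool))
    decoy <- if (n_decoy > 0) sample(pool, n_decoy) else character(0)
    rest <- setdiff(pool, decoy)

    edge <- function(a, b, lo, hi)
      data.frame(gene_a = a, gene_b = b,
                 score = stats::runif(length(a), lo, hi),
                 stringsAsFactors = FALSE)
    edges <- list()
    if (length(l1) && length(designated_genes))
      edges$l1 <- edge(sample(designated_genes, length(l1), replace = TRUE),
                       l1, 0.905, 0.995)
    if (length(l2) && length(l1))
      edges$l2 <- edge(sample(l1, length(l2), replace = TRUE),
                       l2, 0.905, 0.995)
    if (length(decoy) && length(designated_genes))
      edges$decoy <- edge(sample(designated_genes, length(decoy),
                                 replace = TRUE),
                          decoy, 0.3, 0.9)
    if (length(rest) >= 2) {
      n_bg <- min(30L, choose(length(rest), 2))
      a <- sample(rest, n_bg, replace = TRUE)
      b <- sample(rest, n_bg, replace = TRUE)
      keep <- a != b
      edges$bg <- edge(a[keep], b[keep], 0.15, 0.85)
    }
    edges <- do.call(rbind, edges)
    ka <- pmin(edges$gene_a, edges$gene_b)
    kb <- pmax(edges$gene_a, edges$gene_b)
    edges <- data.frame(gene_a = ka, gene_b = kb, score = edges$score,
                        stringsAsFactors = FALSE)
    edges <- edges[!duplicated(edges[c("gene_a", "gene_b")]), ]
    rownames(edges) <- NULL

    truth_ppi <- data.frame(
      gene_id = c(designated_genes, l1, l2, decoy),
      level = c(rep(0L, length(designated_genes)), rep(1L, length(l1)),
                rep(2L, length(l2)), rep(NA_integer_, length(decoy))),
      stringsAsFactors = FALSE)
    list(catalog = catalog, edges = edges,
         truth_traits = data.frame(
           trait = traits, planted = planted,
           enrichment_factor = ifelse(planted,
                                      cfg$planted_enrichment_factor, 1),
           stringsAsFactors = FALSE),
         truth_ppi = truth_ppi)
  })
}

#' Simulate a complete synthetic study
#'
#' Orchestrates every generator under one configuration: reference panel,
#' regulatory world, causal-gene truth, outcome GWAS, per-cell-type eQTL
#' tables, trait catalog and interaction network.  Each component generator
#' is independently seeded from `cfg$seed`, so the bundle is a pure function
#' of the configuration.
#'
#' @param cfg a [sim_config()] object.
#' @return a list of class `synthetic_study` with elements `cfg`, `panel`,
#'   `world`, `theta`, `gwas`, `celltype_eqtl`, `catalog`, `edges`, and
#'   `truth` (gene, pair, trait and PPI-level manifests).
#' @examples
#' study <- simulate_study(sim_config(n_snps = 100, n_genes = 20,
#'                                    n_ref_individuals = 120, seed = 7))
#' names(study)
#' @export
simulate_study <- function(cfg) {
  validate_sim_config(cfg)
  panel <- simulate_panel(cfg)
  world <- simulate_regulatory_world(cfg, panel)
  theta <- simulate_causal_truth(cfg, world$genes)
  gwas <- simulate_outcome_gwas(cfg, panel, world$eqtl, theta)
  ct <- simulate_celltype_eqtls(cfg, world)
  causal <- names(theta)[theta != 0]
  cp <- simulate_catalog_and_ppi(cfg, panel, world, causal)
  truth <- list(
    genes = data.frame(gene_id = names(theta), theta = as.numeric(theta),
                       causal = theta != 0, stringsAsFactors = FALSE),
    pairs = world$truth_pairs,
    traits = cp$truth_traits,
    ppi_levels = cp$truth_ppi)
  structure(list(cfg = cfg, panel = panel, world = world, theta = theta,
                 gwas = gwas, celltype_eqtl = ct, catalog = cp$catalog,
                 edges = cp$edges, truth = truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study: %d SNPs, %d genes (%d causal), ",
                     "%d true pairs + %d decoys, %d traits (%d planted)\n"),
              nrow(x$panel$snps), nrow(x$world$genes),
              sum(x$truth$genes$causal),
              sum(x$truth$pairs$label == "true_pair"),
              sum(x$truth$pairs$label != "true_pair"),
              nrow(x$truth$traits), sum(x$truth$traits$planted)))
  invisible(x)
}
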