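test_that("configuration validation names the offending field", {
  expect_error(sim_config(maf_min = 0.6), "maf_min")
  expect_error(sim_config(within_block_r2 = 1), "within_block_r2")
  expect_error(sim_config(frac_causal_genes = 1.2), "frac_causal_genes")
  expect_error(sim_config(n_snps = -5), "n_snps")
  expect_error(sim_config(planted_enrichment_factor = 0.5),
               "planted_enrichment_factor")
  expect_error(sim_config(n_instruments_per_gene = c(3, 1)),
               "n_instruments_per_gene")
})

test_that("panel LD structure matches the block target", {
  mean_offdiag_r2 <- function(panel) {
    vals <- unlist(lapply(split(panel$snps$snp_id, panel$snps$block),
                          function(s) {
                            r2 <- cor(panel$dosage[, s])^2
                            r2[upper.tri(r2)]
                          }))
    mean(vals)
  }
  # independence limit
  p0 <- simulate_panel(sim_config(n_snps = 100, n_ref_individuals = 500,
                                  within_block_r2 = 0, seed = 11))
  expect_lt(mean_offdiag_r2(p0), 0.05)
  # calibrated block LD
  p9 <- simulate_panel(sim_config(n_snps = 200, n_ref_individuals = 1000,
                                  within_block_r2 = 0.9, seed = 11))
  expect_lt(abs(mean_offdiag_r2(p9) - 0.9), 0.05)
  # cross-block independence (first two blocks of the default block size)
  d <- p9$dosage
  b <- sum(p9$snps$block == 1)
  r2_cross <- cor(d[, seq_len(b)], d[, b + seq_len(b)])^2
  expect_lt(mean(r2_cross), 0.05)
})

test_that("no emitted SNP violates the minor-allele-frequency floor", {
  for (s in 1:3) {
    p <- simulate_panel(tiny_cfg(seed = s))
    maf <- pmin(p$snps$eaf, 1 - p$snps$eaf)
    expect_true(all(maf >= p$maf_min))
  }
})

test_that("panel positions increase and generators are deterministic", {
  cfg <- tiny_cfg(seed = 5)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  expect_true(all(diff(p1$snps$pos) > 0))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
})

test_that("regulatory world emits labelled truth with exact decoy counts", {
  cfg <- tiny_cfg(seed = 2, decoy_frac = 0.3)
  world <- simulate_regulatory_world(cfg, simulate_panel(cfg))
  truth <- world$truth_pairs
  n_true <- sum(truth$label == "true_pair")
  expect_identical(sum(truth$label != "true_pair"),
                   as.integer(round(0.3 * n_true)))
  # every record traceable to a truth label
  expect_true(all(truth$label %in% c("true_pair", "no_contact",
                                     "weak_eqtl")))
  expect_identical(nrow(world$eqtl), nrow(truth))

  # true pairs: contact present and eQTL p < 1e-6
  key <- function(df) paste(df$snp_id, df$gene_id)
  cand <- find_spatial_pairs(world$contacts, world$assignments)
  tp <- truth[truth$label == "true_pair", ]
  expect_true(all(key(tp) %in% key(cand)))
  expect_true(all(world$eqtl$pval[truth$label == "true_pair"] < 1e-6))

  # no_contact decoys: absent from the contact-supported candidates
  nc <- truth[truth$label == "no_contact", ]
  expect_false(any(key(nc) %in% key(cand)))

  # weak decoys have a contact but a non-significant eQTL
  wk <- truth[truth$label == "weak_eqtl", ]
  expect_true(all(key(wk) %in% key(cand)))
  expect_true(all(world$eqtl$pval[truth$label == "weak_eqtl"] > 0.05))
})

test_that("fragment maps tile the region and SNPs map uniquely", {
  cfg <- tiny_cfg(seed = 4)
  world <- simulate_regulatory_world(cfg, simulate_panel(cfg))
  fr <- world$fragments
  expect_true(all(fr$start[-1] == fr$end[-nrow(fr)]))
  expect_identical(anyDuplicated(world$assignments$snp_map$snp_id), 0L)
  expect_true(all(!is.na(world$assignments$snp_map$fragment_id)))
  # contacts: unordered, no self-contacts, labels from the four cell lines
  expect_true(all(world$contacts$frag_a != world$contacts$frag_b))
  expect_true(all(world$contacts$cell_line %in% world$cell_lines))
  expect_length(world$cell_lines, 4L)
})

test_that("outcome GWAS follows the linear mediation model", {
  cfg <- tiny_cfg(seed = 6)
  panel <- simulate_panel(cfg)
  world <- simulate_regulatory_world(cfg, panel)
  theta <- setNames(rep(0.5, 20), world$genes$gene_id)
  gwas <- simulate_outcome_gwas(cfg, panel, world$eqtl, theta)
  expect_identical(nrow(gwas), nrow(panel$snps))
  expect_true(all(gwas$standard_error > 0))
  # se consistent with the stated effective sample size
  i <- match(gwas$rsid, panel$snps$snp_id)
  expect_equal(gwas$standard_error,
               1 / sqrt(cfg$n_gwas_effective * 2 * panel$snps$eaf[i] *
                          (1 - panel$snps$eaf[i])))
  # alleles always match the panel's ref/alt pair
  expect_true(all((gwas$effect_allele == panel$snps$alt[i] &
                     gwas$other_allele == panel$snps$ref[i]) |
                    (gwas$effect_allele == panel$snps$ref[i] &
                       gwas$other_allele == panel$snps$alt[i])))
  expect_error(simulate_outcome_gwas(cfg, panel, world$eqtl,
                                     c(NOPE = 0.5)), "unknown gene")
})

test_that("null outcome model gives standard-normal Wald z-scores", {
  cfg <- sim_config(n_snps = 2000, n_genes = 10, ld_block_size = 10,
                    n_ref_individuals = 200, seed = 8)
  panel <- simulate_panel(cfg)
  world <- simulate_regulatory_world(cfg, panel)
  theta <- setNames(numeric(10), world$genes$gene_id)
  gwas <- simulate_outcome_gwas(cfg, panel, world$eqtl, theta)
  z <- gwas$beta / gwas$standard_error
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(sd(z) - 1), 0.06)
})

test_that("catalog planting and decoy PPI edges carry their design", {
  cfg <- tiny_cfg(seed = 9)
  study <- simulate_study(cfg)
  expect_identical(sum(study$truth$traits$planted), 1L)
  expect_true(all(table(study$catalog$trait) <=
                    cfg$n_catalog_snps_per_trait))
  expect_identical(anyDuplicated(study$catalog[c("snp_id", "trait")]), 0L)
  # edges: undirected unique pairs, no self loops
  e <- study$edges
  expect_true(all(e$gene_a != e$gene_b))
  expect_identical(anyDuplicated(e[c("gene_a", "gene_b")]), 0L)
  # designated level-1/2 genes reachable only through score > 0.9;
  # decoy genes attach only through sub-threshold edges
  ppi <- study$truth$ppi_levels
  seeds <- ppi$gene_id[!is.na(ppi$level) & ppi$level == 0]
  lv <- expand_levels(seeds, e, score_min = 0.9, n_levels = 2)
  expect_setequal(lv$level1, ppi$gene_id[!is.na(ppi$level) & ppi$level == 1])
  expect_setequal(lv$level2, ppi$gene_id[!is.na(ppi$level) & ppi$level == 2])
  decoy <- ppi$gene_id[is.na(ppi$level)]
  expect_false(any(decoy %in% unlist(lv)))
})

test_that("the planted trait's overlap dominates every background trait", {
  planted_wins <- vapply(41:60, function(s) {
    study <- simulate_study(tiny_cfg(seed = s))
    causal <- study$truth$genes$gene_id[study$truth$genes$causal]
    tp <- study$world$truth_pairs
    snps <- unique(tp$snp_id[tp$label == "true_pair" &
                               tp$gene_id %in% causal])
    expanded <- unique(ld_expand(snps, study$panel, r2_min = 0.8)$snp_id)
    enr <- hypergeom_enrich(expanded, study$catalog)
    planted <- grepl("planted", enr$trait)
    enr$k[planted] > max(enr$k[!planted])
  }, logical(1))
  expect_gte(mean(planted_wins), 0.95)
})

test_that("unit planted enrichment is indistinguishable from background", {
  cfg <- tiny_cfg(seed = 10, planted_enrichment_factor = 1)
  study <- simulate_study(cfg)
  # under factor 1 the planted trait's catalog is a uniform draw; its
  # overlap with the designated genes' eQTL set should sit in the bulk of
  # the background traits' overlaps
  causal <- study$truth$genes$gene_id[study$truth$genes$causal]
  snps <- unique(study$world$eqtl$snp_id[
    study$world$eqtl$gene_id %in% causal &
      study$world$truth_pairs$label == "true_pair"])
  expanded <- unique(ld_expand(snps, study$panel, r2_min = 0.8)$snp_id)
  enr <- hypergeom_enrich(expanded, study$catalog)
  planted_p <- enr$pval[grepl("planted", enr$trait)]
  expect_gt(planted_p, 0.01)
})
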