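test_that("level expansion follows threshold and shell semantics", {
  edges <- data.frame(gene_a = c("a", "b", "a"),
                      gene_b = c("b", "c", "d"),
                      score = c(0.95, 0.92, 0.5))
  lv <- expand_levels("a", edges)
  expect_identical(lv$level0, "a")
  expect_identical(lv$level1, "b")
  expect_identical(lv$level2, "c")
  expect_false("d" %in% unlist(lv))
  # strict inequality at the boundary
  lv2 <- expand_levels("a", data.frame(gene_a = "a", gene_b = "b",
                                       score = 0.9))
  expect_identical(lv2$level1, character(0))
  expect_error(expand_levels(character(0), edges), "empty")
  # level sets are disjoint even with back-edges
  edges3 <- data.frame(gene_a = c("a", "b", "c", "c"),
                       gene_b = c("b", "c", "a", "d"),
                       score = rep(0.95, 4))
  lv3 <- expand_levels("a", edges3)
  all_genes <- unlist(lv3)
  expect_identical(anyDuplicated(all_genes), 0L)
})

test_that("expansion matches an independent graph-library BFS oracle", {
  skip_if_not_installed("igraph")
  set.seed(71)
  for (i in 1:500) {
    n <- sample(5:25, 1)
    genes <- sprintf("g%02d", 1:n)
    m <- sample(4:40, 1)
    edges <- data.frame(gene_a = sample(genes, m, TRUE),
                        gene_b = sample(genes, m, TRUE),
                        score = runif(m, 0.5, 1))
    edges <- edges[edges$gene_a != edges$gene_b, ]
    if (nrow(edges) == 0) next
    seeds <- sample(genes, sample(1:3, 1))
    got <- expand_levels(seeds, edges, score_min = 0.9, n_levels = 2)
    want <- bfs_oracle(seeds, edges, 0.9, 2)
    expect_identical(unclass(got)[names(want)], want)
  }
})

test_that("level eQTL sets are unions over the network", {
  edges <- data.frame(
    snp_id = c("s1", "s2", "s3", "s3", "s4"),
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    n_cell_lines = 1L, effect_allele = "A", other_allele = "G",
    beta = 1, se = 0.1, pval = 1e-9, adj_pval = 1e-8,
    stringsAsFactors = FALSE)
  grn <- grnmr:::new_spatial_grn(edges, 0.05, 5L)
  e <- level_eqtls(c("gA", "gB"), grn)
  expect_setequal(unique(e$snp_id), c("s1", "s2", "s3", "s4"))
  expect_identical(level_eqtls(c("gB", "gA"), grn), e)
  expect_identical(nrow(level_eqtls("gZ", grn)), 0L)
})

test_that("LD expansion adds partners at or above the threshold", {
  set.seed(72)
  a <- rbinom(500, 2, 0.3)
  panel <- panel_from_dosage(cbind(A = a, B = a, C = rbinom(500, 2, 0.3)))
  ex <- ld_expand("A", panel, r2_min = 0.8)
  expect_setequal(unique(ex$snp_id), c("A", "B"))
  expect_identical(ex$source_snp, rep("A", 2))
  # unsatisfiable threshold returns the input set
  ex2 <- ld_expand(c("A", "C"), panel, r2_min = 1.01)
  expect_setequal(unique(ex2$snp_id), c("A", "C"))
  # unknown SNPs pass through unexpanded
  expect_message(ex3 <- ld_expand("rsX", panel), "pass through")
  expect_identical(ex3$snp_id, "rsX")
  # monotonicity: raising the threshold never grows the set
  cfg <- tiny_cfg(seed = 73)
  p <- simulate_panel(cfg)
  snps <- p$snps$snp_id[seq(1, 100, by = 10)]
  sizes <- vapply(c(0.5, 0.8, 0.95),
                  function(r) length(unique(ld_expand(snps, p,
                                                      r2_min = r)$snp_id)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("LD expansion agrees with a brute-force all-pairs oracle", {
  cfg <- tiny_cfg(seed = 74, n_snps = 60, ld_block_size = 6)
  panel <- simulate_panel(cfg)
  r2 <- cor(panel$dosage)^2
  for (i in 1:20) {
    snps <- sample(panel$snps$snp_id, 5)
    got <- unique(ld_expand(snps, panel, r2_min = 0.8)$snp_id)
    want <- unique(c(snps, colnames(r2)[colSums(
      r2[snps, , drop = FALSE] >= 0.8) > 0]))
    expect_setequal(got, want)
  }
  # precomputed partner maps give identical results
  pm <- ld_partner_map(panel, r2_min = 0.8)
  snps <- panel$snps$snp_id[1:7]
  expect_identical(ld_expand(snps, panel, r2_min = 0.8),
                   ld_expand(snps, panel, r2_min = 0.8, partner_map = pm))
})

test_that("hypergeometric p equals exact combinatorial enumeration", {
  # deterministic example: N = 10, K = 4, n = 5, k = 3 -> 66/252
  catalog <- data.frame(
    snp_id = sprintf("s%02d", c(1:10, 1:4)),
    trait = c(rep("bg", 10), rep("tA", 4)))
  enr <- hypergeom_enrich(sprintf("s%02d", c(1, 2, 3, 5, 6)), catalog)
  row <- enr[enr$trait == "tA", ]
  expect_identical(c(row$N, row$K, row$n, row$k), c(10L, 4L, 5L, 3L))
  expect_equal(row$pval, 66 / 252, tolerance = 1e-12)
  # k = n = K extreme: N = 6, K = 3, n = 3 -> 1/20
  catalog2 <- data.frame(snp_id = c(sprintf("s%d", 1:6), "s1", "s2", "s3"),
                         trait = c(rep("bg", 6), rep("tB", 3)))
  row2 <- hypergeom_enrich(c("s1", "s2", "s3"), catalog2)
  row2 <- row2[row2$trait == "tB", ]
  expect_equal(row2$pval, 1 / 20, tolerance = 1e-12)
  # k = 0 is the certain event
  row3 <- hypergeom_enrich(c("s4", "s5"), catalog2)
  expect_equal(row3$pval[row3$trait == "tB"], 1)

  # all parameter combinations with N <= 20 against the enumeration oracle
  set.seed(75)
  for (N in c(5, 12, 20)) {
    for (rep in 1:30) {
      K <- sample(1:N, 1); n <- sample(1:N, 1); k <- sample(0:min(K, n), 1)
      if (n - k > N - K) next
      expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   hyper_oracle(N, K, n, k), tolerance = 1e-12,
                   label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
  }
  # empty overlap warns and returns p = 1 everywhere
  expect_warning(all1 <- hypergeom_enrich("zz", catalog), "p = 1")
  expect_true(all(all1$pval == 1))
})

test_that("bootstrap p follows the (count+1)/(n_boot+1) formula", {
  cfg <- tiny_cfg(seed = 76)
  study <- simulate_study(cfg)
  cand <- find_spatial_pairs(study$world$contacts, study$world$assignments)
  grn <- build_grn(cand, study$world$eqtl)
  boot <- bootstrap_null(names(grn$by_gene), 3, study$edges, grn,
                         study$catalog, study$panel, n_boot = 25, seed = 5)
  expect_equal(boot$boot_pval, (boot$boot_count + 1) / 26)
  expect_true(all(boot$boot_pval >= 1 / 26 & boot$boot_pval <= 1))
  # bit-identical under the same seed
  boot2 <- bootstrap_null(names(grn$by_gene), 3, study$edges, grn,
                          study$catalog, study$panel, n_boot = 25, seed = 5)
  expect_identical(boot, boot2)
  expect_error(bootstrap_null(c("g1", "g2"), 3, study$edges, grn,
                              study$catalog, study$panel),
               "smaller than the seed set size")
})

test_that("the dual significance rule needs both p-values", {
  enr <- data.frame(trait = c("t1", "t2", "t3"), level = 0L,
                    N = 100L, K = 10L, n = 10L, k = c(8L, 8L, 0L),
                    pval = c(0.001, 0.001, 0.9))
  boot <- data.frame(trait = c("t1", "t2", "t3"), level = 0L,
                     boot_count = c(50L, 2L, 0L),
                     boot_pval = c(0.2, 0.02, 1 / 241))
  te <- significant_traits(enr, boot)
  t <- as.data.frame(te)
  expect_identical(t$significant[t$trait == "t1"], FALSE)
  expect_identical(t$significant[t$trait == "t2"], TRUE)
  expect_identical(t$significant[t$trait == "t3"], FALSE)
  expect_error(significant_traits(enr, boot[1:2, ]), "disagree")
})

test_that("raising the score threshold never grows a level", {
  cfg <- tiny_cfg(seed = 77)
  study <- simulate_study(cfg)
  seeds <- study$truth$genes$gene_id[study$truth$genes$causal]
  sizes <- vapply(c(0.5, 0.9, 0.95), function(s) {
    lv <- expand_levels(seeds, study$edges, score_min = s)
    length(unlist(lv))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})
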