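# grnmr

Integrative pipeline for nominating disease-causal genes from regulatory
genomics: spatially constrained eQTL networks, two-sample Mendelian
randomization, cell-type effect orientation, protein-interaction expansion,
and GWAS-catalog trait enrichment — with a fully synthetic study generator so
every stage is testable against known ground truth, offline.

## The problem

GWAS loci rarely name the genes they act through.  One route from variant to
gene combines three kinds of evidence:

1. **Spatial eQTLs.** A SNP is linked to a gene when it associates with the
   gene's expression *and* its restriction fragment physically contacts the
   gene's fragments in Hi-C data (here: contacts from four blood cell lines,
   support in ≥ 1 cell line, Benjamini-Hochberg adjusted eQTL p ≤ 0.05).
   These SNP→gene edges form a bipartite gene regulatory network (GRN).
2. **Two-sample Mendelian randomization (MR).** Each gene's spatial eQTLs
   act as instrumental variables for its expression; combined with
   case-control GWAS summary statistics they estimate the causal effect of
   expression on disease liability.  For gene *g* with instruments *j*:

   - Wald ratio (1 instrument): `θ̂ = β_out / β_exp`,
     `se = se_out / |β_exp|`
   - IVW (≥ 2): `θ̂ = Σ w_j β̂_j / Σ w_j`, `w_j = 1/se_j²`,
     `se = (Σ w_j)^{-1/2}`
   - Weighted median (≥ 3): inverse-variance-weighted 50th percentile of the
     per-instrument ratios (robust to < 50 % invalid weight)
   - Sensitivity: Cochran's Q (heterogeneity) and the MR-Egger intercept
     (directional pleiotropy); genes flagged at p ≤ 0.05 are excluded.
   - Selection: Bonferroni, headline p ≤ 0.05 / m over the m genes tested.

   `exp(θ̂)` is the odds ratio per unit increase in expression; the sign of
   the harmonised outcome beta identifies the **risk allele** of each
   instrument, to which all downstream effect directions are oriented.
3. **Trait sharing.** Causal genes are expanded through a scored
   protein-interaction network (edges with score > 0.9, shells 0–2).  Each
   level's spatial eQTLs, plus LD partners at r² ≥ 0.8, are tested for
   overlap with GWAS-catalog trait associations by a hypergeometric test
   (BH within level), with a gene-set randomization bootstrap null:
   `p_boot = (#{replicates where the trait is significant} + 1) / (n_boot + 1)`
   at the default `n_boot = 240`.  A trait is reported when both the
   adjusted hypergeometric p and the bootstrap p are ≤ 0.05.

The package implements all of this as composable R functions with classed
results (`spatial_grn`, `mr_scan`, `trait_enrichment`), plus a synthetic-data
module that generates every input table — block-LD reference panel, fragment
map, Hi-C contacts, eQTL and GWAS summary tables, per-cell-type eQTLs, trait
catalog, interaction edges — with planted causal genes, labelled decoy edges
and a planted enriched trait.

## Worked example

```r
library(grnmr)

cfg   <- sim_config(seed = 1)          # the documented default study
study <- simulate_study(cfg)

candidates <- find_spatial_pairs(study$world$contacts, study$world$assignments)
grn        <- build_grn(candidates, study$world$eqtl)
scan       <- run_mr_scan(grn, study$gwas, study$panel)
seeds      <- scan$results$gene_id[scan$results$significant]
enrich     <- trait_enrichment_scan(seeds, study$edges, grn, study$catalog,
                                    study$panel, n_boot = 240, seed = 1)
print(grn); print(scan); print(enrich)
```

```
Spatial eQTL gene regulatory network: 712 SNP-gene edges (712 SNPs, 360 genes)
  retained at BH-adjusted p <= 0.05 out of 819 tested pairs
Two-sample MR scan: 360 genes tested (Bonferroni p <= 0.000139)
  6 significant causal gene(s); 18 gene(s) failed sensitivity
 gene_id n_iv                    method odds_ratio      pval
    G358    3 Inverse variance weighted       1.66 2.11e-188
    G063    3 Inverse variance weighted       1.61  6.30e-89
    G047    2 Inverse variance weighted       1.60  5.01e-66
    G173    1                Wald ratio       1.66  1.14e-51
    G201    1                Wald ratio       1.60  5.43e-41
    G197    1                Wald ratio       1.79  2.47e-21
Trait enrichment: 90 trait-level tests; universe = distinct SNPs in the trait catalog
  level 0: 1 significant trait(s) (trait_planted_01)
  level 1: 0 significant trait(s)
  level 2: 0 significant trait(s)
```

The six Bonferroni-significant genes are exactly the six genes the generator
made causal (θ = 0.5, so OR ≈ e^0.5 ≈ 1.65 per unit expression), and the one
trait planted at 10× enrichment among their regulatory SNPs is the one trait
recovered at level 0; the 107 decoy pairs that fail exactly one retention
rule are all absent from the network.  `coef()`, `confint()`, `summary()`
and `as.data.frame()` work on the scan; `lookup_iv_effects()` +
`orient_to_risk()` produce the risk-allele-oriented cell-type matrix, and
`gene_trait_matrix()` / `hcluster_matrix()` / `write_reports()` produce the
clustered report tables.

A thin CLI mirrors the same steps
(`Rscript $(Rscript -e 'cat(system.file("cli.R", package="grnmr"))') simulate --config cfg.yaml --outdir DIR --seed 3`,
then `build-grn`, `run-mr`, `celltype`, `ppin-traits`, `report`).

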