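---
title: "Methods: spatial-eQTL networks, Mendelian randomization and trait enrichment"
author: "grnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-eQTL networks, Mendelian randomization and trait enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(grnmr)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where the method leaves
room.

## 1. The spatially constrained regulatory network

A *spatial eQTL* is a SNP that (a) associates with a gene's expression and
(b) sits in a restriction fragment that physically contacts one of the
gene's fragments in Hi-C data.  `build_grn()` composes three operations:

* `assign_fragments()` maps each SNP to its unique containing fragment and
  each gene to every fragment overlapping its body.  All coordinates are
  0-based half-open (BED convention); a SNP at a fragment boundary belongs
  to the right-hand fragment.  Whole gene bodies are used rather than the
  TSS because the overlap unit of fragment-based contact maps is the
  fragment, not a point.
* `find_spatial_pairs()` counts, per SNP-gene pair, the cell lines in which
  any gene fragment contacts the SNP fragment.  Contacts are unordered and
  deduplicated per cell line before counting (contact matrices are
  symmetric); support in at least one of the four cell lines retains a
  pair.  A SNP and gene sharing a fragment are linked only if a self-contact
  is recorded, and the contact sets exclude self-contacts, so co-location
  alone is never evidence.
* `bh_adjust()` applies the Benjamini-Hochberg step-up adjustment once
  across *all* contact-supported, eQTL-covered pairs in the run — one test
  family, not per gene — and pairs with adjusted p ≤ 0.05 (the `fdr`
  argument) survive.

No cis-window restriction is imposed on the eQTL join: the contact
requirement is the spatial constraint, and adding a distance filter would
silently re-define the method.

## 2. Two-sample Mendelian randomization

`run_mr_scan()` treats each gene's surviving network SNPs as candidate
instruments for its expression and estimates the causal effect of
expression on the (log-odds scale) outcome.

**Clumping.**  Instruments are greedily pruned by exposure p-value under a
pairwise r² ceiling of 0.001 estimated from the reference panel, *within a
250 kb distance window* (`kb` argument).  The window deserves a note: r²
estimated from n individuals scatters around 1/n between truly unlinked
SNPs, which is far above 0.001 for any realistic panel, so a windowless
ceiling would prune essentially everything.  Clumping tools therefore only
ever compare SNPs within a local window; we adopt the same convention, with
`kb = Inf` available to disable it.  Ranking is by exposure p because
instruments are selected for exposure relevance before the outcome is seen.

**Harmonisation.**  `harmonise_instruments()` re-expresses each outcome
beta on the exposure's effect allele, resolving label swaps and strand
flips.  Palindromic (A/T, C/G) pairs cannot be resolved by labels; outside
the frequency ambiguity window (default open interval 0.42–0.58) they are
resolved by matching which side of 0.5 the effect-allele frequencies fall
on, inside it they are dropped.  The *risk allele* is read off the
harmonised outcome beta: positive means the effect allele raises risk
(`orientation_sign = +1`), negative means the other allele does.  An exact
zero — a measure-zero event — is assigned to the effect allele with a
logged note.  The allele-flip transform is an involution, and the whole
pipeline is invariant under arbitrary ref/alt relabelling of its inputs;
both are enforced by tests.

**Estimation and dispatch.**  One instrument: Wald ratio.  Two: fixed-effect
IVW.  Three or more: IVW as the headline estimate with the weighted median
reported alongside — one estimate per gene is reported, and IVW is the
default the dispatch rule names for multi-instrument genes.  All weights are
first-order (`1/se_ratio²`, exposure-side variance ignored), the standard
default in two-sample MR; a second-order variant could be added without
changing interfaces.  The weighted median uses cumulative-weight linear
interpolation between bracketing ratios (nearest-rank is the other
defensible reading; interpolation is the common software default and is
flagged here as the choice).  Its standard error comes from a parametric
bootstrap (default 1000 draws) under a fixed internal seed, so results are
reproducible and the caller's RNG stream is untouched.

**Sensitivity and selection.**  Cochran's Q (≥ 2 instruments) and the
MR-Egger intercept (≥ 3, exposure betas oriented non-negative first, WLS
with weights `1/se_out²`, t-distribution p on J−2 df) flag heterogeneity
and directional pleiotropy at p ≤ 0.05; flagged genes are excluded from the
causal list.  Significance is Bonferroni at `0.05 / m` where m counts the
genes that retained at least one instrument *in this run* — m is a property
of the data set, not a constant.

Degenerate inputs are errors, not guesses: a zero exposure beta
(undefined ratio), a monomorphic SNP (undefined LD), collinear exposure
betas in the Egger design.  An Egger fit with zero residual has a known
intercept; its p-value degenerates to 0/1 by the intercept's value.

## 3. Cell-type effects oriented to the risk allele

`lookup_iv_effects()` restricts the cell-type analysis to exactly the
instrument SNP-gene pairs from the scan — the same SNP regulating a
*different* gene is excluded — and BH-adjusts within each cell type (the
quoted rule is per cell type, so each cell type is one family).
`orient_to_risk()` re-signs each reported beta so direction refers to the
risk allele, using allele-aware alignment (swap or strand complement); a
pair without a harmonisation record is an error.  Missing cells stay
missing — rendering them as zero would fabricate a null effect.

## 4. Interaction-network expansion and trait enrichment

`expand_levels()` performs breadth-first shells on the subgraph of edges
with score **strictly greater than** 0.9 (the boundary is excluded, as the
filter is written); level k is the set of new neighbours of level k−1.
Levels are disjoint and serialized sorted, so output is deterministic.
`level_eqtls()` unions the network SNPs of a level's genes; `ld_expand()`
adds every panel SNP at r² ≥ 0.8 (**inclusive**) with provenance back to
its source eQTL.

`hypergeom_enrich()` needs a sampling frame the method itself does not
name.  We take N = distinct SNPs in the trait catalog, K = the trait's
distinct catalog SNPs, n = expanded-set members present in the catalog,
k = expanded members carrying the trait, and report the upper tail
P(X ≥ k).  This keeps all four parameters inside one frame (the catalog);
the alternative universe (catalog ∪ network SNPs) inflates N with SNPs that
can never overlap any trait and makes every p smaller.  The choice is
stated in the result object's metadata.  Overlap counts *distinct catalog
SNPs*: an eQTL and its LD partners credit a catalog SNP once.

`bootstrap_null()` re-runs the entire chain — expansion, eQTL collection,
LD expansion, hypergeometric test, BH within level — for each of `n_boot`
(default 240) random seed sets of the observed size, drawn uniformly
without replacement from the genes present in the network (the observed
seeds were network-eligible genes, so the null draws from the same frame).
The bootstrap p is `(count + 1) / (n_boot + 1)`, bounded in
`[1/(n_boot+1), 1]`.  One replicate stream is drawn per run and reused
across levels.  Replicates apply the same BH-within-level rule at
α = 0.05 rather than reusing the observed thresholds: each replicate is a
complete re-analysis.  A trait is *significant* only if both its
BH-adjusted hypergeometric p and its bootstrap p are ≤ 0.05.

## 5. Report matrices and clustering

`gene_trait_matrix()` fills cells with `log10(count + 1)` of the distinct
catalog SNPs credited to a gene for a trait (base 10 with a +1 offset keeps
zero counts at exactly zero; the log base is a package choice and is noted
in output metadata).  `hcluster_matrix()` uses standard agglomerative
clustering with Euclidean distance and complete linkage — the defaults of
the heatmap tooling this style of figure is drawn with — both configurable.
Rows are sorted lexicographically before clustering so tie-breaking is
deterministic; missing cells are row-mean imputed *for the distance
computation only* and remain missing in every written table.  Dendrograms
serialize as newick.

## 6. What the synthetic generator emulates — and what it does not

`simulate_study()` draws every input table from one seeded configuration
(`sim_config()`); identical configurations give byte-identical bundles, and
each component generator is independently seeded, so the bundle is a pure
function of its configuration.

* **Reference panel.**  Block LD by haplotype copying: each block has an
  ancestral haplotype per chromosome and every site copies it with
  probability `within_block_r2^(1/4)`, giving pairwise dosage r² at the
  target (default 0.9) inside blocks and independence between blocks.
  Blocks are regenerated until every folded minor-allele frequency clears
  the 0.05 common-variant floor.  The layout places one SNP per 10 kb and
  separates blocks by 300 kb, so physical distance and LD agree the way
  distance-windowed clumping expects.  Allele pairs are non-palindromic by
  construction (ambiguous-strand variants are conventionally excluded from
  instrument sets); palindromic handling is exercised by explicit cases.
* **Regulatory world.**  Each gene receives 1–3 true instrument SNPs in
  distinct LD blocks, a contact in ≥ 1 of four cell lines, and an eQTL row
  with p < 1e-6.  Decoy pairs (30 % of true pairs) violate exactly one
  retention rule — `no_contact` or `weak_eqtl` — so each filter's behaviour
  is separately observable.  Instrument SNPs are globally exclusive (one
  gene each), and the causal genes' blocks are retired entirely: at genome
  scale a random gene set's eQTLs are essentially never in LD with the
  causal loci, and block-exclusive placement preserves that property in a
  compressed genome.  Without it, random bootstrap seed sets collide with
  causal loci at rates real data never shows, and the bootstrap null is
  contaminated by construction rather than by biology.
* **Outcome GWAS.**  `β_out = θ_g β_exp + α + noise` with standard errors
  from one effective sample size for all SNPs, default
  n_eff = 4/(1/3305 + 1/9196) ≈ 9725, the harmonic effective size of the
  case-control design the pipeline targets.  The noise standard deviation
  equals the reported standard error, so null Wald z-scores are exactly
  standard normal — type-I error and CI coverage are then method
  properties, not generator artifacts.  Pleiotropic direct effects are
  drawn per exposure-increasing allele; with random eQTL signs, alt-allele
  directional pleiotropy would cancel under Egger orientation and no
  directional signal could ever be simulated.
* **Scale.**  The default study uses 360 genes (6 causal, θ = 0.5),
  900 panel SNPs in blocks of 4 over 500 individuals, 15 cell types,
  30 traits with one planted at 10× enrichment, 200 catalog SNPs per
  trait.  These sizes keep the causal fraction small relative to the gene
  universe — the regime the gene-set bootstrap assumes — while every stage
  still runs in seconds.  Statistical checks in the test suite use larger
  dedicated worlds (up to 4000 single-instrument genes for type-I error,
  2000 for coverage, 300 six-instrument genes per pleiotropy arm, 50
  replicate worlds for planted-trait recovery); these sizes are the
  package's documented experiment design.
* **Not emulated:** realistic human LD maps and allele-frequency spectra,
  phased haplotypes, population structure and other confounding beyond the
  pleiotropy term, winner's curse in instrument selection, shared
  instruments across genes (real data has them; the scan handles them, but
  truth labels in simulation stay exclusive), overlapping exposure/outcome
  samples, and trait catalogs with realistic per-trait SNP counts.  Passing
  tests therefore demonstrate correctness of the estimators, filters and
  null machinery under the stated generative model — not robustness to
  every failure mode of real summary statistics.

## 7. Numerical conventions

* BH adjustment is order-preserving, capped at 1, and matches a brute-force
  step-up oracle to 1e-12; hypergeometric tails match exact combinatorial
  enumeration to 1e-12 for N ≤ 20.
* MR estimators match closed-form/brute-force oracles to 1e-9 on random
  instances; the weighted median's interpolation is checked against an
  independent cumulative-weight oracle.
* Determinism: generators, the bootstrap and the weighted-median bootstrap
  restore the caller's RNG state; rerunning any stage with the same inputs
  and seeds is byte-identical, including written report files.
* Ties: clumping breaks p-value ties by SNP id; clustering breaks distance
  ties by lexicographic label order; a harmonised outcome beta of exactly 0
  assigns the risk allele to the effect allele with a note.

## 8. Known limitations

The bootstrap null re-runs the full chain per replicate, so its cost is
linear in `n_boot`; the default 240 is the method's shipped configuration
and smaller counts coarsen the p floor to `1/(n_boot+1)`.  The Egger
intercept has low power with few instruments or a narrow exposure-beta
spread — the test suite's power checks use six instruments per gene for
that reason.  The hypergeometric universe choice materially affects
p-values and is deliberately explicit rather than hidden.  MR assumptions
themselves (relevance, exchangeability, exclusion restriction) are tested
only as far as Q and the Egger intercept can see; multivariable MR,
MR-PRESSO and colocalization are out of scope.
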