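#' Per-gene two-sample Mendelian randomization scan
#'
#' For every gene in the network: take its spatial-eQTL SNPs as candidate
#' instruments, LD-clump them by exposure p-value, harmonise against the
#' outcome GWAS, and estimate the causal effect of expression on the outcome.
#' Dispatch follows the surviving instrument count: one instrument uses the
#' Wald ratio; two use inverse-variance weighting; three or more use IVW as
#' the headline estimate with the weighted median reported alongside.
#' Cochran's Q (two or more instruments) and the MR-Egger intercept (three or
#' more) provide the sensitivity analyses: a gene passes when neither flags
#' at p <= 0.05.  A gene is declared significant when it passes sensitivity
#' and its headline p-value is at or below the Bonferroni threshold
#' `0.05 / m`, with `m` the number of genes that retained at least one
#' instrument in this run.
#'
#' @param grn a `spatial_grn` from [build_grn()].
#' @param gwas outcome GWAS summary table (GWAS-SSF or short column names).
#' @param panel a `genotype_panel` (LD reference for clumping and the source
#'   of exposure effect-allele frequencies).
#' @param clump_r2 pairwise r-squared ceiling for clumping (default 0.001).
#' @param alpha family-wise error rate for the Bonferroni rule and the
#'   sensitivity flags (default 0.05).
#' @param wm_boot bootstrap draws for the weighted-median standard error.
#' @return an object of class `mr_scan`; `results` holds one row per gene
#'   (`gene_id`, `n_iv`, `method`, `estimate`, `se`, `pval`, `odds_ratio`,
#'   `wm_estimate`, `wm_pval`, `q_stat`, `q_df`, `q_pval`, `egger_intercept`,
#'   `egger_pval`, `passed_sensitivity`, `significant`), `harmonised` the
#'   per-gene harmonised instruments, and `dropped` the genes that lost all
#'   instruments with a reason.
#' @export
run_mr_scan <- function(grn, gwas, panel, clump_r2 = 0.001, alpha = 0.05,
                        wm_boot = 1000) {
  if (!inherits(grn, "spatial_grn")) stop("'grn' must be a spatial_grn",
                                          call. = FALSE)
  if (nrow(grn$edges) == 0) stop("the network has no edges", call. = FALSE)
  gwas <- normalise_gwas_columns(gwas)
  assert_cols(gwas, c("snp_id", "effect_allele", "other_allele",
                      "beta", "se"), "outcome GWAS")

  genes <- sort(names(grn$by_gene))
  n_missing <- sum(!grn$edges$snp_id %in% gwas$snp_id)
  if (n_missing > 0)
    message(n_missing, " instrument record(s) had no outcome GWAS row and ",
            "were dropped")

  rows <- vector("list", length(genes))
  harm_all <- vector("list", length(genes))
  dropped <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    edges <- grn$edges[grn$by_gene[[g]], , drop = FALSE]
    edges <- edges[edges$snp_id %in% gwas$snp_id, , drop = FALSE]
    if (nrow(edges) == 0) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(gene_id = g, reason = "no instrument in outcome GWAS")
      next
    }
    kept <- clump_instruments(edges[c("snp_id", "pval")], panel,
                              r2_max = clump_r2)
    edges <- edges[match(kept, edges$snp_id), , drop = FALSE]

    exposure <- data.frame(
      snp_id = edges$snp_id, effect_allele = edges$effect_allele,
      other_allele = edges$other_allele, beta = edges$beta, se = edges$se,
      pval = edges$pval,
      eaf = panel$snps$eaf[match(edges$snp_id, panel$snps$snp_id)],
      stringsAsFactors = FALSE)
    h <- harmonise_instruments(exposure,
                               gwas[gwas$snp_id %in% edges$snp_id, ])
    if (nrow(h) == 0) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(gene_id = g,
                   reason = "all instruments lost in harmonisation")
      next
    }
    harm_all[[gi]] <- cbind(gene_id = g, as.data.frame(h))

    J <- nrow(h)
    if (J == 1) {
      fit <- wald_ratio(h); method <- "Wald ratio"
    } else {
      fit <- ivw(h)
      method <- "Inverse variance weighted"
    }
    wm <- if (J >= 3) weighted_median(h, n_boot = wm_boot) else NULL
    qh <- if (J >= 2) cochran_q(h, fit$estimate) else NULL
    eg <- if (J >= 3) egger_intercept(h) else NULL
    passed <- (is.null(qh) || qh$p > alpha) && (is.null(eg) || eg$p > alpha)
    rows[[gi]] <- data.frame(
      gene_id = g, n_iv = J, method = method,
      estimate = fit$estimate, se = fit$se, pval = fit$p,
      odds_ratio = exp(fit$estimate),
      wm_estimate = if (is.null(wm)) NA_real_ else wm$estimate,
      wm_pval = if (is.null(wm)) NA_real_ else wm$p,
      q_stat = if (is.null(qh)) NA_real_ else qh$q,
      q_df = if (is.null(qh)) NA_integer_ else qh$df,
      q_pval = if (is.null(qh)) NA_real_ else qh$p,
      egger_intercept = if (is.null(eg)) NA_real_ else eg$intercept,
      egger_pval = if (is.null(eg)) NA_real_ else eg$p,
      passed_sensitivity = passed,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(results) || nrow(results) == 0)
    stop("no gene retained an instrument after clumping and harmonisation",
         call. = FALSE)
  m <- nrow(results)
  threshold <- alpha / m
  results$significant <- results$passed_sensitivity &
    results$pval <= threshold
  results <- results[order(results$pval), ]
  rownames(results) <- NULL
  harmonised <- do.call(rbind,
                        harm_all[!vapply(harm_all, is.null, logical(1))])
  rownames(harmonised) <- NULL
  structure(list(results = results, m = m, threshold = threshold,
                 alpha = alpha, clump_r2 = clump_r2,
                 harmonised = harmonised,
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                           else data.frame(gene_id = character(0),
                                           reason = character(0))),
            class = "mr_scan")
}

#' @export
print.mr_scan <- function(x, ...) {
  cat(sprintf("Two-sample MR scan: %d genes tested (Bonferroni p <= %.3g)\n",
              x$m, x$threshold))
  sig <- x$results[x$results$significant, ]
  cat(sprintf("  %d significant causal gene(s); %d gene(s) failed sensitivity\n",
              nrow(sig), sum(!x$results$passed_sensitivity)))
  if (nrow(sig)) {
    show <- utils::head(sig[c("gene_id", "n_iv", "method", "odds_ratio",
                              "pval")], 10)
    show$odds_ratio <- signif(show$odds_ratio, 3)
    show$pval <- signif(show$pval, 3)
    print(show, row.names = FALSE)
    if (nrow(sig) > 10) cat(sprintf("  ... and %d more\n", nrow(sig) - 10))
  }
  invisible(x)
}

#' @export
summary.mr_scan <- function(object, ...) {
  r <- object$results
  cat(sprintf("Genes tested: %d; threshold 0.05/m = %.3g\n",
              object$m, object$threshold))
  cat("Method dispatch:\n"); print(table(r$method))
  cat(sprintf("Significant: %d; failed sensitivity: %d; dropped: %d\n",
              sum(r$significant), sum(!r$passed_sensitivity),
              nrow(object$dropped)))
  invisible(object)
}

#' @export
coef.mr_scan <- function(object, ...) {
  stats::setNames(object$results$estimate, object$results$gene_id)
}

#' @export
confint.mr_scan <- function(object, parm, level = 0.95, ...) {
  r <- object$results
  if (!missing(parm)) r <- r[r$gene_id %in% parm, ]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(r$estimate - z * r$se, r$estimate + z * r$se)
  dimnames(out) <- list(r$gene_id,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  out
}

#' @export
as.data.frame.mr_scan <- function(x, ...) x$results
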