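#' Harmonise exposure and outcome summary statistics
#'
#' Re-expresses the outcome effect of every shared SNP on the exposure's
#' effect allele.  Allele pairs are matched directly, as a ref/alt swap
#' (outcome beta re-signed, frequency flipped) or after a strand flip;
#' irreconcilable pairs raise an error naming the SNP.  Palindromic (A/T or
#' C/G) SNPs whose effect-allele frequency lies inside the ambiguity window
#' are dropped; outside the window they are resolved by frequency matching
#' (the outcome allele whose frequency sits on the same side of 0.5 as the
#' exposure's is taken to be the same allele).  The risk allele is then read
#' off the harmonised outcome beta: positive beta means the effect allele is
#' the risk allele (`orientation_sign = +1`), negative means the other
#' allele is (`orientation_sign = -1`); a beta of exactly zero is assigned
#' to the effect allele with a note.
#'
#' @param exposure data frame with `snp_id`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pval` and `eaf` (effect-allele frequency).
#' @param outcome data frame with `snp_id`, `effect_allele`, `other_allele`,
#'   `beta`, `se` and `eaf` (GWAS-SSF-named columns are also accepted).
#' @param palindromic_window open frequency interval inside which palindromic
#'   SNPs are considered unresolvable (default `c(0.42, 0.58)`).
#' @return data frame of class `harmonised_instruments`: one row per retained
#'   SNP with `snp_id`, `effect_allele`, `other_allele`, `beta_exposure`,
#'   `se_exposure`, `p_exposure`, `eaf`, `beta_outcome`, `se_outcome`,
#'   `risk_allele` (`"effect"` or `"other"`) and `orientation_sign`.
#'   Dropped palindromic SNPs are recorded in the `"dropped_palindromic"`
#'   attribute.
#' @export
harmonise_instruments <- function(exposure, outcome,
                                  palindromic_window = c(0.42, 0.58)) {
  outcome <- normalise_gwas_columns(outcome)
  assert_cols(exposure, c("snp_id", "effect_allele", "other_allele",
                          "beta", "se", "pval", "eaf"), "exposure table")
  assert_cols(outcome, c("snp_id", "effect_allele", "other_allele",
                         "beta", "se"), "outcome table")
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  ei <- match(shared, exposure$snp_id)
  oi <- match(shared, outcome$snp_id)

  n <- length(shared)
  keep <- rep(TRUE, n)
  dropped <- character(0)
  bout <- numeric(n); seout <- numeric(n)
  for (i in seq_len(n)) {
    e_ea <- toupper(exposure$effect_allele[ei[i]])
    e_oa <- toupper(exposure$other_allele[ei[i]])
    o_ea <- toupper(outcome$effect_allele[oi[i]])
    o_oa <- toupper(outcome$other_allele[oi[i]])
    b <- outcome$beta[oi[i]]
    o_eaf <- if ("eaf" %in% names(outcome)) outcome$eaf[oi[i]] else NA_real_

    if (is_palindromic(e_ea, e_oa)) {
      f <- exposure$eaf[ei[i]]
      if (f > palindromic_window[1] && f < palindromic_window[2]) {
        keep[i] <- FALSE
        dropped <- c(dropped, shared[i])
        next
      }
      # labels cannot distinguish strands; align by frequency side
      if (!(identical(o_ea, e_ea) && identical(o_oa, e_oa)) &&
          !(identical(o_ea, e_oa) && identical(o_oa, e_ea)))
        stop(sprintf("cannot harmonise SNP '%s': allele pair %s/%s vs %s/%s",
                     shared[i], e_ea, e_oa, o_ea, o_oa), call. = FALSE)
      same_label <- identical(o_ea, e_ea)
      sign_out <- if (same_label) 1 else -1
      if (!is.na(o_eaf)) {
        # frequency of the outcome effect re-expressed on the exposure's
        # effect allele under the label alignment; disagreement on the
        # side of 0.5 indicates the strands differ, which for a
        # palindromic pair inverts the alignment
        o_f_on_e <- if (same_label) o_eaf else 1 - o_eaf
        if ((f < 0.5) != (o_f_on_e < 0.5)) sign_out <- -sign_out
      }
      bout[i] <- sign_out * b
      seout[i] <- outcome$se[oi[i]]
      next
    }

    matched <- FALSE
    for (flip_strand in c(FALSE, TRUE)) {
      a1 <- if (flip_strand) dna_complement(o_ea) else o_ea
      a2 <- if (flip_strand) dna_complement(o_oa) else o_oa
      if (identical(a1, e_ea) && identical(a2, e_oa)) {
        bout[i] <- b; matched <- TRUE; break
      }
      if (identical(a1, e_oa) && identical(a2, e_ea)) {
        bout[i] <- -b; matched <- TRUE; break
      }
    }
    if (!matched)
      stop(sprintf("cannot harmonise SNP '%s': allele pair %s/%s vs %s/%s",
                   shared[i], e_ea, e_oa, o_ea, o_oa), call. = FALSE)
    seout[i] <- outcome$se[oi[i]]
  }

  idx <- which(keep)
  if (any(bout[idx] == 0))
    message("harmonised outcome beta of exactly 0 for SNP(s) ",
            paste(shared[idx][bout[idx] == 0], collapse = ", "),
            "; risk allele assigned to the effect allele by convention")
  h <- data.frame(
    snp_id = shared[idx],
    effect_allele = toupper(exposure$effect_allele[ei[idx]]),
    other_allele = toupper(exposure$other_allele[ei[idx]]),
    beta_exposure = exposure$beta[ei[idx]],
    se_exposure = exposure$se[ei[idx]],
    p_exposure = exposure$pval[ei[idx]],
    eaf = exposure$eaf[ei[idx]],
    beta_outcome = bout[idx],
    se_outcome = seout[idx],
    stringsAsFactors = FALSE)
  h$risk_allele <- ifelse(h$beta_outcome >= 0, "effect", "other")
  h$orientation_sign <- ifelse(h$beta_outcome >= 0, 1, -1)
  attr(h, "dropped_palindromic") <- dropped
  class(h) <- c("harmonised_instruments", "data.frame")
  h
}

# accept GWAS-SSF column names alongside the short convention
normalise_gwas_columns <- function(df) {
  map <- c(rsid = "snp_id", chromosome = "chrom",
           base_pair_location = "pos",
           effect_allele_frequency = "eaf",
           standard_error = "se", p_value = "pval")
  for (from in names(map)) {
    to <- map[[from]]
    if (from %in% names(df) && !(to %in% names(df)))
      names(df)[names(df) == from] <- to
  }
  df
}

#' Wald ratio estimate from a single instrument
#'
#' `estimate = beta_outcome / beta_exposure`, with first-order standard
#' error `se_outcome / |beta_exposure|` and a two-sided normal p-value.
#'
#' @param h a one-row `harmonised_instruments` (or any list with
#'   `beta_exposure`, `beta_outcome`, `se_outcome`).
#' @return list with `estimate`, `se`, `p`.
#' @examples
#' wald_ratio(list(beta_exposure = 0.5, beta_outcome = 1.0, se_outcome = 0.2))
#' @export
wald_ratio <- function(h) {
  if (any(h$beta_exposure == 0))
    stop("degenerate instrument: exposure beta is zero", call. = FALSE)
  est <- h$beta_outcome[1] / h$beta_exposure[1]
  se <- h$se_outcome[1] / abs(h$beta_exposure[1])
  list(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
}

# per-instrument ratios and first-order inverse-variance weights
ratio_terms <- function(h) {
  if (any(h$beta_exposure == 0))
    stop("degenerate instrument: exposure beta is zero", call. = FALSE)
  b <- h$beta_outcome / h$beta_exposure
  se <- h$se_outcome / abs(h$beta_exposure)
  list(b = b, se = se, w = 1 / se^2)
}

#' Inverse-variance-weighted estimate
#'
#' Fixed-effect inverse-variance meta-analysis of the per-instrument Wald
#' ratios with first-order weights.
#'
#' @param hs `harmonised_instruments` with at least 2 rows.
#' @return list with `estimate`, `se`, `p`.
#' @export
ivw <- function(hs) {
  if (nrow(hs) < 2)
    stop("IVW requires at least 2 instruments", call. = FALSE)
  r <- ratio_terms(hs)
  est <- sum(r$w * r$b) / sum(r$w)
  se <- sqrt(1 / sum(r$w))
  list(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
}

# inverse-variance-weighted 50th percentile with linear interpolation
weighted_percentile <- function(b, w, prob = 0.5) {
  o <- order(b)
  b <- b[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (prob <= s[1]) return(b[1])
  if (prob >= s[length(s)]) return(b[length(b)])
  j <- max(which(s < prob))
  b[j] + (b[j + 1] - b[j]) * (prob - s[j]) / (s[j + 1] - s[j])
}

#' Weighted-median estimate
#'
#' Inverse-variance-weighted 50th percentile of the per-instrument ratios,
#' with linear interpolation between bracketing ratios.  The standard error
#' comes from a parametric bootstrap (exposure and outcome betas resampled
#' from their normal sampling distributions) under a fixed internal seed, so
#' repeated calls are reproducible and leave the caller's random stream
#' untouched.
#'
#' @param hs `harmonised_instruments` with at least 3 rows.
#' @param n_boot bootstrap draws for the standard error (default 1000; 0
#'   skips the bootstrap and returns `NA` se/p, useful when only the point
#'   estimate is needed).
#' @param boot_seed internal bootstrap seed.
#' @return list with `estimate`, `se`, `p`.
#' @export
weighted_median <- function(hs, n_boot = 1000, boot_seed = 20240901) {
  if (nrow(hs) < 3)
    stop("the weighted median requires at least 3 instruments", call. = FALSE)
  r <- ratio_terms(hs)
  est <- weighted_percentile(r$b, r$w)
  if (n_boot <= 0)
    return(list(estimate = est, se = NA_real_, p = NA_real_))
  J <- nrow(hs)
  boots <- with_seed(boot_seed, {
    bexp <- matrix(stats::rnorm(n_boot * J, hs$beta_exposure,
                                hs$se_exposure), ncol = J, byrow = TRUE)
    bout <- matrix(stats::rnorm(n_boot * J, hs$beta_outcome,
                                hs$se_outcome), ncol = J, byrow = TRUE)
    vapply(seq_len(n_boot), function(i) {
      bb <- bout[i, ] / bexp[i, ]
      ww <- bexp[i, ]^2 / hs$se_outcome^2
      weighted_percentile(bb, ww)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  list(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (b_j - estimate)^2` over the per-instrument ratios, compared
#' to a chi-square with J-1 degrees of freedom.
#'
#' @param hs `harmonised_instruments` with at least 2 rows.
#' @param ivw_estimate the pooled estimate the ratios are compared against
#'   (defaults to the IVW estimate of `hs`).
#' @return list with `q`, `df`, `p`.
#' @export
cochran_q <- function(hs, ivw_estimate = NULL) {
  if (nrow(hs) < 2)
    stop("Cochran's Q requires at least 2 instruments", call. = FALSE)
  r <- ratio_terms(hs)
  if (is.null(ivw_estimate)) ivw_estimate <- sum(r$w * r$b) / sum(r$w)
  q <- sum(r$w * (r$b - ivw_estimate)^2)
  df <- nrow(hs) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Weighted least squares of the outcome betas on the exposure betas with a
#' free intercept and weights `1/se_outcome^2`, after orienting all exposure
#' betas non-negative (the standard Egger orientation).  A significant
#' non-zero intercept (p <= 0.05) is evidence of directional horizontal
#' pleiotropy.  P-values use the t distribution with J-2 degrees of freedom.
#'
#' @param hs `harmonised_instruments` with at least 3 rows.
#' @return list with `intercept`, `se`, `p`, and the `slope` of the fit.
#' @export
egger_intercept <- function(hs) {
  if (nrow(hs) < 3)
    stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- sign(hs$beta_exposure)
  flip[flip == 0] <- 1
  x <- hs$beta_exposure * flip
  y <- hs$beta_outcome * flip
  w <- 1 / hs$se_outcome^2
  if (stats::var(x) == 0)
    stop("degenerate Egger design: exposure betas are collinear",
         call. = FALSE)
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)$coefficients
  int <- sm["(Intercept)", "Estimate"]
  se <- sm["(Intercept)", "Std. Error"]
  # an exact fit (zero residual) gives se 0; the intercept is then known
  # without error
  p <- if (se == 0) as.numeric(int == 0) else
    2 * stats::pt(-abs(int / se), df = nrow(hs) - 2)
  list(intercept = int, se = se, p = p,
       slope = sm["x", "Estimate"])
}

#' Greedy LD clumping of instruments
#'
#' Repeatedly keeps the instrument with the smallest exposure p-value and
#' removes every remaining instrument lying within the distance window whose
#' r-squared against it exceeds `r2_max`.  The window (standard practice in
#' clumping tools) exists because r-squared is estimated from a finite
#' reference panel: between truly unlinked SNPs the estimate scatters around
#' 1/(n individuals), which a ceiling as strict as 0.001 would otherwise
#' treat as real LD.  Within the window, the retained set has pairwise
#' estimated r-squared at or below the ceiling.
#'
#' @param instruments data frame with `snp_id` and `pval` (exposure p).
#' @param panel a `genotype_panel` for LD (also supplies positions).
#' @param r2_max pairwise r-squared ceiling (default 0.001).
#' @param kb distance window in kilobases (default 250); SNPs on different
#'   chromosomes or farther apart than this are never pruned against each
#'   other.  `Inf` disables the window.
#' @return character vector of retained SNP ids, in selection order.
#' @export
clump_instruments <- function(instruments, panel, r2_max = 0.001,
                              kb = 250) {
  assert_cols(instruments, c("snp_id", "pval"), "instrument table")
  if (nrow(instruments) == 0) return(character(0))
  instruments <- instruments[!duplicated(instruments$snp_id), ]
  if (nrow(instruments) == 1) return(instruments$snp_id)
  r2 <- ld_r2_matrix(panel, instruments$snp_id)
  i <- match(instruments$snp_id, panel$snps$snp_id)
  same_chr <- outer(panel$snps$chrom[i], panel$snps$chrom[i], "==")
  near <- same_chr &
    abs(outer(panel$snps$pos[i], panel$snps$pos[i], "-")) <= kb * 1000
  remaining <- order(instruments$pval, instruments$snp_id)
  kept <- integer(0)
  while (length(remaining)) {
    top <- remaining[1]
    kept <- c(kept, top)
    remaining <- remaining[!(near[remaining, top] &
                               r2[remaining, top] > r2_max)]
  }
  instruments$snp_id[kept]
}
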