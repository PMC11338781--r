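test_that("Wald ratio arithmetic, null and sign invariance", {
  h <- h_frame(0.5, 1.0, 0.2)
  fit <- wald_ratio(h)
  expect_equal(fit$estimate, 2.0)
  expect_equal(fit$se, 0.4)
  expect_equal(exp(fit$estimate), exp(2), tolerance = 1e-12)
  expect_equal(wald_ratio(h_frame(0.5, 0, 0.2))$estimate, 0)
  neg <- wald_ratio(h_frame(-0.5, -1.0, 0.2))
  expect_equal(neg$estimate, fit$estimate)
  expect_equal(neg$se, fit$se)
  expect_error(wald_ratio(h_frame(0, 1, 0.2)), "degenerate")
})

test_that("IVW pools ratios by inverse variance", {
  expect_equal(ivw(h_frame(c(1, 1), c(2, 2), c(0.5, 0.5)))$estimate, 2.0)
  fit <- ivw(h_frame(c(1, 1), c(1, 3), c(1, 1)))
  expect_equal(fit$estimate, 2.0)
  expect_equal(fit$se, sqrt(0.5), tolerance = 1e-12)
  # permutation symmetry
  h <- h_frame(c(0.3, -0.4, 0.6), c(0.1, 0.2, -0.3), c(0.1, 0.2, 0.15))
  expect_equal(ivw(h), ivw(h[c(3, 1, 2), ]))
  expect_error(ivw(h_frame(1, 1, 1)), "at least 2")
  # single-instrument IVW formula coincides with the Wald ratio
  h1 <- h_frame(0.4, 0.3, 0.1)
  r <- list(b = h1$beta_outcome / h1$beta_exposure,
            se = h1$se_outcome / abs(h1$beta_exposure))
  expect_equal(r$b, wald_ratio(h1)$estimate)
  expect_equal(r$se, wald_ratio(h1)$se)
})

test_that("weighted median interpolates the weighted 50th percentile", {
  # equal weights, odd count: the simple median
  h <- h_frame(c(1, 1, 1), c(1, 2, 9), c(0.5, 0.5, 0.5))
  expect_equal(weighted_median(h, n_boot = 0)$estimate, 2)
  # robustness: one outlier among nine concordant ratios
  h2 <- h_frame(rep(1, 10), c(rep(2, 9), 40), rep(0.5, 10))
  expect_lt(abs(weighted_median(h2, n_boot = 0)$estimate - 2), 0.01)
  expect_gt(abs(ivw(h2)$estimate - 2), 1)
  expect_error(weighted_median(h_frame(c(1, 1), c(1, 2), c(1, 1))),
               "at least 3")
  # bootstrap se is deterministic and leaves the caller's RNG untouched
  set.seed(99); before <- runif(1)
  set.seed(99)
  f1 <- weighted_median(h, n_boot = 200)
  expect_identical(runif(1), before)
  f2 <- weighted_median(h, n_boot = 200)
  expect_identical(f1, f2)
  expect_gt(f1$se, 0)
})

test_that("Cochran's Q quantifies ratio heterogeneity", {
  h <- h_frame(c(1, 1), c(2, 2), c(1, 1))
  q0 <- cochran_q(h)
  expect_equal(q0$q, 0)
  expect_equal(q0$p, 1)
  q <- cochran_q(h_frame(c(1, 1), c(1, 3), c(1, 1)))
  expect_equal(q$q, 2)
  expect_identical(q$df, 1L)
  expect_equal(q$p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(q$p, 0.1573, tolerance = 1e-3)
  h3 <- h_frame(c(0.3, 0.5, 0.7), c(0.1, 0.4, 0.2), c(0.1, 0.2, 0.15))
  expect_equal(cochran_q(h3), cochran_q(h3[3:1, ]))
  expect_error(cochran_q(h_frame(1, 1, 1)), "at least 2")
})

test_that("Egger regression recovers exact fits and flags pleiotropy", {
  # alpha = 0, no noise: intercept exactly 0
  bexp <- c(0.2, 0.4, 0.6, 0.8)
  h <- h_frame(bexp, 0.5 * bexp, rep(0.1, 4))
  expect_equal(suppressWarnings(egger_intercept(h))$intercept, 0,
               tolerance = 1e-12)
  # constant directional pleiotropy, no noise: intercept = 0.3 exactly
  h2 <- h_frame(bexp, 0.5 * bexp + 0.3, rep(0.1, 4))
  fit2 <- suppressWarnings(egger_intercept(h2))
  expect_equal(fit2$intercept, 0.3, tolerance = 1e-10)
  expect_equal(fit2$slope, 0.5, tolerance = 1e-10)
  expect_error(egger_intercept(h_frame(c(1, 2), c(1, 2), c(1, 1))),
               "at least 3")
  expect_error(egger_intercept(h_frame(c(1, 1, 1), c(1, 2, 3),
                                       c(1, 1, 1))), "collinear")
})

test_that("estimators match independent oracles on random instances", {
  set.seed(7)
  for (i in 1:400) {
    J <- sample(3:12, 1)
    h <- h_frame(runif(J, 0.1, 1) * sample(c(-1, 1), J, TRUE),
                 rnorm(J, 0, 0.5), runif(J, 0.05, 0.5),
                 runif(J, 0.02, 0.1))
    b <- h$beta_outcome / h$beta_exposure
    se_r <- h$se_outcome / abs(h$beta_exposure)
    o_ivw <- ivw_oracle(b, se_r)
    f_ivw <- ivw(h)
    expect_equal(f_ivw$estimate, o_ivw$estimate, tolerance = 1e-9)
    expect_equal(f_ivw$se, o_ivw$se, tolerance = 1e-9)
    expect_equal(weighted_median(h, n_boot = 0)$estimate,
                 wm_oracle(b, 1 / se_r^2), tolerance = 1e-9)
    o_egger <- egger_oracle(h$beta_exposure, h$beta_outcome,
                            1 / h$se_outcome^2)
    f_egger <- egger_intercept(h)
    expect_equal(f_egger$intercept, o_egger$intercept, tolerance = 1e-9)
    expect_equal(f_egger$se, o_egger$se, tolerance = 1e-9)
    q <- cochran_q(h, f_ivw$estimate)
    expect_equal(q$q, sum((b - f_ivw$estimate)^2 / se_r^2),
                 tolerance = 1e-9)
  }
})

test_that("greedy clumping respects the r2 ceiling and the p ranking", {
  # A keeps out nearby correlated B but not distant independent C
  set.seed(31)
  zA <- rbinom(400, 2, 0.3)
  zB <- ifelse(runif(400) < 0.85, zA, rbinom(400, 2, 0.3))
  zC <- rbinom(400, 2, 0.3)
  panel <- panel_from_dosage(cbind(A = zA, B = zB, C = zC),
                             pos = c(100L, 5000L, 10000000L))
  stopifnot(ld_r2(panel, "A", "B") > 0.5, ld_r2(panel, "A", "C") < 0.05)
  inst <- data.frame(snp_id = c("A", "B", "C"), pval = c(1e-8, 1e-5, 1e-4))
  expect_identical(clump_instruments(inst, panel), c("A", "C"))
  expect_identical(clump_instruments(inst[1, ], panel), "A")
  expect_identical(clump_instruments(inst[0, ], panel), character(0))
  # inside the window the empirical-r2 rule itself decides: with enough
  # reference individuals an independent SNP's estimated r2 clears 0.001
  set.seed(32)
  yA <- rbinom(20000, 2, 0.3)
  yD <- rbinom(20000, 2, 0.3)
  panel2 <- panel_from_dosage(cbind(A = yA, D = yD), pos = c(100L, 5000L))
  stopifnot(ld_r2(panel2, "A", "D") <= 0.001)
  inst2 <- data.frame(snp_id = c("A", "D"), pval = c(1e-8, 1e-4))
  expect_identical(clump_instruments(inst2, panel2), c("A", "D"))

  # random instances against the literal sorted-p greedy oracle
  for (i in 1:25) {
    n <- 20
    dos <- matrix(rbinom(200 * n, 2, 0.4), ncol = n,
                  dimnames = list(NULL, sprintf("s%02d", 1:n)))
    # induce some LD by copying columns with noise
    for (j in seq(2, n, by = 4)) {
      keep <- runif(200) < 0.9
      dos[, j] <- ifelse(keep, dos[, j - 1], dos[, j])
    }
    pan <- panel_from_dosage(dos)
    inst <- data.frame(snp_id = colnames(dos), pval = runif(n))
    r2 <- cor(dos)^2
    expect_identical(clump_instruments(inst, pan),
                     clump_oracle(inst$snp_id, inst$pval, r2))
  }
})

test_that("LD r2 identity, independence and perfect copies", {
  set.seed(17)
  a <- rbinom(1000, 2, 0.3)
  b <- rbinom(1000, 2, 0.4)
  panel <- panel_from_dosage(cbind(A = a, B = b, C = a, M = rep(1L, 1000)))
  expect_equal(ld_r2(panel, "A", "A"), 1.0)
  expect_equal(ld_r2(panel, "A", "C"), 1.0)
  expect_lt(ld_r2(panel, "A", "B"), 0.02)
  expect_error(ld_r2(panel, "A", "M"), "monomorphic")
  expect_error(ld_r2(panel, "A", "nope"), "not in the reference panel")
})
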