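test_that("instrument selection filters on the p column", {
  ss <- data.frame(snp = c("rs1", "rs2"), p = c(1e-9, 1e-3))
  expect_equal(select_instruments(ss)$snp, "rs1")
  expect_equal(nrow(select_instruments(ss, 1.0)), 2)
  expect_error(select_instruments(ss, 1e-12), "no instruments")
  expect_error(select_instruments(data.frame(snp = "rs1")), "`p` column")
})

sumstats_row <- function(snp, ea, oa, eaf, beta, se = 0.02) {
  data.frame(snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, p = 1e-9, n = 1e5, stringsAsFactors = FALSE)
}

test_that("harmonization aligns effects to the exposure's effect allele", {
  ex <- rbind(sumstats_row("rs1", "A", "G", 0.3, 0.1),
              sumstats_row("rs2", "C", "T", 0.2, 0.2),
              sumstats_row("rs3", "A", "T", 0.50, 0.1),
              sumstats_row("rs4", "A", "T", 0.10, 0.1),
              sumstats_row("rs5", "A", "G", 0.3, 0.1))
  ou <- rbind(sumstats_row("rs1", "A", "G", 0.3, 0.05),     # identical
              sumstats_row("rs2", "T", "C", 0.8, 0.3),      # swapped -> flip
              sumstats_row("rs3", "A", "T", 0.50, 0.1),     # palindromic, eaf 0.5
              sumstats_row("rs4", "A", "T", 0.10, 0.2),     # palindromic, clear eaf
              sumstats_row("rs5", "A", "C", 0.3, 0.1))      # irreconcilable
  h <- harmonize(ex, ou)
  expect_setequal(h$snp, c("rs1", "rs2", "rs4"))
  expect_equal(h$beta_y[h$snp == "rs1"], 0.05)
  expect_equal(h$beta_y[h$snp == "rs2"], -0.3)
  expect_equal(h$beta_y[h$snp == "rs4"], 0.2)
  expect_error(harmonize(ex, sumstats_row("rs9", "A", "G", 0.3, 0.1)),
               "no shared SNPs")
})

test_that("strand-complement alleles harmonize without a flip", {
  ex <- sumstats_row("rs1", "A", "G", 0.3, 0.1)
  ou <- sumstats_row("rs1", "T", "C", 0.3, 0.07)   # same SNP on other strand
  h <- harmonize(ex, ou)
  expect_equal(h$beta_y, 0.07)
})

test_that("IVW reproduces hand-computable cases", {
  inp <- data.frame(snp = c("a", "b"), beta_x = c(0.2, 0.2),
                    se_x = 0.01, beta_y = c(0.1, 0.1), se_y = 0.02)
  r <- mr_ivw(inp)
  expect_equal(r$estimate, 0.5)
  inp2 <- data.frame(snp = c("a", "b"), beta_x = c(1, 2), se_x = 0.01,
                     beta_y = c(0.5, 1.0), se_y = 0.02)
  r2 <- mr_ivw(inp2)
  expect_equal(r2$estimate, 0.5)
  expect_equal(r2$q_stat, 0)
  expect_equal(r2$or_, exp(r2$estimate))
  expect_error(mr_ivw(inp[1, ]), "at least 2")
})

test_that("IVW equals the weighted least-squares slope through the origin", {
  for (s in 1:100) {
    inp <- rand_mr_input(10, s)
    r <- mr_ivw(inp)
    o <- wls_origin_oracle(inp)
    expect_equal(r$estimate, o$estimate, tolerance = 1e-10)
    expect_equal(r$se, o$se, tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the half-weight percentile", {
  inp <- data.frame(snp = letters[1:3], beta_x = c(1, 1, 1), se_x = 0.01,
                    beta_y = c(0.1, 0.5, 0.9), se_y = 0.02)
  expect_equal(mr_weighted_median(inp, n_boot = 10)$estimate, 0.5)
  inp$beta_y <- c(0.4, 0.4, 0.4)
  expect_equal(mr_weighted_median(inp, n_boot = 10)$estimate, 0.4)
  expect_error(mr_weighted_median(inp[1:2, ]), "at least 3")
  inp$beta_x[1] <- 0
  expect_error(mr_weighted_median(inp), "zero exposure effect")
})

test_that("weighted median matches the direct cumulative-weight oracle", {
  for (s in 1:100) {
    inp <- rand_mr_input(5, 1000 + s)
    est <- mr_weighted_median(inp, n_boot = 2)$estimate
    r <- inp$beta_y / inp$beta_x
    w <- (inp$beta_x / inp$se_y)^2
    expect_equal(est, weighted_median_oracle(r, w), tolerance = 1e-10)
  }
})

test_that("weighted median is invariant to ordering and joint sign flips", {
  inp <- rand_mr_input(9, 77)
  est <- mr_weighted_median(inp, n_boot = 50, seed = 4)$estimate
  perm <- inp[sample(9), ]
  expect_equal(mr_weighted_median(perm, n_boot = 50, seed = 4)$estimate, est)
  flip <- inp
  flip$beta_x[3] <- -flip$beta_x[3]
  flip$beta_y[3] <- -flip$beta_y[3]
  expect_equal(mr_weighted_median(flip, n_boot = 50, seed = 4)$estimate, est)
})

test_that("Egger regression recovers an exact affine relation", {
  inp <- data.frame(snp = letters[1:5], beta_x = c(0.05, 0.1, 0.15, 0.2, 0.25),
                    se_x = 0.01, se_y = 0.02)
  inp$beta_y <- 0.1 + 0.4 * inp$beta_x
  r <- mr_egger(inp)
  expect_equal(r$estimate[r$method == "egger_slope"], 0.4, tolerance = 1e-10)
  expect_equal(r$estimate[r$method == "egger_intercept"], 0.1, tolerance = 1e-10)
  expect_error(mr_egger(inp[1:2, ]), "at least 3")
})

test_that("Egger slope recovers the causal effect under balanced pleiotropy", {
  est <- vapply(1:100, function(s) {
    ss <- generate_summary_stats(sumstats_spec(
      n_snps = 50, causal_effect = -0.3, invalid_fraction = 1,
      pleiotropy_mean = 0, pleiotropy_sd = 0.01, seed = 2000 + s))
    inp <- harmonize(select_instruments(ss$exposure), ss$outcome)
    r <- mr_egger(inp)
    c(r$estimate[r$method == "egger_slope"],
      within2se = abs(r$estimate[r$method == "egger_intercept"]) <
        2 * r$se[r$method == "egger_intercept"])
  }, c(0, 0))
  expect_lt(abs(mean(est[1, ]) + 0.3), 2 * sd(est[1, ]) / 10)
  expect_gte(sum(est[2, ]), 93)    # intercept covers 0
})

test_that("Q-contribution pruning removes exactly a planted outlier", {
  inp <- rand_mr_input(10, 55)
  inp$beta_y <- 0.3 * inp$beta_x + rnorm(10, 0, 0.001)
  inp$se_y <- 0.01
  clean <- remove_outliers(inp)
  expect_equal(attr(clean, "outliers_removed"), character(0))
  bad <- inp
  bad$beta_y[4] <- 0.3 * bad$beta_x[4] + 10 * bad$se_y[4]   # 10-SD deviant
  pruned <- remove_outliers(bad)
  expect_equal(attr(pruned, "outliers_removed"), bad$snp[4])
  expect_equal(nrow(pruned), 9)
  expect_lte(mr_ivw(pruned)$q_stat, mr_ivw(bad)$q_stat)
})

test_that("estimators are equivariant under exposure rescaling", {
  inp <- rand_mr_input(8, 91)
  sc <- inp
  sc$beta_x <- 2 * sc$beta_x
  sc$se_x <- 2 * sc$se_x
  expect_equal(mr_ivw(sc)$estimate, mr_ivw(inp)$estimate / 2, tolerance = 1e-12)
  expect_equal(mr_weighted_median(sc, n_boot = 5)$estimate,
               mr_weighted_median(inp, n_boot = 5)$estimate / 2,
               tolerance = 1e-12)
  e1 <- mr_egger(inp)
  e2 <- mr_egger(sc)
  expect_equal(e2$estimate[e2$method == "egger_slope"],
               e1$estimate[e1$method == "egger_slope"] / 2, tolerance = 1e-12)
})

test_that("the MR pipeline only supports protective effects", {
  ss <- generate_summary_stats(sumstats_spec(n_snps = 50, causal_effect = 0.3,
                                             seed = 12))
  res <- run_mr(ss$exposure, ss$outcome)
  expect_false(attr(res, "mr_supported"))     # direction filter: OR > 1
  expect_gt(res$p[res$method == "ivw"], 0)    # significant but risk-directed
  ss2 <- generate_summary_stats(sumstats_spec(n_snps = 50, causal_effect = -0.3,
                                              seed = 12))
  res2 <- run_mr(ss2$exposure, ss2$outcome)
  expect_true(attr(res2, "mr_supported"))
  expect_true(attr(res2, "dual_support"))
})

test_that("a strongly powered synthetic exposure retains nearly all instruments", {
  kept <- vapply(1:40, function(s) {
    ss <- generate_summary_stats(sumstats_spec(n_snps = 50, n_exposure = 1e5,
                                               seed = 3000 + s))
    nrow(select_instruments(ss$exposure))
  }, 0)
  expect_gte(mean(kept >= 45), 0.95)
})
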