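test_that("dichotomization at the mean is inclusive on the high side", {
  expect_equal(dichotomize_by_mean(c(-1, 1)), c("low", "high"))
  expect_equal(dichotomize_by_mean(c(1, 0, 2)), c("high", "low", "high"))
  sym <- c(-2, -1, 1, 2)
  expect_equal(sum(dichotomize_by_mean(sym) == "high"), 2)
  expect_error(dichotomize_by_mean(c(1, NA)), "non-missing")
})

test_that("percentile prevalence curves count cases exactly", {
  score <- seq_len(200)
  status <- rep(0, 200)
  status[c(1:5, 150:200)] <- 1
  cv <- prevalence_by_percentile(score, status, n_bins = 2)
  expect_equal(cv$n, c(100, 100))
  expect_equal(cv$k, c(sum(status[1:100]), sum(status[101:200])))
  expect_equal(cv$prevalence, cv$k / cv$n)
  # constant status -> flat curve at 1
  flat <- prevalence_by_percentile(rnorm(300), rep(1, 300), n_bins = 10)
  expect_true(all(flat$prevalence == 1))
  expect_error(prevalence_by_percentile(rnorm(50), rep(0, 50), 100),
               "fewer individuals")
})

test_that("curves conserve group prevalence and balance bin sizes", {
  withr::with_seed(61, {
    score <- rnorm(1003)
    status <- rbinom(1003, 1, 0.2)
    cv <- prevalence_by_percentile(score, status, 100)
    expect_equal(sum(cv$n), 1003)
    expect_true(all(abs(cv$n - 1003 / 100) <= 1))
    expect_equal(sum(cv$k) / sum(cv$n), mean(status))
    expect_equal(sum(cv$prevalence * cv$n) / sum(cv$n), mean(status))
  })
})

test_that("curves are invariant under strictly monotone score transforms", {
  withr::with_seed(62, {
    score <- rnorm(500)
    status <- rbinom(500, 1, plogis(-2 + score))
    a <- prevalence_by_percentile(score, status, 50)
    b <- prevalence_by_percentile(exp(3 * score), status, 50)
    expect_equal(a, b)
    expect_equal(tail_difference(a, 0.04), tail_difference(b, 0.04))
  })
})

test_that("tail differences follow direct arithmetic on the tail bins", {
  p <- c(0.01, 0.02, rep(0.05, 96), 0.40, 0.50)
  cv <- toy_curve(p, n_per_bin = rep(100, 100))
  expect_equal(tail_difference(cv),
               (40 + 50) / 200 - (1 + 2) / 200)
  flat <- toy_curve(rep(0.3, 100), rep(50, 100))
  expect_equal(tail_difference(flat), 0)
  inc <- toy_curve(seq(0.01, 0.99, length.out = 100), rep(100, 100))
  expect_gt(tail_difference(inc), 0)
  expect_error(tail_difference(cv, 0.001), "tail_fraction")
})

test_that("observed delta is the signed difference of tail contrasts", {
  a <- toy_curve(seq(0.05, 0.45, length.out = 100), rep(100, 100))
  b <- toy_curve(seq(0.10, 0.20, length.out = 100), rep(100, 100))
  expect_equal(delta_observed(a, a), 0)
  expect_gt(delta_observed(a, b), 0)                    # a steeper
  expect_equal(delta_observed(b, a), -delta_observed(a, b))
  expect_error(delta_observed(a, toy_curve(rep(0.1, 50), rep(100, 50))),
               "binning")
})

test_that("expected deltas are seeded, self-consistent, and match the binomial
           variance oracle", {
  pa <- plogis(-2.5 + 0.02 * (1:100))
  pb <- plogis(-2.2 + 0.005 * (1:100))
  na <- rep(400, 100)
  withr::with_seed(63, {
    a <- toy_curve(pa, na)
    a$k <- rbinom(100, na, pa)
    a$prevalence <- a$k / a$n
    b <- toy_curve(pb, na)
    b$k <- rbinom(100, na, pb)
    b$prevalence <- b$k / b$n
  })
  e1 <- delta_expected(a, b, n_iterations = 10, seed = 5)
  expect_identical(e1, delta_expected(a, b, n_iterations = 10, seed = 5))
  big <- delta_expected(a, b, n_iterations = 1000, seed = 6)
  obs <- delta_observed(a, b)
  # the observed delta is one draw from (approximately) the simulated
  # distribution, so it sits within ~2 of its SDs of the simulation mean
  expect_lt(abs(mean(big) - obs), 2 * sd(big) * (1 + 1 / sqrt(1000)))
  # binomial propagation: Var(delta) summed over the fitted tail bins
  fit_p <- function(cv) fitted(glm(cbind(k, n - k) ~ bin,
                                   family = binomial(), data = cv))
  var_tail <- function(p, n) {
    idx <- c(1, 2, 99, 100)
    sum(p[idx] * (1 - p[idx]) * n[idx]) / (2 * n[1])^2
  }
  v_oracle <- var_tail(fit_p(a), a$n) + var_tail(fit_p(b), b$n)
  expect_lt(abs(sd(big) - sqrt(v_oracle)) / sqrt(v_oracle), 0.1)
  degenerate <- toy_curve(rep(0, 100), rep(10, 100))
  expect_error(delta_expected(degenerate, b), "degenerate")
})

test_that("delta departure is zero at equality and negative for excess deviation", {
  expect_equal(delta_departure(0.05, c(0.04, 0.05, 0.06)), 0)
  expect_lt(delta_departure(0.5, c(0.04, 0.05, 0.06)), 0)
  expect_gt(delta_departure(0.001, c(0.04, 0.05, 0.06)), 0)
  expect_equal(delta_departure(-0.05, c(0.04, 0.05, 0.06)), 0)  # |observed|
  expect_error(delta_departure(0.1, 0.2), ">= 2")
  expect_error(delta_departure(0.1, c(0.2, 0.2)), "zero SD")
})

test_that("the canalization analysis wires strata, curves and deltas together", {
  sp <- cohort_spec(20000, seed = 71,
                    metabolites = list(metabolite_spec("m1")),
                    diseases = list(disease_spec("d1", baseline_prevalence = 0.15,
                                                 beta_metabolite = -0.2,
                                                 beta_obesity = 0.4,
                                                 interaction_mode = "pgs",
                                                 interaction_with = "bmi_obese")))
  co <- prepare_cohort(generate_cohort(sp))
  res <- canalization_analysis(co$pgs_m1, co$status_d1,
                               ifelse(co$bmi_obese == 1, "obese", "non_obese"),
                               "obese", n_iterations = 10, seed = 3)
  expect_true(is.finite(res$delta_departure))
  expect_gte(res$delta_expected_sd, 0)
  expect_equal(res$n_a + res$n_b, 20000)
  res2 <- canalization_analysis(co$pgs_m1, co$status_d1,
                                ifelse(co$bmi_obese == 1, "obese", "non_obese"),
                                "obese", n_iterations = 10, seed = 3)
  expect_identical(res, res2)
})

test_that("the comparison grid enumerates disease x measure x metabolite once", {
  grid <- canalization_comparisons(c("d1", "d2"), c("m1", "m2", "m3"))
  expect_equal(nrow(grid), 2 * 2 * 3)
  expect_equal(anyDuplicated(grid), 0)
})
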