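test_that("QC-filtered median collapse follows the removal rule", {
  expect_equal(collapse_measurements(3.1, FALSE), 3.1)
  expect_equal(collapse_measurements(c(1, 2, 9), c(FALSE, FALSE, TRUE)), 1.5)
  expect_true(is.na(collapse_measurements(1.0, TRUE)))
  expect_error(collapse_measurements(1:3, c(FALSE, TRUE)), "equal length")
  # permutation invariance
  v <- c(2.2, 0.7, 5.1, 3.3)
  f <- c(FALSE, TRUE, FALSE, FALSE)
  p <- c(3, 1, 4, 2)
  expect_equal(collapse_measurements(v, f), collapse_measurements(v[p], f[p]))
})

test_that("Z-scoring normalizes, propagates missingness, and is affine-invariant", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z[3], 1.0)          # sample SD is 1
  expect_equal(z[2], 0.0)          # x = mean
  x <- rnorm(50, 10, 3)
  zx <- zscore(x)
  expect_lt(abs(mean(zx)), 1e-12)
  expect_lt(abs(sd(zx) - 1), 1e-12)
  expect_equal(zscore(5 + 2 * x), zx, tolerance = 1e-12)
  x[7] <- NA
  expect_true(is.na(zscore(x)[7]))
  expect_error(zscore(rep(1, 5)), "variance")
  expect_error(zscore(c(1, NA)), "non-missing")
})

test_that("waist-to-hip ratio and obesity cutoffs behave at the boundaries", {
  expect_equal(compute_whr(80, 100), 0.8)
  expect_equal(compute_whr(95, 95), 1.0)
  expect_error(compute_whr(80, 0), "positive")
  # strict cutoffs: the boundary value is non-obese
  expect_equal(classify_obesity("bmi", 30.0), 0L)
  expect_equal(classify_obesity("bmi", 30.01), 1L)
  expect_equal(classify_obesity("whr", 0.86, "female"), 1L)
  expect_equal(classify_obesity("whr", 0.85, "female"), 0L)
  expect_equal(classify_obesity("whr", 0.95, "male"), 0L)
  expect_equal(classify_obesity("whr", 0.96, 1L), 1L)
  expect_error(classify_obesity("whr", 0.9), "sex")
  expect_error(classify_obesity("whr", 0.9, "unknown"), "sex label")
})

test_that("configured obesity prevalences reproduce the excess of WHR-obese women", {
  sp <- cohort_spec(20000, seed = 5)
  co <- prepare_cohort(generate_cohort(sp))
  f <- co$sex == 0
  expect_gt(mean(co$whr_obese[f]), mean(co$whr_obese[!f]))
  expect_gt(mean(co$whr_obese[f]), mean(co$bmi_obese[f]))
})

test_that("minimum-case filter keeps diseases at exactly the threshold", {
  status <- data.frame(status_a = rep(c(1, 0), c(49, 151)),
                       status_b = rep(c(1, 0), c(50, 150)),
                       status_c = rep(0, 200))
  expect_identical(min_case_filter(status), "b")
  expect_identical(min_case_filter(status, min_cases = 10), c("a", "b"))
})

test_that("allele-sum scoring matches direct arithmetic and chunks additively", {
  expect_equal(score_individuals(matrix(0, 3, 1, dimnames = list(NULL, "rs1")),
                                 data.frame(snp = "rs1", effect_allele = "A",
                                            weight = 0.7)),
               c(0, 0, 0))
  expect_equal(score_individuals(matrix(2, 1, 1, dimnames = list(NULL, "rs1")),
                                 data.frame(snp = "rs1", effect_allele = "A",
                                            weight = 0.5)),
               1.0)
  withr::with_seed(21, {
    dos <- matrix(sample(0:2, 200, TRUE), 20, 10,
                  dimnames = list(NULL, sprintf("rs%d", 1:10)))
    w <- data.frame(snp = sprintf("rs%d", 1:10), effect_allele = "A",
                    weight = rnorm(10))
    chr <- rep(1:3, c(4, 3, 3))
    expect_equal(score_individuals(dos, w, chromosome = chr),
                 score_individuals(dos, w), tolerance = 1e-12)
  })
})

test_that("scoring flips weights for swapped alleles and drops mismatches", {
  dos <- matrix(c(2, 1, 0, 1, 2, 0), 3, 2,
                dimnames = list(NULL, c("rs1", "rs2")))
  w <- data.frame(snp = c("rs1", "rs2"), effect_allele = c("A", "C"),
                  weight = c(1, 1))
  # rs1 dosage counts A (match); rs2 dosage counts T with other allele C
  # (weight effect allele C is the other allele -> sign flip)
  da <- data.frame(snp = c("rs1", "rs2"), dosage_allele = c("A", "T"),
                   other_allele = c("G", "C"))
  expect_equal(score_individuals(dos, w, dosage_alleles = da),
               dos[, 1] - dos[, 2])
  # weight allele C among an A/T dosage pair -> dropped with a warning
  da2 <- data.frame(snp = c("rs1", "rs2"), dosage_allele = c("A", "A"),
                    other_allele = c("G", "T"))
  expect_warning(s <- score_individuals(dos, w, dosage_alleles = da2),
                 "unresolvable")
  expect_equal(s, dos[, 1])
  expect_error(score_individuals(dos * 2, w), "\\[0, 2\\]")
})

test_that("prepare_cohort collapses repeats and reports QC removals", {
  sp <- cohort_spec(300, seed = 2,
                    metabolites = list(metabolite_spec("m1", n_repeats = 3,
                                                       qc_warning_rate = 0.3)))
  co <- generate_cohort(sp)
  expect_message(prep <- prepare_cohort(co, verbose = TRUE), "flagged")
  expect_true(all(c("m1_level", "m1_z", "whr", "bmi_z", "whr_z",
                    "bmi_obese", "whr_obese") %in% names(prep)))
  i <- which(!is.na(prep$m1_level))[1]
  vals <- unlist(co[i, sprintf("m1_rep_%d", 1:3)])
  flags <- unlist(co[i, sprintf("m1_qc_%d", 1:3)])
  expect_equal(prep$m1_level[i], collapse_measurements(vals, flags))
})
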