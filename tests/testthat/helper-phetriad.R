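# Shared fixtures and independent oracles for the test suite.

# Random harmonized MR input (already allele-aligned).
rand_mr_input <- function(k, seed) {
  withr::with_seed(seed, {
    data.frame(snp = sprintf("rs%03d", seq_len(k)),
               eaf = runif(k, 0.1, 0.5),
               beta_x = runif(k, 0.05, 0.2) * sample(c(-1, 1), k, TRUE),
               se_x = runif(k, 0.005, 0.02),
               beta_y = rnorm(k, 0, 0.05),
               se_y = runif(k, 0.01, 0.05),
               stringsAsFactors = FALSE)
  })
}

# Weighted least squares through the origin: the independent check that the
# fixed-effect IVW estimate is exactly this regression slope.
wls_origin_oracle <- function(input) {
  fit <- stats::lm(beta_y ~ 0 + beta_x, data = input, weights = input$se_y^-2)
  s <- summary(fit)
  list(estimate = unname(coef(fit)[1]),
       se = unname(s$coefficients[1, 2] / s$sigma))
}

# Direct cumulative-weight interpolation for the weighted median, written as
# an explicit scan over the ordered ratios.
weighted_median_oracle <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  s <- 0
  prev_m <- NA_real_
  prev_r <- NA_real_
  for (j in seq_along(r)) {
    m_j <- s + w[j] / 2
    if (m_j >= 0.5) {
      if (j == 1L) return(r[1])
      return(prev_r + (0.5 - prev_m) / (m_j - prev_m) * (r[j] - prev_r))
    }
    s <- s + w[j]
    prev_m <- m_j
    prev_r <- r[j]
  }
  r[length(r)]
}

# Exhaustive hypergeometric tail sum for the two-sided Fisher exact p-value
# of the 2x2 table rbind(c(a, b), c(c, d)).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n_ <- c + d
  k <- a + c
  lo <- max(0, k - n_)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_, k)
  pobs <- stats::dhyper(a, m, n_, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Tiny two-stratum cohort builder used by canalization tests.
toy_curve <- function(p_per_bin, n_per_bin) {
  k <- round(p_per_bin * n_per_bin)
  structure(data.frame(bin = seq_along(p_per_bin), n = n_per_bin, k = k,
                       prevalence = k / n_per_bin),
            class = c("prevalence_curve", "data.frame"))
}
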