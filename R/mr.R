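#' Select genetic instruments from exposure summary statistics
#'
#' @param exposure Summary-statistics data.frame with a `p` column.
#' @param p_threshold Inclusion threshold (default genome-wide significance,
#'   5e-8); rows with `p < p_threshold` are kept.
#' @return The filtered summary statistics.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8) {
  if (!"p" %in% names(exposure)) stop("exposure lacks a `p` column", call. = FALSE)
  out <- exposure[exposure$p < p_threshold, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no instruments reach the selection threshold", call. = FALSE)
  }
  out
}

is_palindromic <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins the two tables on SNP id and aligns every effect to the
#' exposure's effect allele: when the outcome's effect allele equals the
#' exposure's other allele (directly or via strand complement), the outcome
#' beta sign and frequency are flipped. Palindromic SNPs (A/T or C/G) whose
#' exposure frequency lies in [0.42, 0.58] are dropped as strand-ambiguous;
#' SNPs whose alleles cannot be reconciled are dropped too.
#'
#' @param exposure,outcome Summary-statistics data.frames (columns `snp,
#'   effect_allele, other_allele, eaf, beta, se, p, n`).
#' @param ambiguous_eaf_range Frequency window treated as unresolvable for
#'   palindromic SNPs.
#' @return Data.frame of harmonized instruments: `snp, eaf, beta_x, se_x,
#'   beta_y, se_y`.
#' @export
harmonize <- function(exposure, outcome, ambiguous_eaf_range = c(0.42, 0.58)) {
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0L) stop("no shared SNPs between exposure and outcome",
                                 call. = FALSE)
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  same <- (ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele) |
    (ou$effect_allele == comp[ex$effect_allele] & ou$other_allele == comp[ex$other_allele])
  swapped <- (ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele) |
    (ou$effect_allele == comp[ex$other_allele] & ou$other_allele == comp[ex$effect_allele])
  palin <- is_palindromic(ex$effect_allele, ex$other_allele)
  ambiguous <- palin & ex$eaf >= ambiguous_eaf_range[1] & ex$eaf <= ambiguous_eaf_range[2]

  keep <- (same | swapped) & !ambiguous
  beta_y <- ifelse(swapped & !same, -ou$beta, ou$beta)
  data.frame(snp = shared[keep], eaf = ex$eaf[keep],
             beta_x = ex$beta[keep], se_x = ex$se[keep],
             beta_y = beta_y[keep], se_y = ou$se[keep],
             stringsAsFactors = FALSE)
}

mr_result <- function(method, estimate, se, n_snps, q_stat = NA_real_,
                      outliers_removed = character(0)) {
  p <- max(2 * stats::pnorm(-abs(estimate / se)), .Machine$double.xmin)
  data.frame(method = method, estimate = estimate, se = se, p = p,
             or_ = exp(estimate), ci_low = exp(estimate - 1.96 * se),
             ci_high = exp(estimate + 1.96 * se), n_snps = n_snps,
             q_stat = q_stat,
             outliers_removed = paste(outliers_removed, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect IVW: with weights \eqn{w_j = se_{yj}^{-2}}, the estimate is
#' \eqn{\sum w_j \beta_{xj}\beta_{yj} / \sum w_j \beta_{xj}^2} with
#' \eqn{se = (\sum w_j \beta_{xj}^2)^{-1/2}}; this is exactly the
#' \eqn{se_y^{-2}}-weighted least-squares slope of outcome on exposure
#' effects through the origin. Cochran's Q,
#' \eqn{\sum w_j (\beta_{yj} - \hat\beta \beta_{xj})^2}, is reported as the
#' heterogeneity statistic.
#'
#' @param input Harmonized instruments (see [harmonize()]), >= 2 rows.
#' @return One-row MR result data.frame.
#' @export
mr_ivw <- function(input) {
  if (nrow(input) < 2L) stop("IVW needs at least 2 instruments", call. = FALSE)
  w <- input$se_y^-2
  denom <- sum(w * input$beta_x^2)
  est <- sum(w * input$beta_x * input$beta_y) / denom
  se <- sqrt(1 / denom)
  q <- sum(w * (input$beta_y - est * input$beta_x)^2)
  mr_result("ivw", est, se, nrow(input), q_stat = q)
}

# Weighted median of values `x` with weights `w`: the percentile-interpolated
# point where the cumulative weight crosses one half.
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(x[1])
  if (s[length(s)] <= 0.5) return(x[length(s)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' Takes per-instrument ratio estimates \eqn{r_j = \beta_{yj}/\beta_{xj}}
#' with weights \eqn{w_j = (\beta_{xj}/se_{yj})^2} (inverse variance of the
#' ratio) and returns the weight-0.5 percentile with linear interpolation.
#' Consistent when at least half the total weight comes from valid
#' instruments. The standard error is estimated by a seeded parametric
#' bootstrap resampling `beta_x` and `beta_y` from their sampling
#' distributions.
#'
#' @param input Harmonized instruments, >= 3 rows, all `beta_x != 0`.
#' @param n_boot Bootstrap draws for the SE (default 1000).
#' @param seed Seed for the bootstrap.
#' @return One-row MR result data.frame.
#' @export
mr_weighted_median <- function(input, n_boot = 1000, seed = 1L) {
  if (nrow(input) < 3L) stop("weighted median needs at least 3 instruments",
                             call. = FALSE)
  if (any(input$beta_x == 0)) stop("zero exposure effect among instruments",
                                   call. = FALSE)
  r <- input$beta_y / input$beta_x
  w <- (input$beta_x / input$se_y)^2
  est <- weighted_median_point(r, w)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(input), input$beta_x, input$se_x)
      by <- stats::rnorm(nrow(input), input$beta_y, input$se_y)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], (bx[ok] / input$se_y[ok])^2)
    }, 0)
  })
  mr_result("weighted_median", est, stats::sd(boot), nrow(input))
}

#' MR-Egger regression
#'
#' Weighted (\eqn{se_y^{-2}}) linear regression of outcome on exposure
#' effects with an intercept, after orienting all exposure effects to be
#' non-negative. The intercept estimates directional pleiotropy; the slope
#' is the pleiotropy-adjusted causal effect. Standard errors use the usual
#' residual-variance estimate of weighted least squares.
#'
#' @param input Harmonized instruments, >= 3 rows.
#' @return Two-row MR result data.frame (`egger_slope`, `egger_intercept`).
#' @export
mr_egger <- function(input) {
  if (nrow(input) < 3L) stop("Egger needs at least 3 instruments", call. = FALSE)
  flip <- sign(input$beta_x) < 0
  bx <- abs(input$beta_x)
  by <- ifelse(flip, -input$beta_y, input$beta_y)
  fit <- stats::lm(by ~ bx, weights = input$se_y^-2)
  cf <- summary(fit)$coefficients
  rbind(mr_result("egger_slope", cf["bx", 1], cf["bx", 2], nrow(input)),
        mr_result("egger_intercept", cf["(Intercept)", 1], cf["(Intercept)", 2],
                  nrow(input)))
}

#' Cochran's-Q instrument outlier removal
#'
#' Iteratively refits the IVW model and removes the instrument with the
#' largest per-SNP Q contribution, as long as that contribution exceeds the
#' upper-`alpha` chi-square(1) quantile and at least 3 instruments would
#' remain. The default `alpha` is Bonferroni-corrected per round
#' (0.05 / number of instruments).
#'
#' @param input Harmonized instruments, >= 3 rows.
#' @param alpha Per-instrument significance level for the Q contribution;
#'   default `0.05 / nrow(input)`.
#' @return `input` with outlying rows removed; removed SNP ids in the
#'   `outliers_removed` attribute.
#' @export
remove_outliers <- function(input, alpha = NULL) {
  removed <- character(0)
  if (nrow(input) < 3L) {
    attr(input, "outliers_removed") <- removed
    return(input)
  }
  alpha <- alpha %||% (0.05 / nrow(input))
  crit <- stats::qchisq(1 - alpha, df = 1)
  repeat {
    if (nrow(input) <= 3L) break
    w <- input$se_y^-2
    est <- sum(w * input$beta_x * input$beta_y) / sum(w * input$beta_x^2)
    qj <- w * (input$beta_y - est * input$beta_x)^2
    worst <- which.max(qj)
    if (qj[worst] <= crit) break
    removed <- c(removed, input$snp[worst])
    input <- input[-worst, , drop = FALSE]
  }
  attr(input, "outliers_removed") <- removed
  input
}

#' Two-sample Mendelian randomization for one exposure-outcome pair
#'
#' Full pipeline: instrument selection at `p_threshold`, allele
#' harmonization, Cochran's-Q outlier removal, then IVW (primary), weighted
#' median and Egger. The pair is flagged `mr_supported` when the IVW
#' estimate is nominally significant (`p < mr_alpha`) AND protective
#' (OR < 1) — the direction filter applied because the triangulated
#' associations under study are protective — and `dual_support` when the
#' weighted median is also nominally significant.
#'
#' @param exposure,outcome Summary-statistics data.frames.
#' @param p_threshold Instrument selection threshold (default 5e-8).
#' @param mr_alpha Nominal significance level for support flags (default
#'   0.05).
#' @param outlier_alpha Passed to [remove_outliers()] (default Bonferroni
#'   per round).
#' @param wm_seed Seed for the weighted-median bootstrap.
#' @return Data.frame with one row per method plus attributes
#'   `mr_supported`, `dual_support`, `outliers_removed`, `n_instruments`.
#' @export
run_mr <- function(exposure, outcome, p_threshold = 5e-8, mr_alpha = 0.05,
                   outlier_alpha = NULL, wm_seed = 1L) {
  inst <- select_instruments(exposure, p_threshold)
  input <- harmonize(inst, outcome)
  input <- remove_outliers(input, alpha = outlier_alpha)
  removed <- attr(input, "outliers_removed")
  res <- mr_ivw(input)
  if (nrow(input) >= 3L) {
    res <- rbind(res, mr_weighted_median(input, seed = wm_seed), mr_egger(input))
  }
  res$outliers_removed <- paste(removed, collapse = ",")
  ivw <- res[res$method == "ivw", ]
  wm <- res[res$method == "weighted_median", ]
  attr(res, "mr_supported") <- ivw$p < mr_alpha && ivw$or_ < 1
  attr(res, "dual_support") <- attr(res, "mr_supported") &&
    nrow(wm) == 1L && wm$p < mr_alpha
  attr(res, "outliers_removed") <- removed
  attr(res, "n_instruments") <- nrow(input)
  res
}
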