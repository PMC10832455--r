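#' Dichotomize standardized levels at their mean
#'
#' @param z Numeric vector (typically Z-scores); values at or above the mean
#'   are labelled `"high"`, below it `"low"` (the boundary is inclusive on
#'   the high side).
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
dichotomize_by_mean <- function(z) {
  if (anyNA(z)) stop("`z` must be non-missing", call. = FALSE)
  ifelse(z >= mean(z), "high", "low")
}

#' Disease prevalence across score percentiles
#'
#' Ranks individuals by a polygenic score (stable ties: earlier input rows
#' get the lower rank), splits them into `n_bins` near-equal ordered groups
#' (sizes differ by at most 1), and computes the case fraction per bin.
#'
#' @param score Numeric score vector.
#' @param status Binary 0/1 disease status, same length.
#' @param n_bins Number of percentile bins (default 100).
#' @return Data.frame of class `prevalence_curve`: `bin, n, k, prevalence`.
#' @export
prevalence_by_percentile <- function(score, status, n_bins = 100) {
  stopifnot(length(score) == length(status))
  n <- length(score)
  if (n < n_bins) stop("fewer individuals than bins", call. = FALSE)
  ord <- order(score)  # stable: ties keep input order
  status <- as.numeric(status)[ord]
  base <- n %/% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, n %% n_bins), rep(0L, n_bins - n %% n_bins))
  bin <- rep(seq_len(n_bins), times = sizes)
  k <- tapply(status, bin, sum)
  out <- data.frame(bin = seq_len(n_bins), n = sizes, k = as.numeric(k),
                    prevalence = as.numeric(k) / sizes)
  class(out) <- c("prevalence_curve", "data.frame")
  out
}

#' Tail prevalence contrast of a percentile curve
#'
#' Case-weighted mean prevalence over the top `ceiling(tail_fraction *
#' n_bins)` bins minus that over the bottom bins (pooled cases over pooled
#' individuals within each tail).
#'
#' @param curve A [prevalence_by_percentile()] curve.
#' @param tail_fraction Fraction of bins in each tail (default 0.02, i.e.
#'   2 bins of 100).
#' @return Numeric tail difference (top minus bottom).
#' @export
tail_difference <- function(curve, tail_fraction = 0.02) {
  n_bins <- nrow(curve)
  if (tail_fraction * n_bins < 1) {
    stop("tail_fraction too small for the binning", call. = FALSE)
  }
  m <- ceiling(tail_fraction * n_bins)
  if (2L * m > n_bins) stop("tails overlap: too few bins", call. = FALSE)
  top <- curve[(n_bins - m + 1L):n_bins, ]
  bot <- curve[1:m, ]
  sum(top$k) / sum(top$n) - sum(bot$k) / sum(bot$n)
}

#' Observed delta between two strata
#'
#' Signed difference of the tail contrasts of two percentile curves built on
#' the same binning: stratum a (obese, or low-metabolite) minus stratum b
#' (non-obese, or high-metabolite).
#'
#' @param curve_a,curve_b Prevalence curves with the same number of bins.
#' @param tail_fraction Passed to [tail_difference()].
#' @return Signed prevalence difference.
#' @export
delta_observed <- function(curve_a, curve_b, tail_fraction = 0.02) {
  if (nrow(curve_a) != nrow(curve_b)) stop("curves must share binning", call. = FALSE)
  tail_difference(curve_a, tail_fraction) - tail_difference(curve_b, tail_fraction)
}

fit_expected_prevalence <- function(curve, model = c("logistic", "linear")) {
  model <- match.arg(model)
  if (all(curve$k == 0) || all(curve$k == curve$n)) {
    stop("degenerate stratum: all controls or all cases", call. = FALSE)
  }
  if (model == "logistic") {
    fit <- stats::glm(cbind(k, n - k) ~ bin, family = stats::binomial(),
                      data = curve)
    as.numeric(stats::fitted(fit))
  } else {
    fit <- stats::lm(prevalence ~ bin, data = curve)
    pmin(pmax(as.numeric(stats::fitted(fit)), 0), 1)
  }
}

#' Simulated expected deltas under a smooth prevalence model
#'
#' Fits an expected prevalence per bin for each stratum (by default a
#' logistic regression of case counts on the percentile index; a
#' linear-in-percentile alternative is available), then, per iteration,
#' redraws each bin's case count as Binomial(n_b, fitted_b), rebuilds both
#' curves and records the simulated [delta_observed()]. The spread of these
#' values is the sampling expectation against which the observed delta is
#' judged.
#'
#' @param curve_a,curve_b Prevalence curves (same binning).
#' @param n_iterations Number of simulation iterations (default 10; use
#'   1000+ for a stable SD).
#' @param seed Seed for the binomial draws.
#' @param tail_fraction Passed to [delta_observed()].
#' @param model Expected-prevalence model: `"logistic"` (default) or
#'   `"linear"`.
#' @return Numeric vector of `n_iterations` simulated deltas.
#' @export
delta_expected <- function(curve_a, curve_b, n_iterations = 10, seed = 1L,
                           tail_fraction = 0.02,
                           model = c("logistic", "linear")) {
  model <- match.arg(model)
  fa <- fit_expected_prevalence(curve_a, model)
  fb <- fit_expected_prevalence(curve_b, model)
  with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      sa <- curve_a; sb <- curve_b
      sa$k <- stats::rbinom(nrow(sa), sa$n, fa)
      sb$k <- stats::rbinom(nrow(sb), sb$n, fb)
      sa$prevalence <- sa$k / sa$n
      sb$prevalence <- sb$k / sb$n
      delta_observed(sa, sb, tail_fraction)
    }, 0)
  })
}

#' Scaled delta-departure canalization statistic
#'
#' \deqn{departure = (mean(|expected|) - |observed|) / sd(|expected|)}
#' Positive values mean the two strata's curves deviate less from each other
#' than the smooth expectation predicts (canalization); negative values mean
#' greater deviation than expected (decanalization).
#'
#' @param observed Observed delta (signed; the absolute value is used).
#' @param expected Vector of simulated expected deltas (>= 2 values).
#' @return Departure in SD units.
#' @export
delta_departure <- function(observed, expected) {
  if (length(expected) < 2L) stop("need >= 2 expected deltas", call. = FALSE)
  s <- stats::sd(abs(expected))
  if (!is.finite(s) || s <= 0) stop("zero SD of expected deltas", call. = FALSE)
  (mean(abs(expected)) - abs(observed)) / s
}

#' Canalization analysis for one stratified comparison
#'
#' Builds percentile prevalence curves for two strata of a cohort, then
#' computes the observed delta, the simulated expected deltas and the
#' delta-departure statistic.
#'
#' @param score Polygenic score vector (whole cohort).
#' @param status Binary disease status.
#' @param stratum Two-level vector (factor/character/0-1) defining the
#'   strata; `stratum_a` names the level treated as stratum a.
#' @param stratum_a Level of `stratum` used as group a (e.g. `"obese"` or
#'   `"low"`).
#' @param n_bins,tail_fraction,n_iterations,seed,model Passed through to the
#'   curve and delta functions.
#' @return One-row data.frame: `delta_observed, delta_expected_mean,
#'   delta_expected_sd, delta_departure, n_iterations, seed, tail_fraction,
#'   n_a, n_b`.
#' @export
canalization_analysis <- function(score, status, stratum, stratum_a,
                                  n_bins = 100, tail_fraction = 0.02,
                                  n_iterations = 10, seed = 1L,
                                  model = c("logistic", "linear")) {
  model <- match.arg(model)
  lv <- unique(stratum)
  if (!stratum_a %in% lv) stop("`stratum_a` not a level of `stratum`", call. = FALSE)
  in_a <- stratum == stratum_a
  curve_a <- prevalence_by_percentile(score[in_a], status[in_a], n_bins)
  curve_b <- prevalence_by_percentile(score[!in_a], status[!in_a], n_bins)
  obs <- delta_observed(curve_a, curve_b, tail_fraction)
  exp_d <- delta_expected(curve_a, curve_b, n_iterations, seed,
                          tail_fraction, model)
  data.frame(delta_observed = obs,
             delta_expected_mean = mean(abs(exp_d)),
             delta_expected_sd = stats::sd(abs(exp_d)),
             delta_departure = delta_departure(obs, exp_d),
             n_iterations = n_iterations, seed = seed,
             tail_fraction = tail_fraction,
             n_a = sum(in_a), n_b = sum(!in_a))
}

#' Enumerate the canalization/interaction comparison grid
#'
#' One comparison per disease x obesity measure x metabolite; with 178
#' diseases, 2 measures and 3 metabolites this is 1,068 comparisons.
#'
#' @param diseases,metabolites Label vectors.
#' @param measures Obesity measures (default `c("bmi", "whr")`).
#' @return Data.frame with columns `disease, measure, metabolite`, one row
#'   per comparison.
#' @export
canalization_comparisons <- function(diseases, metabolites,
                                     measures = c("bmi", "whr")) {
  out <- expand.grid(disease = unique(diseases), measure = unique(measures),
                     metabolite = unique(metabolites),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out[order(out$disease, out$measure, out$metabolite), , drop = FALSE]
}

#' Canalization screen over obesity strata
#'
#' For every (disease, obesity measure, metabolite) comparison, stratifies
#' the cohort into obese vs non-obese by that measure and computes the
#' delta-departure of the metabolite-PGS prevalence curves.
#'
#' @param cohort Prepared cohort (needs `bmi_obese`/`whr_obese`, `pgs_*`,
#'   `status_*` columns).
#' @param comparisons Grid from [canalization_comparisons()]; defaults to
#'   all diseases x both measures x all metabolites in the cohort.
#' @param n_bins,tail_fraction,n_iterations,seed,model Passed to
#'   [canalization_analysis()].
#' @return The comparisons grid with the canalization columns appended.
#' @export
canalization_screen <- function(cohort, comparisons = NULL, n_bins = 100,
                                tail_fraction = 0.02, n_iterations = 10,
                                seed = 1L, model = "logistic") {
  comparisons <- comparisons %||% canalization_comparisons(
    cohort_diseases(cohort), cohort_metabolites(cohort))
  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    cmp <- comparisons[i, ]
    obese <- cohort[[paste0(cmp$measure, "_obese")]]
    res <- canalization_analysis(
      score = cohort[[paste0("pgs_", cmp$metabolite)]],
      status = cohort[[paste0("status_", cmp$disease)]],
      stratum = ifelse(obese == 1, "obese", "non_obese"),
      stratum_a = "obese", n_bins = n_bins, tail_fraction = tail_fraction,
      n_iterations = n_iterations,
      seed = derive_seed(seed, paste(cmp$disease, cmp$measure, cmp$metabolite)),
      model = model)
    cbind(cmp, res, row.names = NULL)
  })
  do.call(rbind, rows)
}
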