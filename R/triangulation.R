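#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests (>= 1). For the full metabolite-disease
#'   scan this is `n_diseases * n_metabolites * 2` (two association modes).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0,1)", call. = FALSE)
  }
  if (!is.numeric(n_tests) || n_tests < 1) {
    stop("`n_tests` must be at least 1", call. = FALSE)
  }
  alpha / n_tests
}

#' Triangulate direct-level and polygenic-score associations
#'
#' A metabolite-disease association is called suggestive when the direct
#' (metabolite Z-score) and genetic (PGS-m) logistic associations are both
#' significant at `threshold` and point in the same direction (OR > 1 risk,
#' OR < 1 protective). A pair missing either counterpart fails with the
#' reason recorded.
#'
#' @param level_results,pgs_results Association tables (rows as returned by
#'   [run_association()]) for the level and pgs modes.
#' @param threshold P-value threshold, e.g. [bonferroni_threshold()].
#' @return Data.frame with one row per (metabolite, disease) seen in either
#'   input: `metabolite, disease, direction, beta_level, p_level, or_level,
#'   beta_pgs, p_pgs, or_pgs, passes, reason`.
#' @export
triangulate <- function(level_results, pgs_results, threshold) {
  key <- function(df) paste(df$metabolite, df$disease, sep = "\r")
  lv <- level_results[!duplicated(key(level_results)), , drop = FALSE]
  pg <- pgs_results[!duplicated(key(pgs_results)), , drop = FALSE]
  all_keys <- union(key(lv), key(pg))
  li <- match(all_keys, key(lv))
  pi <- match(all_keys, key(pg))
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  out <- data.frame(metabolite = parts[, 1], disease = parts[, 2],
                    beta_level = lv$beta[li], p_level = lv$p[li],
                    or_level = lv$or_[li],
                    beta_pgs = pg$beta[pi], p_pgs = pg$p[pi],
                    or_pgs = pg$or_[pi], stringsAsFactors = FALSE)
  missing_part <- is.na(li) | is.na(pi)
  both_sig <- !missing_part & out$p_level <= threshold & out$p_pgs <= threshold
  concordant <- !missing_part & sign(out$beta_level) == sign(out$beta_pgs)
  out$passes <- both_sig & concordant
  dir_beta <- ifelse(is.na(out$beta_level), out$beta_pgs, out$beta_level)
  out$direction <- ifelse(is.na(dir_beta), NA_character_,
                          ifelse(dir_beta > 0, "risk", "protective"))
  out$reason <- ifelse(missing_part, "missing counterpart result",
                       ifelse(!both_sig, "not significant in both modes",
                              ifelse(!concordant, "discordant directions", "")))
  out
}

#' Disease-group enrichment by relative risk and Fisher's exact test
#'
#' For each disease group the relative risk of being a significant disease,
#' \deqn{RR = (N_{sig,group}/N_{sig}) / (N_{group}/N_{total}),}
#' is computed together with a two-sided Fisher exact p-value on the 2x2
#' count table (significant/not x in-group/not). The per-group significance
#' threshold is `alpha` divided by the number of groups with at least one
#' significant disease (or by `n_groups` when supplied).
#'
#' @param significant Character vector of significant diseases, or a
#'   triangulated table (rows with `passes == TRUE` are used).
#' @param group_map Data.frame with columns `phecode` and `group` covering
#'   the full disease universe tested.
#' @param alpha Family-wise alpha for the group tests.
#' @param n_groups Optional fixed denominator for the Bonferroni threshold;
#'   by default the number of groups containing at least one significant
#'   disease.
#' @return Data.frame with one row per group: `group, n_sig_in_group,
#'   n_sig_total, n_group, n_total, rr, fisher_p, significant`.
#' @export
enrichment <- function(significant, group_map, alpha = 0.05, n_groups = NULL) {
  if (is.data.frame(significant)) {
    significant <- unique(significant$disease[significant$passes])
  }
  stopifnot(all(c("phecode", "group") %in% names(group_map)))
  significant <- unique(significant)
  unmapped <- setdiff(significant, group_map$phecode)
  if (length(unmapped)) {
    stop(sprintf("significant disease(s) missing from group map: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  n_total <- length(unique(group_map$phecode))
  n_sig_total <- length(significant)
  groups <- sort(unique(group_map$group))
  rows <- lapply(groups, function(g) {
    in_group <- unique(group_map$phecode[group_map$group == g])
    n_group <- length(in_group)
    if (n_group == 0L) stop("group with zero diseases", call. = FALSE)
    a <- length(intersect(significant, in_group))
    tab <- matrix(c(a, n_sig_total - a,
                    n_group - a, (n_total - n_group) - (n_sig_total - a)),
                  2L, 2L, byrow = TRUE)
    rr <- if (n_sig_total == 0) NA_real_ else (a / n_sig_total) / (n_group / n_total)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    data.frame(group = g, n_sig_in_group = a, n_sig_total = n_sig_total,
               n_group = n_group, n_total = n_total, rr = rr, fisher_p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  denom <- n_groups %||% max(1L, sum(out$n_sig_in_group >= 1L))
  out$significant <- out$fisher_p <= bonferroni_threshold(alpha, denom)
  out
}
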