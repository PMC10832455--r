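#' Collapse repeated measurements after QC filtering
#'
#' Measurements whose QC flag reports a warning are removed first; the median
#' of the surviving values is returned, or `NA` when none survive.
#'
#' @param values Numeric vector of repeated raw measurements for one
#'   individual.
#' @param qc_flags Logical or 0/1 vector of the same length; `TRUE`/1 marks a
#'   warning.
#' @return A single numeric value, or `NA_real_`.
#' @export
collapse_measurements <- function(values, qc_flags) {
  if (length(values) != length(qc_flags)) {
    stop("`values` and `qc_flags` must have equal length", call. = FALSE)
  }
  keep <- !(as.logical(qc_flags) %in% TRUE) & !is.na(values)
  if (!any(keep)) return(NA_real_)
  stats::median(values[keep])
}

#' Z-score a vector of raw measurements
#'
#' Centers and scales by the mean and sample SD (n - 1 denominator) of the
#' non-missing entries; missing values propagate.
#'
#' @param values Numeric vector with at least two non-missing entries.
#' @return Numeric vector of Z-scores.
#' @export
zscore <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  s <- stats::sd(values[ok])
  if (!is.finite(s) || s <= 0) stop("zero variance: cannot Z-score", call. = FALSE)
  (values - mean(values[ok])) / s
}

#' Waist-to-hip ratio
#'
#' @param waist,hip Circumferences (cm); when repeated measures are
#'   available, pass the per-individual medians.
#' @return `waist / hip`.
#' @export
compute_whr <- function(waist, hip) {
  if (any(!is.na(hip) & hip <= 0)) stop("`hip` must be positive", call. = FALSE)
  waist / hip
}

#' Classify obesity status
#'
#' BMI obesity is BMI > 30; WHR obesity is WHR > 0.85 for women and > 0.95
#' for men. Cutoffs are strict: a value exactly at the cutoff is non-obese.
#'
#' @param measure `"bmi"` or `"whr"`.
#' @param value Measure value(s).
#' @param sex `"female"`/`"male"`, or 0/1 with 0 = female (required for WHR).
#' @return Integer vector, 1 = obese, 0 = non-obese.
#' @export
classify_obesity <- function(measure, value, sex = NULL) {
  measure <- match.arg(tolower(measure), c("bmi", "whr"))
  if (measure == "bmi") return(as.integer(value > 30))
  if (is.null(sex)) stop("`sex` is required for WHR classification", call. = FALSE)
  if (is.character(sex)) {
    if (!all(sex %in% c("female", "male"))) stop("unknown sex label", call. = FALSE)
    sex <- as.integer(sex == "male")
  }
  if (!all(sex %in% c(0L, 1L))) stop("unknown sex coding", call. = FALSE)
  cut <- unname(WHR_CUTOFFS[sex + 1L])
  as.integer(value > cut)
}

#' Retain diseases with enough cases
#'
#' @param cohort A cohort table with `status_*` columns, or a data.frame of
#'   binary status columns.
#' @param min_cases Minimum case count (default 50; "at least" is inclusive).
#' @return Character vector of retained disease labels.
#' @export
min_case_filter <- function(cohort, min_cases = 50) {
  status_cols <- grep("^status_", names(cohort), value = TRUE)
  if (length(status_cols)) {
    counts <- vapply(cohort[status_cols], function(x) sum(x == 1, na.rm = TRUE), 0)
    names(counts) <- sub("^status_", "", status_cols)
  } else {
    counts <- vapply(cohort, function(x) sum(x == 1, na.rm = TRUE), 0)
  }
  names(counts)[counts >= min_cases]
}

#' Prepare a raw cohort for analysis
#'
#' Adds, for every metabolite `m` present: the QC-filtered median-collapsed
#' level `m_level` and its Z-score `m_z`; and the body-weight variables
#' `whr`, `bmi_z`, `whr_z` (Z-score of log-BMI and of WHR), `bmi_obese`,
#' `whr_obese`. Counts of QC-removed measurements and of individuals with no
#' surviving measurement are reported via `message()`.
#'
#' @param cohort A cohort `data.frame` (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @param verbose Emit per-metabolite QC messages.
#' @return The cohort with analysis columns appended.
#' @export
prepare_cohort <- function(cohort, verbose = FALSE) {
  for (m in cohort_metabolites(cohort)) {
    rep_cols <- grep(paste0("^", m, "_rep_\\d+$"), names(cohort), value = TRUE)
    if (!length(rep_cols)) next
    qc_cols <- sub("_rep_", "_qc_", rep_cols)
    vals <- as.matrix(cohort[rep_cols])
    flags <- if (all(qc_cols %in% names(cohort))) {
      as.matrix(cohort[qc_cols])
    } else matrix(0, nrow(vals), ncol(vals))
    vals[flags == 1] <- NA
    n_flagged <- sum(flags == 1)
    level <- apply(vals, 1L, function(v) {
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
    })
    if (verbose) {
      message(sprintf("%s: removed %d flagged measurements; %d/%d individuals retain a level",
                      m, n_flagged, sum(!is.na(level)), length(level)))
    }
    cohort[[paste0(m, "_level")]] <- level
    cohort[[paste0(m, "_z")]] <- zscore(level)
  }
  if (all(c("waist", "hip") %in% names(cohort))) {
    cohort$whr <- compute_whr(cohort$waist, cohort$hip)
  }
  if ("bmi" %in% names(cohort)) {
    cohort$bmi_z <- zscore(log(cohort$bmi))
    cohort$bmi_obese <- classify_obesity("bmi", cohort$bmi)
  }
  if ("whr" %in% names(cohort) && "sex" %in% names(cohort)) {
    cohort$whr_z <- zscore(cohort$whr)
    cohort$whr_obese <- classify_obesity("whr", cohort$whr, cohort$sex)
  }
  cohort
}

#' Allele-sum polygenic scoring from a dosage matrix
#'
#' Computes `score_i = sum_j dosage_ij * weight_j` over the SNPs shared
#' between the weight table and the dosage columns. When dosage alleles are
#' supplied, a weight whose effect allele matches the dosage allele (or its
#' strand complement) is used as is; one matching the other allele (or its
#' complement) has its sign flipped; anything else is dropped with a warning.
#' Scoring in chromosome chunks and summing is exactly equivalent to a
#' single pass.
#'
#' @param dosages Numeric matrix (individuals x SNPs, entries in [0, 2])
#'   with SNP ids as column names.
#' @param weights Data.frame with columns `snp`, `effect_allele`, `weight`
#'   (unique snp ids).
#' @param dosage_alleles Optional data.frame with columns `snp`,
#'   `dosage_allele` and optionally `other_allele`, describing the allele
#'   counted by each dosage column. When omitted, alleles are assumed
#'   aligned.
#' @param chromosome Optional vector assigning each weight row to a
#'   chromosome; scores are then computed per chunk and summed.
#' @return Numeric vector of per-individual scores.
#' @export
score_individuals <- function(dosages, weights, dosage_alleles = NULL,
                              chromosome = NULL) {
  stopifnot(is.matrix(dosages), !is.null(colnames(dosages)))
  if (anyDuplicated(weights$snp)) stop("duplicate snp ids in weights", call. = FALSE)
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  idx <- match(weights$snp, colnames(dosages))
  if (all(is.na(idx))) stop("no weight snp ids match dosage columns", call. = FALSE)
  keep <- !is.na(idx)
  w <- weights$weight[keep]
  snp <- weights$snp[keep]
  ea <- weights$effect_allele[keep]
  cols <- idx[keep]

  if (!is.null(dosage_alleles)) {
    da <- dosage_alleles[match(snp, dosage_alleles$snp), , drop = FALSE]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    same <- ea == da$dosage_allele | ea == comp[da$dosage_allele]
    flip <- if ("other_allele" %in% names(da)) {
      ea == da$other_allele | ea == comp[da$other_allele]
    } else rep(FALSE, length(ea))
    flip <- flip & !same
    drop <- !(same | flip)
    if (any(drop)) {
      warning(sprintf("dropping %d SNP(s) with unresolvable allele mismatch: %s",
                      sum(drop), paste(snp[drop], collapse = ", ")))
    }
    w <- ifelse(flip, -w, w)[!drop]
    cols <- cols[!drop]
    snp <- snp[!drop]
    if (!is.null(chromosome)) chromosome <- chromosome[keep][!drop]
  } else if (!is.null(chromosome)) {
    chromosome <- chromosome[keep]
  }

  if (is.null(chromosome)) {
    return(as.numeric(dosages[, cols, drop = FALSE] %*% w))
  }
  score <- numeric(nrow(dosages))
  for (chr in unique(chromosome)) {
    sel <- chromosome == chr
    score <- score + as.numeric(dosages[, cols[sel], drop = FALSE] %*% w[sel])
  }
  score
}
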