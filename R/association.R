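#' Maximum-likelihood logistic regression with diagnostics
#'
#' Thin wrapper around [stats::glm()] (binomial, logit link) that enforces
#' the preconditions the PheWAS scan relies on: both outcome classes
#' present, a full-rank design, convergence within tolerance, and a
#' complete-separation flag when any fitted probability is within 1e-8 of 0
#' or 1 at convergence (such fits are marked unreliable).
#'
#' @param y Binary outcome vector (0/1), both classes present.
#' @param X Numeric design matrix; an intercept column is prepended unless
#'   one is already present.
#' @return A `data.frame` with one row per coefficient (`term`, `beta`,
#'   `se`, `z`, `p`) and attributes `converged`, `separation`, `n`.
#' @export
fit_logistic <- function(y, X) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("`y` must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("`y` contains a single class", call. = FALSE)
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  has_intercept <- ncol(X) > 0 &&
    any(apply(X, 2L, function(c) all(c == c[1]) && c[1] != 0))
  if (!has_intercept) {
    X <- if (ncol(X) == 0L) {
      matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
    } else cbind(`(Intercept)` = 1, X)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  # glm.fit's own 0/1-probability warning is superseded by the explicit
  # separation diagnostic below
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) warning("logistic fit did not converge")
  separated <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  if (separated) warning("possible complete separation: fit flagged unreliable")
  # Wald SEs from the observed information at the IRLS solution
  cov <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  se <- sqrt(diag(cov))
  beta <- fit$coefficients
  z <- beta / se
  res <- data.frame(term = colnames(X), beta = unname(beta), se = se, z = z,
                    p = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "converged") <- fit$converged
  attr(res, "separation") <- separated
  attr(res, "n") <- length(y)
  res
}

covariate_matrix <- function(cohort, n_pcs = NULL) {
  pc_cols <- grep("^PC\\d+$", names(cohort), value = TRUE)
  pc_cols <- pc_cols[order(as.integer(sub("PC", "", pc_cols)))]
  if (!is.null(n_pcs)) pc_cols <- pc_cols[seq_len(min(n_pcs, length(pc_cols)))]
  agec <- cohort$age - mean(cohort$age, na.rm = TRUE)  # centered before squaring
  X <- cbind(age = agec, sex = cohort$sex, age2 = agec^2)
  if (length(pc_cols)) X <- cbind(X, as.matrix(cohort[pc_cols]))
  X
}

#' Covariate-adjusted metabolite-disease association
#'
#' Fits the scan's logistic model
#' `status ~ predictor + age + sex + age^2 + PC1..PC10` where the predictor
#' is the metabolite Z-score (`mode = "level"`) or the cohort-standardized
#' metabolite polygenic score (`mode = "pgs"`), so effects are per SD in
#' both modes. Individuals missing any model variable are excluded from
#' this model only.
#'
#' @param cohort A prepared cohort (see [prepare_cohort()]; called
#'   automatically if the level columns are absent).
#' @param metabolite Metabolite label.
#' @param disease Disease (phecode) label.
#' @param mode `"level"` or `"pgs"`.
#' @return One-row `data.frame`: `metabolite, disease, mode, beta, se, or_,
#'   ci_low, ci_high, p, n_case, n_control`.
#' @export
run_association <- function(cohort, metabolite, disease,
                            mode = c("level", "pgs")) {
  mode <- match.arg(mode)
  zcol <- paste0(metabolite, "_z")
  if (mode == "level" && !zcol %in% names(cohort)) cohort <- prepare_cohort(cohort)
  pred <- if (mode == "level") cohort[[zcol]] else {
    pgs <- cohort[[paste0("pgs_", metabolite)]]
    if (is.null(pgs)) stop(sprintf("no PGS column for metabolite `%s`", metabolite),
                           call. = FALSE)
    (pgs - mean(pgs, na.rm = TRUE)) / stats::sd(pgs, na.rm = TRUE)
  }
  y <- cohort[[paste0("status_", disease)]]
  if (is.null(y)) stop(sprintf("no status column for disease `%s`", disease),
                       call. = FALSE)
  X <- cbind(predictor = pred, covariate_matrix(cohort))
  ok <- stats::complete.cases(X) & !is.na(y)
  fit <- fit_logistic(y[ok], X[ok, , drop = FALSE])
  b <- fit[fit$term == "predictor", ]
  data.frame(metabolite = metabolite, disease = disease, mode = mode,
             beta = b$beta, se = b$se, or_ = exp(b$beta),
             ci_low = exp(b$beta - 1.96 * b$se),
             ci_high = exp(b$beta + 1.96 * b$se), p = b$p,
             n_case = sum(y[ok] == 1), n_control = sum(y[ok] == 0),
             stringsAsFactors = FALSE)
}

#' Association scan over metabolites and diseases
#'
#' Runs [run_association()] for every metabolite-disease pair in one or both
#' modes, after applying the minimum-case filter.
#'
#' @param cohort Prepared cohort.
#' @param metabolites,diseases Labels; default all present in the cohort.
#' @param modes Subset of `c("level", "pgs")`.
#' @param min_cases Minimum case count for a disease to be scanned.
#' @return Data.frame of association results, one row per
#'   (metabolite, disease, mode).
#' @export
run_association_scan <- function(cohort, metabolites = NULL, diseases = NULL,
                                 modes = c("level", "pgs"), min_cases = 50) {
  metabolites <- metabolites %||% cohort_metabolites(cohort)
  diseases <- diseases %||% cohort_diseases(cohort)
  diseases <- intersect(diseases, min_case_filter(cohort, min_cases))
  if (!paste0(metabolites[1], "_z") %in% names(cohort)) {
    cohort <- prepare_cohort(cohort)
  }
  rows <- list()
  for (mode in modes) for (m in metabolites) for (d in diseases) {
    rows[[length(rows) + 1L]] <- run_association(cohort, m, d, mode)
  }
  do.call(rbind, rows)
}
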