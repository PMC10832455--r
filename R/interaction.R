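weight_variable <- function(cohort, weight_mode) {
  if (!weight_mode %in% c("bmi_z", "whr_z", "bmi_obese", "whr_obese")) {
    stop(sprintf("unknown weight_mode `%s`", weight_mode), call. = FALSE)
  }
  v <- cohort[[weight_mode]]
  if (is.null(v)) stop(sprintf("cohort lacks `%s`; run prepare_cohort()", weight_mode),
                       call. = FALSE)
  v
}

#' Metabolite-by-body-weight interaction model
#'
#' Fits the logistic model
#' `status ~ predictor + W + predictor:W + age + sex + age^2 + PC1..PC10`
#' where the predictor is the metabolite Z-score (`predictor_mode="level"`)
#' or the standardized metabolite PGS (`"pgs"`), and W is a body-weight
#' variable: the Z-score of log-BMI or WHR, or the 0/1 obesity status under
#' that measure (non-obese as reference). The Wald p-value of the product
#' term is the interaction test.
#'
#' @param cohort Prepared cohort.
#' @param metabolite,disease Labels.
#' @param predictor_mode `"level"` or `"pgs"`.
#' @param weight_mode One of `"bmi_z", "whr_z", "bmi_obese", "whr_obese"`.
#' @return One-row data.frame: `metabolite, disease, predictor_mode,
#'   weight_mode, beta_main_predictor, beta_main_weight, beta_interaction,
#'   se_interaction, p_interaction, n`.
#' @export
fit_interaction <- function(cohort, metabolite, disease,
                            predictor_mode = c("level", "pgs"),
                            weight_mode = c("bmi_z", "whr_z",
                                            "bmi_obese", "whr_obese")) {
  predictor_mode <- match.arg(predictor_mode)
  weight_mode <- match.arg(weight_mode)
  if (!paste0(metabolite, "_z") %in% names(cohort)) cohort <- prepare_cohort(cohort)
  pred <- if (predictor_mode == "level") {
    cohort[[paste0(metabolite, "_z")]]
  } else {
    pgs <- cohort[[paste0("pgs_", metabolite)]]
    (pgs - mean(pgs, na.rm = TRUE)) / stats::sd(pgs, na.rm = TRUE)
  }
  w <- weight_variable(cohort, weight_mode)
  y <- cohort[[paste0("status_", disease)]]
  X <- cbind(predictor = pred, weight = w, interaction = pred * w,
             covariate_matrix(cohort))
  ok <- stats::complete.cases(X) & !is.na(y)
  fit <- fit_logistic(y[ok], X[ok, , drop = FALSE])
  gi <- fit[fit$term == "interaction", ]
  data.frame(metabolite = metabolite, disease = disease,
             predictor_mode = predictor_mode, weight_mode = weight_mode,
             beta_main_predictor = fit$beta[fit$term == "predictor"],
             beta_main_weight = fit$beta[fit$term == "weight"],
             beta_interaction = gi$beta, se_interaction = gi$se,
             p_interaction = gi$p, n = sum(ok), stringsAsFactors = FALSE)
}

#' Interaction screen over triangulated associations
#'
#' Runs [fit_interaction()] for every passing triangulated association in
#' all 4 weight modes x 2 predictor modes, flags nominal significance at
#' `alpha` (and, for transparency, Bonferroni significance over the number
#' of fitted models), and summarizes the fraction of nominally significant
#' interactions per disease group when a group map is supplied.
#'
#' @param cohort Prepared cohort.
#' @param triangulated Table from [triangulate()]; only rows with
#'   `passes == TRUE` are screened.
#' @param group_map Optional `phecode`/`group` map for the per-group summary.
#' @param alpha Nominal significance level (default 0.05).
#' @return Data.frame of interaction results with `nominal_sig` and
#'   `bonferroni_sig` flags; when `group_map` is given, a per-group summary
#'   data.frame is attached as attribute `group_summary`.
#' @export
interaction_screen <- function(cohort, triangulated, group_map = NULL,
                               alpha = 0.05) {
  hits <- triangulated[triangulated$passes, , drop = FALSE]
  if (nrow(hits) == 0L) {
    out <- data.frame(metabolite = character(0), disease = character(0),
                      predictor_mode = character(0), weight_mode = character(0),
                      beta_main_predictor = numeric(0),
                      beta_main_weight = numeric(0),
                      beta_interaction = numeric(0),
                      se_interaction = numeric(0),
                      p_interaction = numeric(0), n = integer(0),
                      nominal_sig = logical(0), bonferroni_sig = logical(0))
    return(out)
  }
  if (!paste0(hits$metabolite[1], "_z") %in% names(cohort)) {
    cohort <- prepare_cohort(cohort)
  }
  grid <- expand.grid(i = seq_len(nrow(hits)),
                      predictor_mode = c("level", "pgs"),
                      weight_mode = c("bmi_z", "whr_z", "bmi_obese", "whr_obese"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    h <- hits[grid$i[g], ]
    fit_interaction(cohort, h$metabolite, h$disease,
                    grid$predictor_mode[g], grid$weight_mode[g])
  })
  out <- do.call(rbind, rows)
  out$nominal_sig <- out$p_interaction < alpha
  out$bonferroni_sig <- out$p_interaction < bonferroni_threshold(alpha, nrow(out))
  if (!is.null(group_map)) {
    out$group <- group_map$group[match(out$disease, group_map$phecode)]
    agg <- stats::aggregate(nominal_sig ~ group, out, mean)
    names(agg)[2] <- "fraction_nominal_sig"
    agg$n_models <- stats::aggregate(nominal_sig ~ group, out, length)$nominal_sig
    attr(out, "group_summary") <- agg
  }
  out
}
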