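#' Specify a simulated metabolite
#'
#' Describes one circulating metabolite for the synthetic cohort generator.
#' The metabolite's polygenic score (PGS-m) is standard normal and explains a
#' fraction `h2_pgs` of the variance of the underlying level; the level is
#' then placed on a positive concentration scale and observed as `n_repeats`
#' noisy repeat measurements, each of which may carry a QC warning flag.
#'
#' @param name Metabolite label (must be a syntactic name, e.g. `"omega3"`).
#' @param h2_pgs Fraction of the metabolite level variance explained by its
#'   polygenic score; must lie strictly in (0, 1). Default 0.5, the typical
#'   share captured by well-powered metabolite scores.
#' @param n_repeats Number of repeated measurements per individual.
#' @param qc_warning_rate Probability that any single measurement carries a
#'   QC warning (flagged measurements are dropped during preparation).
#' @param measurement_sd Measurement noise SD on the concentration scale.
#' @param conc_mean,conc_sd Location and scale used to map the standardized
#'   latent level onto a positive concentration scale.
#' @return An object of class `metabolite_spec`.
#' @export
metabolite_spec <- function(name, h2_pgs = 0.5, n_repeats = 1,
                            qc_warning_rate = 0, measurement_sd = 0.1,
                            conc_mean = 5, conc_sd = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (make.names(name) != name) {
    stop("metabolite `name` must be a syntactic R name", call. = FALSE)
  }
  check_fraction(h2_pgs, "h2_pgs", open = TRUE)
  check_fraction(qc_warning_rate, "qc_warning_rate")
  stopifnot(n_repeats >= 1, measurement_sd >= 0, conc_sd > 0)
  structure(list(name = name, h2_pgs = h2_pgs, n_repeats = as.integer(n_repeats),
                 qc_warning_rate = qc_warning_rate,
                 measurement_sd = measurement_sd,
                 conc_mean = conc_mean, conc_sd = conc_sd),
            class = "metabolite_spec")
}

#' Specify a simulated disease endpoint
#'
#' Describes one binary disease (phecode) generated from a logistic
#' liability model
#' \deqn{logit P(case) = logit(p_0) + \beta_m T_m + \beta_{prs} PRS_d +
#'       \beta_w W + \gamma P W}
#' where \eqn{T_m} is the standardized latent level of the linked metabolite,
#' \eqn{PRS_d} the standard-normal disease risk score, \eqn{W} the chosen
#' body-weight variable (Z-score or obesity indicator, per
#' `interaction_with`) and \eqn{P} the interaction predictor (latent level or
#' PGS-m, per `interaction_mode`). Protective metabolite effects are encoded
#' as `beta_metabolite < 0`.
#'
#' @param phecode Disease label (syntactic name).
#' @param group Disease-group label (e.g. `"digestive"`).
#' @param baseline_prevalence Intercept prevalence \eqn{p_0}, strictly in
#'   (0, 1).
#' @param beta_metabolite Log-OR per SD of the latent metabolite level.
#' @param metabolite Name of the linked metabolite; defaults to the first
#'   metabolite of the cohort spec.
#' @param beta_prs Log-OR per SD of the disease PRS. If `NULL` and
#'   `prs_r2_liability > 0`, it is derived from the liability variance
#'   fraction on the logit scale.
#' @param prs_r2_liability Fraction of logit-liability variance attributed to
#'   the PRS; used only when `beta_prs` is `NULL`.
#' @param beta_obesity Main-effect log-OR of the body-weight variable named
#'   by `interaction_with`.
#' @param gamma_interaction Interaction log-OR per unit product of predictor
#'   and body-weight variable.
#' @param interaction_mode Which metabolite variable enters the product term:
#'   `"level"` (latent standardized level) or `"pgs"`.
#' @param interaction_with Body-weight variable for the main and product
#'   terms: `"bmi_z"`, `"whr_z"`, `"bmi_obese"` or `"whr_obese"`.
#' @return An object of class `disease_spec`.
#' @export
disease_spec <- function(phecode, group = "unassigned",
                         baseline_prevalence = 0.05,
                         beta_metabolite = 0, metabolite = NULL,
                         beta_prs = NULL, prs_r2_liability = 0,
                         beta_obesity = 0, gamma_interaction = 0,
                         interaction_mode = c("level", "pgs"),
                         interaction_with = c("bmi_z", "whr_z",
                                              "bmi_obese", "whr_obese")) {
  stopifnot(is.character(phecode), length(phecode) == 1L, nzchar(phecode))
  if (make.names(phecode) != phecode) {
    stop("`phecode` must be a syntactic R name", call. = FALSE)
  }
  check_fraction(baseline_prevalence, "baseline_prevalence", open = TRUE)
  check_fraction(prs_r2_liability, "prs_r2_liability")
  if (is.null(beta_prs)) {
    beta_prs <- if (prs_r2_liability > 0) {
      # logit-liability variance is beta^2 + pi^2/3 for a N(0,1) PRS
      sqrt(prs_r2_liability * (pi^2 / 3) / (1 - prs_r2_liability))
    } else 0
  }
  structure(list(phecode = phecode, group = group,
                 baseline_prevalence = baseline_prevalence,
                 beta_metabolite = beta_metabolite, metabolite = metabolite,
                 beta_prs = beta_prs, prs_r2_liability = prs_r2_liability,
                 beta_obesity = beta_obesity,
                 gamma_interaction = gamma_interaction,
                 interaction_mode = match.arg(interaction_mode),
                 interaction_with = match.arg(interaction_with)),
            class = "disease_spec")
}

#' Specify a synthetic cohort
#'
#' Bundles the study-level generative parameters: sample size, demographic
#' marginals, target obesity prevalences for the two body-weight measures,
#' and the lists of metabolites and diseases to simulate.
#'
#' @param n_individuals Cohort size (> 0).
#' @param seed Integer seed; identical specs with identical seeds produce
#'   identical cohorts.
#' @param metabolites List of [metabolite_spec()] objects.
#' @param diseases List of [disease_spec()] objects.
#' @param obesity_prevalence_bmi Target fraction with BMI > 30.
#' @param obesity_prevalence_whr Named fractions `c(female=, male=)` above
#'   the sex-specific waist-to-hip ratio cutoffs (0.85 / 0.95).
#' @param age_range Two-element range of ages (years), sampled uniformly.
#' @param sex_fraction Fraction female.
#' @param n_pcs Number of genotype principal components (standard normal).
#' @param bmi_whr_cor Gaussian-copula correlation between BMI and WHR.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals, seed = 1L,
                        metabolites = list(metabolite_spec("omega3")),
                        diseases = list(disease_spec("X008")),
                        obesity_prevalence_bmi = 0.25,
                        obesity_prevalence_whr = c(female = 0.45, male = 0.30),
                        age_range = c(40, 70), sex_fraction = 0.54,
                        n_pcs = 10, bmi_whr_cor = 0.5) {
  if (!is.numeric(n_individuals) || n_individuals < 1) {
    stop("`n_individuals` must be a positive count", call. = FALSE)
  }
  stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2],
            n_pcs >= 0, abs(bmi_whr_cor) <= 1)
  check_fraction(obesity_prevalence_bmi, "obesity_prevalence_bmi", open = TRUE)
  check_fraction(obesity_prevalence_whr, "obesity_prevalence_whr", open = TRUE)
  check_fraction(sex_fraction, "sex_fraction")
  if (is.null(names(obesity_prevalence_whr))) {
    names(obesity_prevalence_whr) <- c("female", "male")
  }
  metabolites <- if (inherits(metabolites, "metabolite_spec")) list(metabolites) else metabolites
  diseases <- if (inherits(diseases, "disease_spec")) list(diseases) else diseases
  stopifnot(all(vapply(metabolites, inherits, TRUE, "metabolite_spec")),
            all(vapply(diseases, inherits, TRUE, "disease_spec")))
  mnames <- vapply(metabolites, `[[`, "", "name")
  if (anyDuplicated(mnames)) stop("duplicate metabolite names", call. = FALSE)
  dnames <- vapply(diseases, `[[`, "", "phecode")
  if (anyDuplicated(dnames)) stop("duplicate phecodes", call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed),
                 metabolites = metabolites, diseases = diseases,
                 obesity_prevalence_bmi = obesity_prevalence_bmi,
                 obesity_prevalence_whr = obesity_prevalence_whr,
                 age_range = age_range, sex_fraction = sex_fraction,
                 n_pcs = as.integer(n_pcs), bmi_whr_cor = bmi_whr_cor),
            class = "cohort_spec")
}

# WHR cutoffs used throughout: > 0.85 for women, > 0.95 for men.
WHR_CUTOFFS <- c(female = 0.85, male = 0.95)

#' Generate a synthetic individual-level cohort
#'
#' Simulates one row per individual: demographics, genotype PCs, body
#' measures (BMI log-normal with median 27; waist and hip consistent with a
#' per-sex normal waist-to-hip ratio; the BMI and WHR marginals are tuned so
#' that the spec's obesity prevalences hold at the standard cutoffs),
#' per-metabolite polygenic scores and repeated concentration measurements
#' with QC flags, per-disease risk scores, and binary disease status drawn
#' from each [disease_spec()]'s logistic model.
#'
#' Column layout: `id`, `age`, `sex` (0 female / 1 male), `PC1..PCk`, `bmi`,
#' `waist`, `hip`; per metabolite `m`: `pgs_m`, `m_true` (latent standardized
#' level, kept for diagnostics), `m_rep_1..`, `m_qc_1..`; per disease `d`:
#' `prs_d`, `status_d`.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` of class `cohort_table`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_individuals
  with_seed(spec$seed, {
    sex <- stats::rbinom(n, 1L, 1 - spec$sex_fraction)  # 1 = male
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    out <- data.frame(id = sprintf("ind%06d", seq_len(n)), age = age, sex = sex)
    if (spec$n_pcs > 0) {
      pcs <- matrix(stats::rnorm(n * spec$n_pcs), n)
      colnames(pcs) <- paste0("PC", seq_len(spec$n_pcs))
      out <- cbind(out, pcs)
    }

    # Body measures: Gaussian copula between log-BMI and WHR, marginals
    # calibrated so P(BMI > 30) and P(WHR > cutoff | sex) match the spec.
    z1 <- stats::rnorm(n)
    z2 <- spec$bmi_whr_cor * z1 +
      sqrt(1 - spec$bmi_whr_cor^2) * stats::rnorm(n)
    sdlog <- (log(30) - log(27)) / stats::qnorm(1 - spec$obesity_prevalence_bmi)
    out$bmi <- exp(log(27) + sdlog * z1)
    whr_sd <- 0.065
    prev_whr <- spec$obesity_prevalence_whr[c("female", "male")]
    whr_mean <- WHR_CUTOFFS - whr_sd * stats::qnorm(1 - prev_whr)
    whr <- whr_mean[sex + 1L] + whr_sd * z2
    out$hip <- stats::rnorm(n, ifelse(sex == 1L, 100, 103), 7)
    out$waist <- whr * out$hip

    bmi_z <- scale_vec(log(out$bmi))
    whr_z <- scale_vec(whr)
    bmi_obese <- as.numeric(out$bmi > 30)
    whr_obese <- as.numeric(whr > WHR_CUTOFFS[sex + 1L])

    truth <- list()
    for (m in spec$metabolites) {
      pgs <- stats::rnorm(n)
      latent <- sqrt(m$h2_pgs) * pgs + sqrt(1 - m$h2_pgs) * stats::rnorm(n)
      out[[paste0("pgs_", m$name)]] <- pgs
      out[[paste0(m$name, "_true")]] <- latent
      conc <- m$conc_mean + m$conc_sd * latent
      for (r in seq_len(m$n_repeats)) {
        out[[paste0(m$name, "_rep_", r)]] <- conc +
          stats::rnorm(n, 0, m$measurement_sd)
        out[[paste0(m$name, "_qc_", r)]] <-
          stats::rbinom(n, 1L, m$qc_warning_rate)
      }
      truth[[m$name]] <- list(pgs = pgs, latent = latent)
    }

    weight_vars <- list(bmi_z = bmi_z, whr_z = whr_z,
                        bmi_obese = bmi_obese, whr_obese = whr_obese)
    mnames <- vapply(spec$metabolites, `[[`, "", "name")
    for (d in spec$diseases) {
      mlink <- d$metabolite %||% mnames[1]
      if (!mlink %in% mnames) {
        stop(sprintf("disease `%s` links to unknown metabolite `%s`",
                     d$phecode, mlink), call. = FALSE)
      }
      prs <- stats::rnorm(n)
      pred <- if (d$interaction_mode == "pgs") truth[[mlink]]$pgs else truth[[mlink]]$latent
      w <- weight_vars[[d$interaction_with]]
      eta <- stats::qlogis(d$baseline_prevalence) +
        d$beta_metabolite * truth[[mlink]]$latent +
        d$beta_prs * prs +
        d$beta_obesity * w +
        d$gamma_interaction * pred * w
      out[[paste0("prs_", d$phecode)]] <- prs
      out[[paste0("status_", d$phecode)]] <-
        stats::rbinom(n, 1L, stats::plogis(eta))
    }
    class(out) <- c("cohort_table", "data.frame")
    attr(out, "metabolites") <- mnames
    attr(out, "diseases") <- vapply(spec$diseases, `[[`, "", "phecode")
    out
  })
}

scale_vec <- function(x) as.numeric(scale(x))

#' Names of metabolites / diseases carried by a cohort table
#'
#' Inferred from column prefixes (`pgs_*` paired with `*_rep_1`, and
#' `status_*`), so they survive a round trip through delimited text.
#' @param cohort A cohort `data.frame`.
#' @return Character vector of labels.
#' @export
cohort_metabolites <- function(cohort) {
  cand <- sub("^pgs_", "", grep("^pgs_", names(cohort), value = TRUE))
  cand[paste0(cand, "_rep_1") %in% names(cohort) |
         paste0(cand, "_level") %in% names(cohort)]
}

#' @rdname cohort_metabolites
#' @export
cohort_diseases <- function(cohort) {
  sub("^status_", "", grep("^status_", names(cohort), value = TRUE))
}

#' Specify paired exposure/outcome GWAS summary statistics
#'
#' @param n_snps Number of independent instruments (>= 2).
#' @param n_exposure,n_outcome GWAS sample sizes for the exposure and
#'   outcome studies.
#' @param causal_effect True causal log-OR on the outcome per SD of exposure.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the direct (pleiotropic)
#'   outcome effects carried by invalid instruments.
#' @param invalid_fraction Fraction of instruments with a direct outcome
#'   effect, in [0, 1].
#' @param maf_range Interval from which effect-allele frequencies are drawn.
#' @param seed Integer seed.
#' @return An object of class `sumstats_spec`.
#' @export
sumstats_spec <- function(n_snps = 50, n_exposure = 100000,
                          n_outcome = 100000, causal_effect = 0,
                          pleiotropy_mean = 0, pleiotropy_sd = 0,
                          invalid_fraction = 0,
                          maf_range = c(0.1, 0.5), seed = 1L) {
  if (n_snps < 2) stop("`n_snps` must be at least 2", call. = FALSE)
  check_fraction(invalid_fraction, "invalid_fraction")
  stopifnot(n_exposure > 1, n_outcome > 1, pleiotropy_sd >= 0,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] <= maf_range[2])
  structure(list(n_snps = as.integer(n_snps),
                 n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome),
                 causal_effect = causal_effect,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 invalid_fraction = invalid_fraction,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "sumstats_spec")
}

#' Generate paired exposure and outcome GWAS summary statistics
#'
#' Per SNP j the true exposure effect is drawn uniformly on [0.05, 0.15],
#' oriented to the exposure-raising allele (so that instruments reach
#' genome-wide significance at biobank-scale `n_exposure` under the
#' standard-error model below); the observed effect adds sampling noise with
#' `se = 1/sqrt(2*maf*(1-maf)*n)`. The outcome effect is
#' `causal_effect * beta_x_true` plus, for the `invalid_fraction` of
#' instruments, a direct pleiotropic effect `N(pleiotropy_mean,
#' pleiotropy_sd)`, again observed with its own sampling noise. Both tables
#' share SNP ids, alleles and frequencies.
#'
#' @param spec A [sumstats_spec()].
#' @return A list with elements `exposure` and `outcome`, each a `data.frame`
#'   with columns `snp, effect_allele, other_allele, eaf, beta, se, p, n`.
#' @export
generate_summary_stats <- function(spec) {
  stopifnot(inherits(spec, "sumstats_spec"))
  with_seed(spec$seed, {
    k <- spec$n_snps
    snp <- sprintf("rs%05d", seq_len(k))
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, k, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), "")
    maf <- stats::runif(k, spec$maf_range[1], spec$maf_range[2])
    eaf <- ifelse(stats::runif(k) < 0.5, maf, 1 - maf)

    # effect alleles are oriented to the exposure-raising allele, the usual
    # instrument-table convention; directional pleiotropy is then a nonzero
    # mean direct effect in that orientation
    beta_x_true <- stats::runif(k, 0.05, 0.15)
    se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * spec$n_exposure)
    beta_x <- beta_x_true + stats::rnorm(k, 0, se_x)

    invalid <- stats::runif(k) < spec$invalid_fraction
    alpha <- ifelse(invalid,
                    stats::rnorm(k, spec$pleiotropy_mean, spec$pleiotropy_sd), 0)
    se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * spec$n_outcome)
    beta_y <- spec$causal_effect * beta_x_true + alpha +
      stats::rnorm(k, 0, se_y)

    mk <- function(beta, se, n) data.frame(
      snp = snp, effect_allele = ea, other_allele = unname(oa), eaf = eaf,
      beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)), n = n,
      stringsAsFactors = FALSE)
    list(exposure = mk(beta_x, se_x, spec$n_exposure),
         outcome = mk(beta_y, se_y, spec$n_outcome))
  })
}
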