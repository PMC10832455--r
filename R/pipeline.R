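#' Read a pipeline configuration file
#'
#' Configurations are one structured file (JSON, or YAML when the `yaml`
#' package is available) with per-stage blocks; see
#' [default_pipeline_config()] for the recognized fields. Scalars omitted
#' from the file take their defaults.
#'
#' @param path Path to a `.json`/`.yaml`/`.yml` file, or a list already in
#'   memory.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the `yaml` package is required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- default_pipeline_config()
  cfg <- utils::modifyList(defaults, cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Default pipeline configuration
#'
#' @return List of stage parameters: root `seed`, `out_dir`, the synthetic
#'   demo sizes (`n_individuals`, `n_metabolites`, `n_diseases`), alpha
#'   levels and thresholds for every stage, and stage toggles
#'   (`run_mr`, `run_interaction`, `run_canalization`).
#' @export
default_pipeline_config <- function() {
  list(seed = 1L, out_dir = "phetriad_results",
       n_individuals = 20000L, n_metabolites = 3L, n_diseases = 12L,
       alpha = 0.05, min_cases = 50L,
       instrument_p = 5e-8, mr_alpha = 0.05, interaction_alpha = 0.05,
       n_bins = 100L, tail_fraction = 0.02, n_iterations = 10L,
       n_snps = 50L, mr_n_exposure = 100000L, mr_n_outcome = 100000L,
       mr_causal_effect = -0.2,
       run_mr = TRUE, run_interaction = TRUE, run_canalization = TRUE)
}

# Demo cohort spec mirroring the analysis structure: 3 metabolites, a mix of
# protective, null and interacting diseases across disease groups.
demo_cohort_spec <- function(config) {
  mnames <- paste0("met", seq_len(config$n_metabolites))
  metabolites <- lapply(mnames, function(nm)
    metabolite_spec(nm, h2_pgs = 0.5, n_repeats = 2, qc_warning_rate = 0.01))
  groups <- c("circulatory", "digestive", "endocrine_metabolic",
              "respiratory", "genitourinary", "musculoskeletal")
  diseases <- lapply(seq_len(config$n_diseases), function(i) {
    m <- mnames[(i - 1L) %% length(mnames) + 1L]
    disease_spec(sprintf("d%03d", i), group = groups[(i - 1L) %% length(groups) + 1L],
                 baseline_prevalence = 0.05 + 0.01 * ((i - 1L) %% 5L),
                 beta_metabolite = if (i %% 3L == 0L) 0 else -0.25,
                 metabolite = m,
                 prs_r2_liability = 0.05,
                 beta_obesity = 0.3,
                 gamma_interaction = if (i %% 4L == 1L) -0.2 else 0,
                 interaction_mode = "pgs", interaction_with = "bmi_obese")
  })
  cohort_spec(config$n_individuals, seed = derive_seed(config$seed, "cohort"),
              metabolites = metabolites, diseases = diseases)
}

#' Run the full analysis pipeline
#'
#' Executes the stage order: synthetic-data generation (or reading of the
#' configured input tables) -> cohort preparation -> level and PGS
#' association scans -> triangulation and disease-group enrichment ->
#' two-sample MR -> interaction screen -> canalization screen. Every stage's
#' table is written tab-delimited under `config$out_dir`, together with a
#' JSON run manifest (configuration, seed, package version). All randomness
#' derives from the root seed through named per-stage streams, so a rerun
#' with the same configuration is bit-identical for every deterministic
#' stage.
#'
#' @param config A `pipeline_config`, a list of overrides, or a path to a
#'   config file.
#' @return (Invisibly) a list with every stage's in-memory result and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) || (is.list(config) && !inherits(config, "pipeline_config"))) {
    config <- read_pipeline_config(config)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list(out_dir = out_dir)

  # stage: synthetic_data (or external inputs)
  cohort <- if (!is.null(config$cohort_path)) {
    read_cohort(config$cohort_path)
  } else {
    generate_cohort(demo_cohort_spec(config))
  }
  spec <- if (is.null(config$cohort_path)) demo_cohort_spec(config) else NULL
  write_cohort(cohort, file.path(out_dir, "cohort.tsv"))

  # stage: cohort_prep
  cohort <- prepare_cohort(cohort)
  diseases <- intersect(cohort_diseases(cohort),
                        min_case_filter(cohort, config$min_cases))
  metabolites <- cohort_metabolites(cohort)

  # stage: association (both modes)
  assoc <- run_association_scan(cohort, metabolites, diseases,
                                min_cases = config$min_cases)
  write_tsv_table(assoc[assoc$mode == "level", ],
                  file.path(out_dir, "associations_level.tsv"))
  write_tsv_table(assoc[assoc$mode == "pgs", ],
                  file.path(out_dir, "associations_pgs.tsv"))
  results$associations <- assoc

  # stage: triangulation + enrichment
  thr <- bonferroni_threshold(config$alpha,
                              length(diseases) * length(metabolites) * 2)
  tri <- triangulate(assoc[assoc$mode == "level", ],
                     assoc[assoc$mode == "pgs", ], thr)
  write_tsv_table(tri, file.path(out_dir, "triangulated.tsv"))
  results$triangulated <- tri
  group_map <- if (!is.null(config$group_map_path)) {
    read_group_map(config$group_map_path)
  } else if (!is.null(spec)) {
    data.frame(phecode = vapply(spec$diseases, `[[`, "", "phecode"),
               group = vapply(spec$diseases, `[[`, "", "group"),
               stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(group_map)) {
    enr <- enrichment(tri, group_map, alpha = config$alpha)
    write_tsv_table(enr, file.path(out_dir, "enrichment.tsv"))
    results$enrichment <- enr
  }

  # stage: mr (paired synthetic summary statistics unless files are given)
  if (isTRUE(config$run_mr)) {
    mr_tables <- list()
    if (!is.null(config$mr_exposure_path)) {
      pairs <- list(list(name = "exposure_outcome",
                         exposure = read_summary_stats(config$mr_exposure_path),
                         outcome = read_summary_stats(config$mr_outcome_path)))
    } else {
      pairs <- lapply(metabolites, function(m) {
        ss <- generate_summary_stats(sumstats_spec(
          n_snps = config$n_snps, n_exposure = config$mr_n_exposure,
          n_outcome = config$mr_n_outcome,
          causal_effect = config$mr_causal_effect,
          seed = derive_seed(config$seed, paste0("mr_", m))))
        list(name = m, exposure = ss$exposure, outcome = ss$outcome)
      })
    }
    for (pr in pairs) {
      res <- run_mr(pr$exposure, pr$outcome, p_threshold = config$instrument_p,
                    mr_alpha = config$mr_alpha,
                    wm_seed = derive_seed(config$seed, paste0("wm_", pr$name)))
      res <- cbind(pair = pr$name, res,
                   mr_supported = attr(res, "mr_supported"),
                   dual_support = attr(res, "dual_support"))
      mr_tables[[pr$name]] <- res
    }
    mr_all <- do.call(rbind, mr_tables)
    write_tsv_table(mr_all, file.path(out_dir, "mr_results.tsv"))
    results$mr <- mr_all
  }

  # stage: interaction
  if (isTRUE(config$run_interaction)) {
    inter <- interaction_screen(cohort, tri, group_map,
                                alpha = config$interaction_alpha)
    write_tsv_table(inter, file.path(out_dir, "interactions.tsv"))
    results$interactions <- inter
  }

  # stage: canalization
  if (isTRUE(config$run_canalization)) {
    cmp <- canalization_comparisons(diseases, metabolites)
    canal <- canalization_screen(cohort, cmp, n_bins = config$n_bins,
                                 tail_fraction = config$tail_fraction,
                                 n_iterations = config$n_iterations,
                                 seed = derive_seed(config$seed, "canalization"))
    write_tsv_table(canal, file.path(out_dir, "canalization.tsv"))
    results$canalization <- canal
  }

  manifest <- list(
    package = "phetriad",
    version = as.character(utils::packageVersion("phetriad")),
    seed = config$seed,
    config = config[setdiff(names(config), NULL)],
    stages = setdiff(names(results), "out_dir"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
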