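#' Read and write the pipeline's tab-delimited tables
#'
#' All pipeline tables are tab-delimited text with a header row. Reading
#' validates the header: an empty file or a missing required column is an
#' error naming the offending column(s).
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @return A `data.frame`.
#' @export
read_tsv_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L) stop(sprintf("empty input file: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L && ncol(df) == 0L) {
    stop(sprintf("empty input file: %s", path), call. = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @rdname read_tsv_table
#' @param df Data.frame to write.
#' @export
write_tsv_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SUMSTATS_COLS <- c("snp", "effect_allele", "other_allele", "eaf",
                   "beta", "se", "p", "n")

#' Readers for the standard pipeline inputs
#'
#' `read_summary_stats()` requires the GWAS columns `snp, effect_allele,
#' other_allele, eaf, beta, se, p, n`; `read_weights()` the 3-column score
#' file `snp, effect_allele, weight`; `read_group_map()` the `phecode,
#' group` map; `read_cohort()` any cohort table with an `id` column.
#'
#' @param path File path.
#' @return A `data.frame` (for `read_cohort`, of class `cohort_table`).
#' @export
read_summary_stats <- function(path) read_tsv_table(path, SUMSTATS_COLS)

#' @rdname read_summary_stats
#' @export
read_weights <- function(path) {
  w <- read_tsv_table(path, c("snp", "effect_allele", "weight"))
  if (anyDuplicated(w$snp)) stop("duplicate snp ids in weight file", call. = FALSE)
  w
}

#' @rdname read_summary_stats
#' @export
read_group_map <- function(path) read_tsv_table(path, c("phecode", "group"))

#' @rdname read_summary_stats
#' @export
read_cohort <- function(path) {
  df <- read_tsv_table(path, "id")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @rdname read_summary_stats
#' @param cohort Cohort table to write.
#' @export
write_cohort <- function(cohort, path) write_tsv_table(cohort, path)
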