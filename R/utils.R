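# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stream seed from a root seed
#'
#' Deterministically maps a root seed and a stream label to an integer seed
#' below 2^31, so that each pipeline stage (or replicate) draws from its own
#' reproducible stream.
#'
#' @param root Integer root seed.
#' @param stream Character label of the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(root, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(root) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_fraction <- function(x, name, open = FALSE) {
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (!is.numeric(x) || anyNA(x) || bad) {
    stop(sprintf("`%s` must be in %s", name, if (open) "(0,1)" else "[0,1]"),
         call. = FALSE)
  }
  invisible(x)
}
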