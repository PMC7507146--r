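# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a global seed and a key
#'
#' The pipeline draws per-record Monte Carlo samples (bootstrap proportions,
#' censoring imputations) from substreams seeded by hashing the global seed
#' together with identifying keys (site, date, analyte). Adding or reordering
#' records therefore never perturbs the draws of unrelated records.
#'
#' @param seed Integer global seed.
#' @param ... Character or numeric keys identifying the substream.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "\x1f")
  # polynomial rolling hash; 31 * (2^31 - 1) < 2^53 so doubles stay exact
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% m
  as.integer(h)
}

# stop() with call. = FALSE everywhere, consistent error surface
abort <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0
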