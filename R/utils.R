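# Internal helpers shared across the package.

#' @importFrom data.table data.table := .N setorder as.data.table setDT
NULL

# Derive a reproducible child seed from a user seed and a stage label.
# Keeps results < 2^31 so set.seed() always accepts them.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- poly_hash(paste0("stage:", stage))
  as.integer((abs(seed) + h) %% 2147483629L)
}

# 32-bit-ish polynomial string hash (provenance stamp, not cryptographic).
poly_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  m <- 2147483647  # 2^31 - 1, keeps the accumulator exactly representable
  for (b in bytes) h <- (h * 33 + b) %% m
  h
}

#' Provenance hash of a configuration object
#'
#' Deterministic 8-hex-digit stamp of any R object (via `deparse`), used to
#' mark every table a pipeline run emits so outputs can be traced to the
#' configuration that produced them.
#'
#' @param x any R object.
#' @return character scalar, eight hex digits.
#' @export
config_hash <- function(x) {
  sprintf("%08x", poly_hash(deparse(x)))
}

# Stable centered running mean with shrinking windows at the edges.
# Window for index i is [i - floor((w-1)/2), i + ceiling((w-1)/2)],
# clipped to [1, n].
#' Centered running-window mean
#'
#' Moving average along a vector already sorted by the key of interest
#' (turnover rank, enrichment delta, ...). Windows shrink near the edges
#' rather than dropping values, so the output has the same length as the
#' input.
#'
#' @param x numeric vector.
#' @param w nominal window size in elements (`1 <= w <= length(x)`).
#' @return numeric vector of running means, same length as `x`.
#' @examples
#' running_window(1:10, 3)
#' @export
running_window <- function(x, w) {
  n <- length(x)
  if (!is.numeric(w) || length(w) != 1 || w < 1 || w != floor(w)) {
    stop("`w` must be a positive integer")
  }
  if (w > n) stop("window size `w` (", w, ") exceeds series length (", n, ")")
  lo <- pmax(1L, seq_len(n) - floor((w - 1) / 2))
  hi <- pmin(n, seq_len(n) + ceiling((w - 1) / 2))
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# messagef to stderr with a level prefix; every masking/filtering step logs
# counts through this.
pc_log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}
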