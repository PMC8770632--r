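#' @keywords internal
"_PACKAGE"

# Percentile threshold shared by edge filtering and expression filtering.
# Linear interpolation between order statistics (quantile type 7).
percentile_threshold <- function(x, percentile) {
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 100) {
    stop("`percentile` must be a single number strictly between 0 and 100",
         call. = FALSE)
  }
  stats::quantile(x, probs = percentile / 100, type = 7, names = FALSE,
                  na.rm = TRUE)
}

# Deterministic per-task seed derived from a master seed and a counter,
# kept inside the 32-bit integer range. Large multiplier decorrelates
# streams of adjacent master seeds.
derive_seed <- function(master_seed, counter) {
  s <- (as.double(master_seed) * 48271 + as.double(counter) * 16807) %%
    2147483629
  as.integer(s) + 1L
}

# Normalize gene symbols: trim whitespace, uppercase.
normalize_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
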