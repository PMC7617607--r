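# internal numerical helpers

#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic per-stream seeds derived from a single master seed.
# stream separates purposes (1 = variant metadata, 2 = shared cohort-overlap
# noise, 3 = per-trait draws); index is the region or trait counter, so adding
# a trait at the end of a configuration never perturbs earlier traits.
#' @keywords internal
derive_seed <- function(seed, stream, index = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 1000003 +
                as.numeric(index) * 7907) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
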