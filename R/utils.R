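#' Numerically stable softmax
#'
#' @param x numeric vector of scores.
#' @return probability vector summing to 1.
#' @export
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a 31-bit sub-seed from a base seed and a string key, so that
# per-subject randomness is reproducible and independent of call order.
derive_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}
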