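# Internal numeric helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf for empty input
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic child seeds: one user-facing integer fans out per stage.
# Offsets are fixed so stages stay independent; result kept inside 32-bit
# integer range.
child_seed <- function(seed, offset) {
  s <- (as.numeric(seed) + as.numeric(offset)) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
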