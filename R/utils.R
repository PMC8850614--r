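# internal helpers

SIR_LEVELS <- c("S", "I", "R")

# Deterministic derivation of named sub-seeds from one user seed.
# Keeps every derived seed in [1, 2^31 - 2]; exact in double arithmetic.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% m
  s <- abs(seed) %% m
  s <- (s * 48271) %% m
  s <- (s + h) %% m
  as.integer(s %% (m - 1) + 1)
}

sir_to_int <- function(sir) {
  if (is.numeric(sir)) return(as.integer(sir))
  out <- match(as.character(sir), SIR_LEVELS) - 1L
  if (anyNA(out)) stop("sir states must be one of S, I, R", call. = FALSE)
  out
}

int_to_sir <- function(code) {
  factor(SIR_LEVELS[code + 1L], levels = SIR_LEVELS)
}

with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("%s must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}
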