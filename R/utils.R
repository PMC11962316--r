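# Internal helpers shared across modules.

# Round half up: floor(x + 0.5). Used for every split / subsample size so
# the arithmetic on printed corpus totals is reproduced exactly.
round_half_up <- function(x) floor(x + 0.5)

# Deterministic 31-bit polynomial string hash (UTF-8 code points).
# Used to derive per-sentence RNG seeds and cache keys; stable across
# platforms because it only uses double-precision modular arithmetic.
str_hash <- function(x) {
  h <- 0
  for (cp in utf8ToInt(enc2utf8(x))) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

# Combine a base seed with extra string context into a reproducible
# 31-bit seed for withr::with_seed().
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "")
  as.integer((seed + str_hash(parts)) %% 2147483647)
}

# substr() on code points with 0-based half-open offsets.
substr_cp <- function(text, start, end) {
  substr(enc2utf8(text), start + 1L, end)
}

n_cp <- function(text) nchar(enc2utf8(text), type = "chars")

`%||%` <- function(a, b) if (is.null(a)) b else a
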