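# Internal helpers shared across modules.

# C-locale string sort, used wherever an ordering must be reproducible
# across platforms and locales.
.rsort <- function(x) sort(x, method = "radix")

# Multi-key deterministic order: descending numeric first key, ascending
# C-locale string second key.
.order_score_key <- function(score, key) {
  order(score, key, decreasing = c(TRUE, FALSE), method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit FNV-1a over a string, in double arithmetic (R has no unsigned
# 32-bit integers); used to stamp CLI outputs with a config fingerprint.
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(s))) {
    lo <- h %% 256
    h <- h - lo + bitwXor(lo, b %% 256)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + (h1 * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
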