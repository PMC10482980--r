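# formatting helpers shared by the print methods and the report writer

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.035 -> 0.04), the convention
#' used in the human-readable reports; base `round()` rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# fixed-decimal formatting with half-up rounding
.fmt_num <- function(x, digits) sprintf("%.*f", digits, round_half_up(x, digits))

# p to three decimals, "< 0.001" when positive but rounding to zero
.fmt_p <- function(p) {
  if (is.na(p)) return("NA")
  r <- round_half_up(p, 3)
  if (r < 0.001 && p > 0) "< 0.001" else sprintf("%.3f", r)
}

# w to two decimals, "< 0.01" when positive but rounding to zero
.fmt_w <- function(w) {
  if (is.na(w)) return("= NA")
  r <- round_half_up(w, 2)
  if (r < 0.01 && w > 0) "< 0.01" else sprintf("= %.2f", r)
}

# small FNV-1a hash for provenance blocks (hex string)
.fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keeps h a double
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit multiply in two 16-bit halves to stay exact in doubles
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
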