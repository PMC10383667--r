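# Internal helpers shared across modules.

# round-half-away-from-zero; base round() is banker's rounding
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Largest-remainder integer allocation
#'
#' Splits `total` into integer counts proportional to `weights`, using the
#' largest-remainder (Hamilton) method so the counts always sum to `total`.
#' Ties in the remainders are broken by position.
#'
#' @param weights non-negative numeric vector of proportions or weights.
#' @param total non-negative integer to allocate.
#' @return integer vector of the same length as `weights` summing to `total`.
#' @keywords internal
alloc_largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), sum(weights) > 0, total >= 0)
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  rem <- as.integer(total - sum(base))
  if (rem > 0L) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Deterministic fan-out of a master seed into per-component substreams.
# Polynomial string hash mod (2^31 - 1); keeps derived seeds valid 32-bit
# integers and independent of evaluation order.
derive_seed <- function(master, ...) {
  parts <- paste(c(as.character(master), vapply(list(...), as.character, "")),
                 collapse = "|")
  h <- 17
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

stop_ibdsig <- function(msg, class) {
  stop(structure(class = c(class, "ibdsig_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
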