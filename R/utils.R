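# Internal helpers shared across modules.

#' Round half-up to a number of decimal places
#'
#' Published contingency tables in this field report percentages rounded
#' half-up to one decimal (40/128 -> 31.3%); base `round()` rounds half to
#' even and would print 31.2. Used wherever rates are rendered.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(100 * 40 / 128, 1)  # 31.3
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-12) / scale
}

# format a fraction as a 1-dp percentage string ("31.3%"); NA -> "NA"
fmt_pct <- function(frac, digits = 1) {
  ifelse(is.na(frac), "NA",
         paste0(formatC(round_half_up(100 * frac, digits),
                        format = "f", digits = digits), "%"))
}

# stop() with a consistent prefix so pipeline logs can attribute failures
abort_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

assert_fraction <- function(x, what, stage = "validate") {
  bad <- !is.finite(x) | x < 0 | x > 1
  if (any(bad)) {
    abort_stage(stage, sprintf("%s must lie in [0,1]; offending values: %s",
                               what, paste(utils::head(x[bad], 5), collapse = ", ")))
  }
  invisible(x)
}

# Derive a reproducible sub-seed from a master seed and a stage label so
# every sub-generator of a simulation (and every replicate of a screen) is
# independently reproducible. Kept strictly below 2^31-1.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# 31-bit polynomial rolling hash over a character scalar; used for config
# hashes in run manifests (a change-detection fingerprint, not cryptographic).
config_hash <- function(x) {
  h <- 17
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
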