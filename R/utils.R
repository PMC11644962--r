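#' @keywords internal
"_PACKAGE"

# Round half away from zero to pixel centres (base round() is banker's).
round_half_up <- function(x) floor(x + 0.5)

# Deterministic sub-seed for independent random components of one run.
# Kept inside 32-bit signed range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + 97 * stream) %% 2147483647)
}

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
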