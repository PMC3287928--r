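# Condition helpers: every user-facing failure carries a class so callers
# (and the pipeline driver) can distinguish configuration, data, structural
# and numerical problems.

synthcorr_abort <- function(class, msg) {
  cond <- structure(
    class = c(class, "synthcorr_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

stop_config <- function(msg) synthcorr_abort("synthcorr_config_error", msg)
stop_data <- function(msg) synthcorr_abort("synthcorr_data_error", msg)
stop_structural <- function(msg) synthcorr_abort("synthcorr_structural_error", msg)
stop_numerical <- function(msg) synthcorr_abort("synthcorr_numerical_error", msg)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stage seed from a base seed; keeps results reproducible while
# decoupling the RNG streams of independent pipeline stages.  Offsets are
# small so derived seeds stay well inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}
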