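# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_quant <- function(...) stop(..., call. = FALSE)

is_count_scalar <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# integral within floating tolerance (counts read from text or DICOM)
check_integral <- function(x, what) {
  if (any(abs(x - round(x)) > 1e-9)) {
    stop_quant(what, ": pixel values must be integral counts")
  }
  round(x)
}

# deterministic child seeds derived from one master seed (kept < 2^31)
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483629
}

round1 <- function(x) round(x, 1)
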