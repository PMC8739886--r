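`%||%` <- function(a, b) if (is.null(a)) b else a

softmax_rows <- function(x) {
  mx <- apply(x, 1L, max)
  ex <- exp(x - mx)
  ex / rowSums(ex)
}

fmt_full <- function(x) sprintf("%.17g", x)
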