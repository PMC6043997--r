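`%||%` <- function(a, b) if (is.null(a)) b else a

np_msg <- function(..., verbose = getOption("netprio.verbose", FALSE)) {
  if (isTRUE(verbose)) message("netprio: ", ...)
  invisible(NULL)
}

np_stop <- function(...) stop(..., call. = FALSE)

## deterministic lexicographic ordering, independent of the session locale
lex_order <- function(x) order(x, method = "radix")

lex_sort <- function(x) x[lex_order(x)]

## derive a bounded child seed from a master seed (kept < 2^31)
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7919L
}
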