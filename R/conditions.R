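# structured conditions so callers can distinguish failure modes
hap_error <- function(class, message, ...) {
  structure(
    class = c(paste0("hap_", class), "hap_error", "error", "condition"),
    list(message = message, ...)
  )
}

# signalled when an estimator has no evidence (zero denominator); the
# traversal maps this onto a hole
hap_no_evidence <- function(message, site = NA_integer_) {
  hap_error("no_evidence", message, site = site)
}
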