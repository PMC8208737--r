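#' Symbol alphabet for haplotype recovery
#'
#' The observable alphabet is `A, C, G, T, N, -`, where `-` denotes a
#' deletion in the read relative to the contig. Insertions are not modelled.
#' Internally the alphabet is extended with a terminal sentinel (rendered
#' `"$"`) that links the last variant site covered by a read to a virtual
#' next column, so that the number of reads spanning a site is recoverable
#' from the matrix alone. The sentinel never appears in user-facing
#' haplotype output and is rejected in read observations.
#'
#' @return `hap_symbols()` returns the six observable symbols in their
#'   canonical order (also the deterministic tie-break order used by the
#'   traversal); `hap_sentinel()` returns the terminal sentinel.
#' @export
hap_symbols <- function() c("A", "C", "G", "T", "N", "-")

#' @rdname hap_symbols
#' @export
hap_sentinel <- function() "$"

# full internal alphabet: observable symbols then the sentinel (index 7)
.hap_alphabet <- function() c(hap_symbols(), hap_sentinel())

.SENTINEL_IDX <- 7L
.N_SYM <- 7L

# map symbol characters to internal indices 1..7; error on unknown symbols
.sym_index <- function(symbols, allow_sentinel = FALSE) {
  idx <- match(symbols, .hap_alphabet())
  if (anyNA(idx)) {
    stop(hap_error("invalid_symbol", sprintf(
      "invalid symbol(s): %s",
      paste(unique(symbols[is.na(idx)]), collapse = ", ")
    )))
  }
  if (!allow_sentinel && any(idx == .SENTINEL_IDX)) {
    stop(hap_error("invalid_symbol",
                   "the terminal sentinel is internal and not a legal observation symbol"))
  }
  idx
}
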