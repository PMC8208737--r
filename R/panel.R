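#' Variant panel: the ordered SNV sites of a contig region
#'
#' A variant panel fixes the frame of reference for haplotype recovery: the
#' contig, the region of interest on it, and the strictly increasing list of
#' 1-based genomic positions treated as single nucleotide variant (SNV)
#' sites. Matrix/site index `i` (1..n) maps to `positions[i]`.
#'
#' @param contig Contig (reference sequence) name.
#' @param positions Integer vector of 1-based variant positions; must be
#'   unique and is sorted ascending.
#' @param region_start,region_end 1-based inclusive bounds of the region of
#'   interest; default to the range of `positions`.
#' @return An object of class `variant_panel` with fields `contig`,
#'   `region_start`, `region_end`, `positions` and `n`.
#' @examples
#' variant_panel("contig1", c(11L, 21L, 31L, 41L))
#' @export
variant_panel <- function(contig, positions,
                          region_start = min(positions),
                          region_end = max(positions)) {
  stopifnot(is.character(contig), length(contig) == 1L, nzchar(contig))
  positions <- as.integer(positions)
  if (length(positions) == 0L) {
    stop(hap_error("empty_panel", "a variant panel needs at least one position"))
  }
  if (anyDuplicated(positions)) {
    stop(hap_error("bad_panel", "variant positions must be unique"))
  }
  positions <- sort(positions)
  region_start <- as.integer(region_start)
  region_end <- as.integer(region_end)
  if (region_start > region_end ||
      positions[1L] < region_start || positions[length(positions)] > region_end) {
    stop(hap_error("bad_panel", "all positions must fall inside [region_start, region_end]"))
  }
  structure(
    list(contig = contig, region_start = region_start, region_end = region_end,
         positions = positions, n = length(positions)),
    class = "variant_panel"
  )
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("variant_panel: %d site(s) on %s:%d-%d\n",
              x$n, x$contig, x$region_start, x$region_end))
  cat("  positions:", paste(utils::head(x$positions, 10L), collapse = ", "),
      if (x$n > 10L) "...\n" else "\n")
  invisible(x)
}

#' @export
length.variant_panel <- function(x) x$n

#' Read a variant panel from a VCF file
#'
#' Keeps ALT-bearing records on the target contig within the region bounds;
#' only positions are used (genotypes and alleles are ignored, as the
#' evidence model re-derives per-site symbols from the reads).
#'
#' @param file Path to a VCF file (plain text or bgzipped).
#' @param contig Contig name to select.
#' @param region_start,region_end Optional region bounds; default to the
#'   range of the retained positions.
#' @return A [variant_panel].
#' @export
read_panel_vcf <- function(file, contig, region_start = NULL, region_end = NULL) {
  if (!file.exists(file)) {
    stop(hap_error("io", sprintf("VCF file not found: %s", file)))
  }
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  keep <- fix[, "CHROM"] == contig &
    !is.na(fix[, "ALT"]) & nzchar(fix[, "ALT"]) & fix[, "ALT"] != "."
  pos <- as.integer(fix[keep, "POS"])
  if (!is.null(region_start)) pos <- pos[pos >= region_start]
  if (!is.null(region_end)) pos <- pos[pos <= region_end]
  if (length(pos) == 0L) {
    stop(hap_error("empty_panel", sprintf(
      "no ALT-bearing VCF records for %s in the requested region", contig)))
  }
  variant_panel(contig, unique(pos),
                region_start = if (is.null(region_start)) min(pos) else region_start,
                region_end = if (is.null(region_end)) max(pos) else region_end)
}
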