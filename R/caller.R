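#' Per-column base tallies over a region
#'
#' Pileup summaries used by the naive variant caller: for every covered
#' column in the region, the tally of read bases (deletions as `-`) and the
#' total depth.
#'
#' @param file SAM or BAM file.
#' @param contig Contig name.
#' @param start,end 1-based inclusive region bounds.
#' @return A data.frame with columns `pos`, `symbol`, `count`.
#' @keywords internal
column_tallies <- function(file, contig, start, end) {
  bam <- as_bam_path(file)
  .check_contig(bam, contig)
  which <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
  pp <- Rsamtools::PileupParam(max_depth = 1000000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = TRUE,
                               include_insertions = FALSE)
  sp <- Rsamtools::ScanBamParam(which = which)
  pu <- Rsamtools::pileup(bam, scanBamParam = sp, pileupParam = pp)
  data.frame(pos = pu$pos, symbol = as.character(pu$nucleotide),
             count = pu$count, stringsAsFactors = FALSE)
}

#' Naive per-column variant calling
#'
#' Screens every alignment column of the region and emits the positions
#' where reads disagree on the base: at least two distinct symbols (`N`
#' excluded, deletions counted as `-`) each supported by at least
#' `min_minor_count` reads, at depth at least `min_depth`. This is the
#' simplest admissible notion of a variant site; any external caller's VCF
#' can be supplied instead.
#'
#' @param file SAM or BAM file.
#' @param contig Contig name.
#' @param start,end 1-based inclusive region bounds.
#' @param min_depth Minimum column depth (default 2).
#' @param min_minor_count Minimum support for each of the two top symbols
#'   (default 1, the literal disagreement rule).
#' @return A [variant_panel]; attribute `"tallies"` carries the per-column
#'   summaries of the called sites. A region with no disagreeing column
#'   yields a warning and an error of class `hap_empty_panel` is avoided by
#'   returning `NULL`.
#' @export
call_variants <- function(file, contig, start, end,
                          min_depth = 2L, min_minor_count = 1L) {
  stopifnot(start >= 1L, end >= start)
  tal <- column_tallies(file, contig, start, end)
  if (nrow(tal) == 0L) {
    warning("no aligned coverage in the region; empty panel")
    return(NULL)
  }
  tal_informative <- tal[tal$symbol != "N", , drop = FALSE]
  depth <- tapply(tal$count, tal$pos, sum)
  called <- vapply(split(tal_informative, tal_informative$pos), function(cols) {
    sum(cols$count >= min_minor_count) >= 2L
  }, logical(1))
  pos <- as.integer(names(called))[called]
  pos <- pos[depth[as.character(pos)] >= min_depth]
  if (length(pos) == 0L) {
    warning("no variant column found in the region; empty panel")
    return(NULL)
  }
  panel <- variant_panel(contig, sort(pos), region_start = start,
                         region_end = end)
  attr(panel, "tallies") <- tal[tal$pos %in% pos, , drop = FALSE]
  panel
}

#' Write a minimal VCF for a called panel
#'
#' One record per site: REF is the majority base among the tallied symbols
#' (falling back to `N` when the majority symbol is a deletion), ALT lists
#' the remaining symbols meeting the caller's support threshold (deletions
#' rendered as the missing-allele `*`), and INFO carries the depth.
#'
#' @param panel A [variant_panel] returned by [call_variants()] (with its
#'   `"tallies"` attribute), or any panel plus an explicit `tallies`
#'   data.frame (`pos`, `symbol`, `count`).
#' @param file Output path.
#' @param tallies Optional override of the tallies attribute.
#' @param min_minor_count ALT inclusion threshold (default 1).
#' @return `file`, invisibly.
#' @export
write_panel_vcf <- function(panel, file, tallies = attr(panel, "tallies"),
                            min_minor_count = 1L) {
  stopifnot(inherits(panel, "variant_panel"))
  if (is.null(tallies)) {
    stop(hap_error("bad_input", "per-column tallies are required to write a VCF"))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Column depth\">",
    sprintf("##contig=<ID=%s>", panel$contig),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- vapply(panel$positions, function(p) {
    cols <- tallies[tallies$pos == p & tallies$symbol != "N", , drop = FALSE]
    cols <- cols[order(-cols$count, cols$symbol), , drop = FALSE]
    ref <- cols$symbol[1L]
    if (ref == "-") ref <- "N"
    alt <- cols$symbol[-1L][cols$count[-1L] >= min_minor_count]
    alt[alt == "-"] <- "*"
    dp <- sum(tallies$count[tallies$pos == p])
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d",
            panel$contig, p, ref,
            if (length(alt)) paste(alt, collapse = ",") else ".", dp)
  }, character(1))
  writeLines(c(header, recs), file)
  invisible(file)
}
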