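#' Open an alignment file as BAM, converting SAM on the fly
#'
#' @param file Path to a SAM (`.sam`) or BAM (`.bam`) file.
#' @return Path to a BAM file (a temporary one for SAM input).
#' @keywords internal
as_bam_path <- function(file) {
  if (!file.exists(file)) {
    stop(hap_error("io", sprintf("alignment file not found: %s", file)))
  }
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                     indexDestination = TRUE)
  } else {
    file
  }
}

.check_contig <- function(bam, contig) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!(contig %in% names(hdr))) {
    stop(hap_error("contig_mismatch", sprintf(
      "contig '%s' absent from alignment header (targets: %s)",
      contig, paste(names(hdr), collapse = ", "))))
  }
  invisible(hdr[[contig]])
}

#' Extract per-read symbol observations over a variant panel
#'
#' Reduces every primary alignment overlapping the panel's region to the
#' symbols it shows at the panel sites its aligned span covers. Read bases
#' are laid out in reference space first, so a deletion in the read over a
#' panel site yields `-` and insertions are dropped; bases outside the
#' alphabet become `N`. Unmapped, secondary and supplementary records are
#' skipped, as are records failing the mapping-quality or
#' minimum-covered-sites filters.
#'
#' @param file SAM or BAM file aligned to the panel's contig.
#' @param panel A [variant_panel].
#' @param min_mapq Minimum mapping quality (default 0: keep everything).
#' @param min_sites Minimum number of panel sites a read must cover
#'   (default 1).
#' @return A list of [read_observation]; attribute `"stats"` carries counts
#'   of kept and skipped records.
#' @export
extract_observations <- function(file, panel, min_mapq = 0L, min_sites = 1L) {
  stopifnot(inherits(panel, "variant_panel"))
  bam <- as_bam_path(file)
  .check_contig(bam, panel$contig)
  which <- GenomicRanges::GRanges(
    panel$contig,
    IRanges::IRanges(panel$region_start, panel$region_end))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(what = c("mapq", "seq"), flag = flag,
                                   which = which)
  gal <- GenomicAlignments::readGAlignments(bam, param = param,
                                            use.names = TRUE)
  stats <- c(kept = 0L, skipped_mapq = 0L, skipped_sites = 0L,
             malformed = 0L)
  obs <- vector("list", length(gal))
  if (length(gal)) {
    # read bases in reference coordinates: deletions -> '-', insertions gone
    ref_seq <- GenomicAlignments::sequenceLayer(
      S4Vectors::mcols(gal)$seq, GenomicAlignments::cigar(gal),
      from = "query", to = "reference", D.letter = "-", N.letter = "-")
    starts <- GenomicAlignments::start(gal)
    ends <- GenomicAlignments::end(gal)
    mapq <- S4Vectors::mcols(gal)$mapq
    ids <- names(gal) %||% as.character(seq_along(gal))
    for (k in seq_along(gal)) {
      q <- mapq[k]
      if (!is.na(q) && q < min_mapq) {
        stats["skipped_mapq"] <- stats["skipped_mapq"] + 1L
        next
      }
      covered <- which(panel$positions >= starts[k] & panel$positions <= ends[k])
      if (length(covered) < min_sites || length(covered) == 0L) {
        stats["skipped_sites"] <- stats["skipped_sites"] + 1L
        next
      }
      # symbol at each covered site
      sym <- tryCatch({
        offs <- panel$positions[covered] - starts[k] + 1L
        ch <- strsplit(as.character(ref_seq[[k]]), "")[[1L]][offs]
        ch[!(ch %in% hap_symbols())] <- "N"
        read_observation(ids[k], covered[1L], ch)
      }, error = function(e) {
        stats["malformed"] <<- stats["malformed"] + 1L
        NULL
      })
      if (!is.null(sym)) {
        stats["kept"] <- stats["kept"] + 1L
        obs[[k]] <- sym
      }
    }
  }
  obs <- obs[!vapply(obs, is.null, logical(1))]
  attr(obs, "stats") <- stats
  obs
}

#' Build the co-occurrence matrix from a stream of observations
#'
#' Folds [observe_read()] over all observations in one vectorised pass; the
#' result is independent of observation order.
#'
#' @param observations List of [read_observation].
#' @param panel A [variant_panel] (fixes the site count).
#' @return A [cooc_matrix].
#' @export
build_matrix <- function(observations, panel) {
  stopifnot(inherits(panel, "variant_panel"))
  n <- panel$n
  H <- cooc_matrix(n)
  if (length(observations) == 0L) return(H)
  bad <- !vapply(observations, inherits, logical(1), "read_observation")
  if (any(bad)) stop(hap_error("bad_input", "observations must be read_observation objects"))
  last <- vapply(observations, function(o) o$last_index, integer(1))
  first <- vapply(observations, function(o) o$first_index, integer(1))
  if (any(first < 1L) || any(last > n)) {
    stop(hap_error("panel_mismatch",
                   "an observation covers sites outside the panel"))
  }
  idx <- unlist(lapply(observations, function(o) .obs_linear_indices(n, o)))
  add <- tabulate(idx, nbins = length(H$counts))
  H$counts <- H$counts + array(add, dim = dim(H$counts),
                               dimnames = dimnames(H$counts))
  H
}
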