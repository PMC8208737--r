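#' Write recovered haplotypes as FASTA
#'
#' One record per recovered path, over the SNV sites only; when a reference
#' backbone is supplied a second file splices each path's alleles into the
#' backbone to give full-length sequences (deleted sites are dropped).
#'
#' @param result A [recover_all()] result.
#' @param panel The [variant_panel] the traversal ran on.
#' @param file Output FASTA of site-symbols.
#' @param reference Optional backbone sequence (character string) covering
#'   `panel$region_start..panel$region_end`.
#' @param full_file Output path for the spliced full-length FASTA (used only
#'   when `reference` is given).
#' @return Invisibly, the path(s) written.
#' @export
write_haplotypes_fasta <- function(result, panel, file, reference = NULL,
                                   full_file = NULL) {
  stopifnot(inherits(result, "traversal_result"), inherits(panel, "variant_panel"))
  haps <- result$haplotypes
  nm <- sprintf("haplotype_rank%d iteration=%d log10_likelihood=%.6f lambda=%.6f",
                seq_along(haps),
                vapply(haps, function(h) h$iteration, integer(1)),
                vapply(haps, function(h) h$log10_likelihood, numeric(1)),
                vapply(haps, function(h) h$lambda_used, numeric(1)))
  seqs <- vapply(haps, function(h) paste(h$symbols, collapse = ""), character(1))
  # site-level output may contain '-' (deletion) and 'N'; keep as plain text
  writeLines(as.vector(rbind(paste0(">", nm), seqs)), file)
  written <- file
  if (!is.null(reference) && length(haps)) {
    stopifnot(!is.null(full_file))
    ref <- strsplit(reference, "")[[1L]]
    offs <- panel$positions - panel$region_start + 1L
    full <- vapply(haps, function(h) {
      s <- ref
      s[offs] <- h$symbols
      paste(s[s != "-"], collapse = "")
    }, character(1))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(full, nm)), full_file)
    written <- c(written, full_file)
  }
  invisible(written)
}

#' Write the haplotype ranking table
#'
#' @param result A [recover_all()] result.
#' @param file Output TSV with columns `rank`, `haplotype`, `iteration`,
#'   `log10_likelihood`, `lambda`.
#' @return `file`, invisibly.
#' @export
write_ranking_tsv <- function(result, file) {
  haps <- result$haplotypes
  df <- data.frame(
    rank = seq_along(haps),
    haplotype = vapply(haps, function(h) paste(h$symbols, collapse = ""),
                       character(1)),
    iteration = vapply(haps, function(h) h$iteration, integer(1)),
    log10_likelihood = vapply(haps, function(h) h$log10_likelihood, numeric(1)),
    lambda = vapply(haps, function(h) h$lambda_used, numeric(1)))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' End-to-end haplotype recovery
#'
#' Wires the full pipeline: read the panel (from VCF, or call variants
#' naively when no VCF is given), extract per-read observations, build the
#' co-occurrence matrix, run iterated greedy traversal, and write the
#' outputs (site-level FASTA, optional full-length FASTA, ranking TSV,
#' machine-readable JSON summary).
#'
#' @param alignment SAM/BAM path.
#' @param contig Contig name.
#' @param start,end Region bounds (1-based inclusive).
#' @param vcf Optional VCF of variant positions; `NULL` invokes
#'   [call_variants()].
#' @param out_dir Output directory (created if needed).
#' @param reference_fasta Optional backbone FASTA for full-length output.
#' @param config A [traversal_config()].
#' @param min_mapq,min_sites Read filters for [extract_observations()].
#' @param min_depth,min_minor_count Caller thresholds (when `vcf` is NULL).
#' @return Invisibly, a list: `result` ([recover_all()] output), `panel`,
#'   `paths` of written artifacts, and `exit_status` (0 = at least one
#'   haplotype recovered; 2 = hole at start; 3 = empty panel; 4 = I/O
#'   failure).
#' @export
run_recover <- function(alignment, contig, start, end, vcf = NULL,
                        out_dir = ".", reference_fasta = NULL,
                        config = traversal_config(),
                        min_mapq = 0L, min_sites = 1L,
                        min_depth = 2L, min_minor_count = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_file <- file.path(out_dir, "run_summary.json")
  fail <- function(status, stage, message) {
    jsonlite::write_json(
      list(status = status, stage = stage, message = message),
      summary_file, auto_unbox = TRUE)
    out <- list(result = NULL, panel = NULL, paths = list(summary = summary_file),
                exit_status = status)
    invisible(out)
  }
  panel <- tryCatch({
    if (is.null(vcf)) {
      call_variants(alignment, contig, start, end,
                    min_depth = min_depth, min_minor_count = min_minor_count)
    } else {
      read_panel_vcf(vcf, contig, start, end)
    }
  }, hap_io = function(e) e, hap_empty_panel = function(e) NULL,
     hap_contig_mismatch = function(e) e)
  if (inherits(panel, "condition")) {
    status <- if (inherits(panel, "hap_io")) 4L else 4L
    return(fail(status, "panel", conditionMessage(panel)))
  }
  if (is.null(panel)) return(fail(3L, "panel", "empty variant panel"))
  obs <- tryCatch(
    extract_observations(alignment, panel, min_mapq = min_mapq,
                         min_sites = min_sites),
    hap_error = function(e) e)
  if (inherits(obs, "condition")) {
    return(fail(4L, "ingest", conditionMessage(obs)))
  }
  H <- build_matrix(obs, panel)
  result <- recover_all(H, config)
  paths <- list(summary = summary_file,
                fasta = file.path(out_dir, "haplotypes.fasta"),
                ranking = file.path(out_dir, "ranking.tsv"))
  reference <- NULL
  if (!is.null(reference_fasta)) {
    refset <- Biostrings::readDNAStringSet(reference_fasta)
    idx <- match(contig, sub("\\s.*$", "", names(refset)))
    if (!is.na(idx)) {
      reference <- as.character(Biostrings::subseq(
        refset[[idx]], panel$region_start,
        min(panel$region_end, Biostrings::nchar(refset[[idx]]))))
      paths$full_fasta <- file.path(out_dir, "haplotypes_full.fasta")
    }
  }
  write_haplotypes_fasta(result, panel, paths$fasta, reference = reference,
                         full_file = paths$full_fasta)
  write_ranking_tsv(result, paths$ranking)
  status <- if (length(result$haplotypes) >= 1L) 0L
            else if (result$termination_reason == "hole_at_start") 2L
            else 2L
  jsonlite::write_json(
    list(status = status, stage = "done",
         contig = contig, region = c(start, end), n_sites = panel$n,
         n_observations = length(obs),
         ingest_stats = as.list(attr(obs, "stats")),
         n_haplotypes = length(result$haplotypes),
         termination_reason = result$termination_reason,
         lookback = config$lookback, max_iterations = config$max_iterations,
         version = as.character(utils::packageVersion("haplopath"))),
    summary_file, auto_unbox = TRUE)
  invisible(list(result = result, panel = panel, paths = paths,
                 exit_status = status))
}
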