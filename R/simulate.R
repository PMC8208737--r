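# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic haplotype community
#'
#' Describes a gene-length region carried by `K` community members at
#' unequal abundances, differing only at planted SNV sites, to be sequenced
#' into error-prone reads. Defaults describe the study conditions the
#' package is validated under: a 1 kb region with 15 biallelic SNVs, reads
#' long enough to span several adjacent sites, and 1% substitution error.
#'
#' @param region_length Region length in bases (default 1000).
#' @param n_snvs Number of planted SNV sites (default 15).
#' @param K Number of haplotypes (default 2).
#' @param abundances K proportions summing to 1. Default: linearly
#'   decreasing weights `K:1` normalised to 1, giving distinctly unequal
#'   abundances.
#' @param snv_positions Explicit 1-based positions, or `NULL` to place
#'   sites uniformly at random (without replacement, away from the region's
#'   first/last base).
#' @param alleles Optional `K x n_snvs` character matrix of per-haplotype
#'   symbols; `NULL` draws them at random according to `allele_mode`.
#' @param allele_mode How random alleles are drawn. `"distinct"` (default)
#'   gives every haplotype its own symbol at every site, so each SNV
#'   distinguishes every haplotype pair (requires `K <= 5`; `K = 5` uses
#'   the deletion symbol as the fifth allele). `"biallelic"` draws two
#'   alleles per site (reference base vs one alternative) and assigns them
#'   at random; haplotypes then share alleles at many sites, which is more
#'   realistic but leaves haplotypes locally indistinguishable wherever
#'   they agree across a window longer than the read span.
#' @param read_length Read length in bases (default 250).
#' @param coverage Mean community depth; haplotype `k` is sequenced to
#'   `coverage * abundances[k]` (default 100).
#' @param error_rate Per-base substitution probability (default 0.01).
#' @param deletion_prob Probability that a drawn alternative allele is a
#'   deletion rather than a base (default 0).
#' @param contig Contig name used in all outputs.
#' @param seed RNG seed; all outputs are byte-deterministic under it.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(region_length = 1000L, n_snvs = 15L, K = 2L,
                           abundances = NULL, snv_positions = NULL,
                           alleles = NULL,
                           allele_mode = c("distinct", "biallelic"),
                           read_length = 250L,
                           coverage = 100, error_rate = 0.01,
                           deletion_prob = 0, contig = "region1",
                           seed = 1L) {
  allele_mode <- match.arg(allele_mode)
  K <- as.integer(K)
  stopifnot(K >= 1L, n_snvs >= 1L, region_length >= n_snvs + 2L,
            read_length >= 1L, coverage > 0, error_rate >= 0, error_rate <= 1,
            deletion_prob >= 0, deletion_prob <= 1)
  if (read_length > region_length) {
    stop(hap_error("bad_spec", "read_length exceeds region_length"))
  }
  if (is.null(abundances)) abundances <- (K:1) / sum(K:1)
  if (length(abundances) != K || abs(sum(abundances) - 1) > 1e-9 ||
      any(abundances <= 0)) {
    stop(hap_error("bad_spec", "abundances must be K positive proportions summing to 1"))
  }
  if (!is.null(snv_positions)) {
    snv_positions <- sort(as.integer(snv_positions))
    if (anyDuplicated(snv_positions) || length(snv_positions) != n_snvs ||
        snv_positions[1L] < 2L || snv_positions[n_snvs] > region_length - 1L) {
      stop(hap_error("bad_spec", "snv_positions must be n_snvs unique positions inside the region"))
    }
  }
  if (!is.null(alleles)) {
    alleles <- as.matrix(alleles)
    if (!all(dim(alleles) == c(K, n_snvs)) ||
        !all(alleles %in% hap_symbols())) {
      stop(hap_error("bad_spec", "alleles must be a K x n_snvs matrix over the symbol alphabet"))
    }
  }
  if (is.null(alleles) && allele_mode == "distinct" && K > 5L) {
    stop(hap_error("bad_spec",
                   "allele_mode = 'distinct' supports at most 5 haplotypes; supply alleles or use 'biallelic'"))
  }
  structure(
    list(region_length = as.integer(region_length), n_snvs = as.integer(n_snvs),
         K = K, abundances = abundances, snv_positions = snv_positions,
         alleles = alleles, allele_mode = allele_mode,
         read_length = as.integer(read_length),
         coverage = coverage, error_rate = error_rate,
         deletion_prob = deletion_prob, contig = contig,
         seed = as.integer(seed)),
    class = "community_spec")
}

#' Generate a ground-truthed haplotype community
#'
#' Draws a random reference backbone and `K` haplotypes that differ from it
#' only at the planted SNV sites. When alleles are drawn at random, each
#' site is biallelic (reference base plus one alternative, possibly a
#' deletion), every site is polymorphic across the community, and the draw
#' is repeated until all haplotype pairs are distinguishable.
#'
#' @param spec A [community_spec()].
#' @return An object of class `hap_community`: `spec`, `reference`
#'   (character string), `hap_chars` (`K x region_length` symbol matrix in
#'   reference coordinates, `-` marking deleted bases), `panel`
#'   (a [variant_panel]), `alleles` (`K x n_snvs`), `abundances`.
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  .with_seed(spec$seed, {
    L <- spec$region_length
    n <- spec$n_snvs
    K <- spec$K
    ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    pos <- spec$snv_positions
    if (is.null(pos)) pos <- sort(sample(2:(L - 1L), n))
    alleles <- spec$alleles
    if (is.null(alleles)) {
      if (spec$allele_mode == "distinct" || K == 1L) {
        # every haplotype gets its own symbol at every site; K = 1 just
        # differs from the backbone
        alleles <- matrix("", nrow = K, ncol = n)
        for (s in seq_len(n)) {
          refb <- ref[pos[s]]
          pool <- if (stats::runif(1) < spec$deletion_prob)
            c(setdiff(c("A", "C", "G", "T"), refb), "-")
          else c("A", "C", "G", "T")
          if (K == 5L) pool <- unique(c(pool, "-"))
          if (K == 1L) pool <- setdiff(pool, refb)
          alleles[, s] <- sample(pool, K)
        }
      } else {
        # biallelic sites: reference base vs one alternative, assigned at
        # random; redraw until all haplotype pairs differ somewhere
        for (try in 1:100) {
          alleles <- matrix("", nrow = K, ncol = n)
          for (s in seq_len(n)) {
            refb <- ref[pos[s]]
            alt <- if (stats::runif(1) < spec$deletion_prob) "-"
                   else sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
            repeat {
              draw <- sample(c(refb, alt), K, replace = TRUE)
              if (length(unique(draw)) > 1L) break
            }
            alleles[, s] <- draw
          }
          if (!anyDuplicated(apply(alleles, 1L, paste, collapse = ""))) break
        }
        if (anyDuplicated(apply(alleles, 1L, paste, collapse = ""))) {
          stop(hap_error("bad_spec",
                         "could not draw pairwise-distinguishable haplotypes; supply alleles explicitly"))
        }
      }
    }
    hap_chars <- matrix(rep(ref, each = K), nrow = K)
    hap_chars[, pos] <- alleles
    panel <- variant_panel(spec$contig, pos, region_start = 1L, region_end = L)
    structure(
      list(spec = spec, reference = paste(ref, collapse = ""),
           hap_chars = hap_chars, panel = panel, alleles = alleles,
           abundances = spec$abundances),
      class = "hap_community")
  })
}

#' @export
print.hap_community <- function(x, ...) {
  cat(sprintf("hap_community: %d haplotype(s), %d SNV site(s) over %d bp (%s)\n",
              x$spec$K, x$spec$n_snvs, x$spec$region_length, x$spec$contig))
  cat("  truth alleles over sites:\n")
  for (k in seq_len(x$spec$K)) {
    cat(sprintf("    h%d (%.3f): %s\n", k, x$abundances[k],
                paste(x$alleles[k, ], collapse = "")))
  }
  invisible(x)
}

#' Simulate error-prone reads from a community
#'
#' Reads are drawn per haplotype in proportion to abundance (count =
#' `coverage * abundance * region_length / read_length`, at least 1),
#' with uniform start positions and independent per-base substitution
#' errors. Because read coordinates are known by construction, alignments
#' are emitted directly (deleted haplotype bases become CIGAR `D`
#' operations); no aligner is involved.
#'
#' @param comm A [generate_community()] result.
#' @return A data.frame of reads: `qname`, `hap`, `pos` (1-based leftmost
#'   reference position), `cigar`, `seq`, and `span` (reference span).
#'   Deterministic under the spec seed.
#' @export
simulate_reads <- function(comm) {
  stopifnot(inherits(comm, "hap_community"))
  spec <- comm$spec
  .with_seed(spec$seed + 1L, {
    L <- spec$region_length
    rl <- spec$read_length
    n_reads <- pmax(1L, round(spec$coverage * spec$abundances * L / rl))
    rows <- vector("list", sum(n_reads))
    r <- 0L
    for (k in seq_len(spec$K)) {
      hap <- comm$hap_chars[k, ]
      for (m in seq_len(n_reads[k])) {
        s <- sample.int(L - rl + 1L, 1L)
        seg <- hap[s:(s + rl - 1L)]
        # leading/trailing deletions are not alignable; shrink the span
        keep <- which(seg != "-")
        if (length(keep) == 0L) next
        seg <- seg[keep[1L]:keep[length(keep)]]
        pos <- s + keep[1L] - 1L
        is_base <- seg != "-"
        bases <- seg[is_base]
        err <- stats::runif(length(bases)) < spec$error_rate
        if (any(err)) {
          bases[err] <- vapply(bases[err], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        }
        rl_ops <- rle(ifelse(seg == "-", "D", "M"))
        cigar <- paste0(rl_ops$lengths, rl_ops$values, collapse = "")
        r <- r + 1L
        rows[[r]] <- data.frame(
          qname = sprintf("h%d_r%d", k, m), hap = k, pos = pos,
          cigar = cigar, seq = paste(bases, collapse = ""),
          span = length(seg), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows[seq_len(r)])
  })
}

#' Write community fixtures to standard formats
#'
#' @param comm A [generate_community()] result.
#' @param dir Output directory (created if needed).
#' @param reads Optional [simulate_reads()] table; generated if missing.
#' @return Named list of written paths: `reference_fasta`, `truth_fasta`,
#'   `sites_vcf`, `sam`, `fastq`.
#' @export
write_community <- function(comm, dir, reads = NULL) {
  stopifnot(inherits(comm, "hap_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- comm$spec
  if (is.null(reads)) reads <- simulate_reads(comm)
  ref_fa <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(comm$reference, spec$contig)),
    ref_fa)
  truth <- apply(comm$hap_chars, 1L, function(ch)
    paste(ch[ch != "-"], collapse = ""))
  names(truth) <- sprintf("haplotype_%d abundance=%.4f seed=%d",
                          seq_along(truth), comm$abundances, spec$seed)
  truth_fa <- file.path(dir, "truth.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(truth), truth_fa)
  vcf <- file.path(dir, "sites.vcf")
  .write_sites_vcf(comm, vcf)
  sam <- file.path(dir, "reads.sam")
  write_sam(reads, spec$contig, spec$region_length, sam, seed = spec$seed)
  fq <- file.path(dir, "reads.fastq")
  writeLines(as.vector(rbind(paste0("@", reads$qname), reads$seq, "+",
                             vapply(nchar(reads$seq), function(w)
                               strrep("I", w), character(1)))), fq)
  list(reference_fasta = ref_fa, truth_fasta = truth_fa, sites_vcf = vcf,
       sam = sam, fastq = fq)
}

# minimal VCF of the planted sites (REF = backbone base, ALT = the other
# community alleles; deletions rendered as '*')
.write_sites_vcf <- function(comm, file) {
  spec <- comm$spec
  pos <- comm$panel$positions
  refb <- strsplit(comm$reference, "")[[1L]][pos]
  recs <- vapply(seq_along(pos), function(s) {
    alt <- setdiff(unique(comm$alleles[, s]), refb[s])
    alt[alt == "-"] <- "*"
    if (length(alt) == 0L) alt <- "."
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=.", spec$contig, pos[s], refb[s],
            paste(alt, collapse = ","))
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", spec$contig,
                       spec$region_length),
               sprintf("##source=haplopath-simulate seed=%d", spec$seed),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               recs), file)
  invisible(file)
}

#' Write pre-aligned reads as SAM
#'
#' @param reads A [simulate_reads()] table (`qname`, `pos`, `cigar`, `seq`).
#' @param contig Reference name for the `@SQ` line.
#' @param contig_length Reference length.
#' @param file Output path.
#' @param seed Seed recorded in an `@CO` comment line.
#' @return `file`, invisibly.
#' @export
write_sam <- function(reads, contig, contig_length, file, seed = NA_integer_) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_length),
              sprintf("@CO\thaplopath-simulate seed=%s", seed))
  reads <- reads[order(reads$pos), , drop = FALSE]
  recs <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, contig, reads$pos, reads$cigar, reads$seq,
                  vapply(nchar(reads$seq), function(w) strrep("I", w),
                         character(1)))
  writeLines(c(header, recs), file)
  invisible(file)
}

#' The three-read worked example
#'
#' A fixed toy instance used throughout the documentation and tests: four
#' biallelic SNV sites on a 60 bp backbone, and three reads whose
#' site-symbols encode `0011`, `0001` and `0100` (0 = `A`, 1 = `C`). The
#' adjacent-evidence graph of this instance famously admits the unsupported
#' paths `0000` and `0101`, which the lookback-conditioned traversal never
#' emits.
#'
#' @param dir Directory to write the fixture into (default: a tempdir).
#' @return A list: `sam`, `vcf`, `reference_fasta` paths; `panel`; `reads`
#'   (the three site-symbol strings); `encoding` (symbol for 0 and 1).
#' @export
toy_alignment <- function(dir = tempfile("toy")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- 60L
  positions <- c(11L, 21L, 31L, 41L)
  ref <- rep(c("G", "T"), length.out = L)
  ref[positions] <- "A"
  reads01 <- c(r1 = "0011", r2 = "0001", r3 = "0100")
  enc <- c(`0` = "A", `1` = "C")
  rows <- lapply(seq_along(reads01), function(k) {
    seg <- ref[1:50]
    sym <- enc[strsplit(reads01[[k]], "")[[1L]]]
    seg[positions] <- sym
    data.frame(qname = names(reads01)[k], hap = NA_integer_, pos = 1L,
               cigar = "50M", seq = paste(seg, collapse = ""), span = 50L,
               stringsAsFactors = FALSE)
  })
  sam <- file.path(dir, "toy.sam")
  write_sam(do.call(rbind, rows), "toy_contig", L, sam)
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=toy_contig,length=60>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("toy_contig\t%d\t.\tA\tC\t.\tPASS\t.", positions)),
             vcf)
  fa <- file.path(dir, "toy_reference.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(toy_contig = paste(ref, collapse = ""))), fa)
  list(sam = sam, vcf = vcf, reference_fasta = fa,
       panel = variant_panel("toy_contig", positions, 1L, L),
       reads = unname(reads01), encoding = enc)
}

#' Score recovered haplotypes against the truth
#'
#' For every truth haplotype, the identity (fraction of matching SNV-site
#' symbols) of its best-matching recovered path, plus summary counts and
#' the rank correlation between truth abundance and the score ranking of
#' the matched paths.
#'
#' @param comm A [generate_community()] result (or a `K x n` truth allele
#'   matrix).
#' @param result A [recover_all()] result.
#' @return An object of class `recovery_report`: data.frame `per_truth`
#'   (`truth`, `abundance`, `best_identity`, `matched_rank`),
#'   `n_perfect`, `abundance_rank_correlation`, and `no_paths` flag.
#' @export
evaluate_recovery <- function(comm, result) {
  truth <- if (inherits(comm, "hap_community")) comm$alleles else as.matrix(comm)
  abundance <- if (inherits(comm, "hap_community")) comm$abundances
               else rep(NA_real_, nrow(truth))
  stopifnot(inherits(result, "traversal_result"))
  K <- nrow(truth)
  n <- ncol(truth)
  paths <- result$haplotypes
  if (length(paths) == 0L) {
    per <- data.frame(truth = seq_len(K), abundance = abundance,
                      best_identity = 0, matched_rank = NA_integer_)
    return(structure(list(per_truth = per, n_perfect = 0L,
                          abundance_rank_correlation = NA_real_,
                          no_paths = TRUE),
                     class = "recovery_report"))
  }
  if (any(vapply(paths, function(p) length(p$symbols), integer(1)) != n)) {
    stop(hap_error("panel_mismatch",
                   "recovered paths and truth are over different panels"))
  }
  pathmat <- do.call(rbind, lapply(paths, function(p) p$symbols))
  per <- do.call(rbind, lapply(seq_len(K), function(k) {
    ident <- rowMeans(sweep(pathmat, 2L, truth[k, ], FUN = "=="))
    best <- which.max(ident)
    data.frame(truth = k, abundance = abundance[k],
               best_identity = ident[best], matched_rank = best)
  }))
  matched <- per[per$best_identity == 1, , drop = FALSE]
  rc <- if (nrow(matched) >= 2L && !anyNA(matched$abundance)) {
    suppressWarnings(stats::cor(matched$abundance, -matched$matched_rank,
                                method = "spearman"))
  } else NA_real_
  structure(list(per_truth = per, n_perfect = sum(per$best_identity == 1),
                 abundance_rank_correlation = rc, no_paths = FALSE),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: %d/%d truth haplotype(s) recovered exactly\n",
              x$n_perfect, nrow(x$per_truth)))
  print(x$per_truth, row.names = FALSE)
  if (!is.na(x$abundance_rank_correlation)) {
    cat(sprintf("  abundance/rank correlation: %.3f\n",
                x$abundance_rank_correlation))
  }
  invisible(x)
}
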