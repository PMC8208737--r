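#' Pairwise SNV co-occurrence matrix
#'
#' The central evidence structure: a rank-4 tensor `H[alpha, beta, i, j]`
#' counting, over all ingested reads, how often symbol `alpha` at site `i`
#' was observed on the same read as symbol `beta` at site `j > i`. Only the
#' strict upper triangle in `(i, j)` is meaningful; a virtual column `n + 1`
#' holds the terminal-sentinel links recorded after the last site each read
#' covers, which is what makes "number of reads spanning site j" computable
#' from column `(j, j + 1)` alone.
#'
#' Counts start as non-negative integers and become fractional once
#' recovered haplotypes are reweighted (see [reweight()]).
#'
#' @param n Number of variant sites (>= 1).
#' @return An object of class `cooc_matrix` with fields `n` and `counts`
#'   (a dense `7 x 7 x n x (n+1)` array over the sentinel-extended alphabet).
#' @seealso [observe_read()], [build_matrix()], [marginal()], [conditional()]
#' @export
cooc_matrix <- function(n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L)
  ab <- .hap_alphabet()
  counts <- array(0, dim = c(.N_SYM, .N_SYM, n, n + 1L),
                  dimnames = list(alpha = ab, beta = ab, i = NULL, j = NULL))
  structure(list(n = n, counts = counts), class = "cooc_matrix")
}

#' @export
print.cooc_matrix <- function(x, ...) {
  real <- .real_pair_total(x)
  cat(sprintf("cooc_matrix: %d site(s); %.6g real-pair observation(s); %.6g terminal link(s)\n",
              x$n, real, sum(x$counts[, .SENTINEL_IDX, , ])))
  invisible(x)
}

# total evidence over real-symbol pairs (excludes sentinel links)
.real_pair_total <- function(H) {
  sum(H$counts[, -.SENTINEL_IDX, , , drop = FALSE])
}

.check_pair_indices <- function(H, i, j) {
  if (any(i < 1L) || any(j > H$n + 1L) || any(j <= i)) {
    stop(hap_error("bad_index", sprintf(
      "co-occurrence indices must satisfy 1 <= i < j <= n + 1 (n = %d)", H$n)))
  }
}

#' Access a single co-occurrence count
#'
#' Strict upper-triangular access: `j <= i` is an error, as is any index
#' outside `1..n + 1`.
#'
#' @param H A [cooc_matrix].
#' @param alpha,beta Symbols (see [hap_symbols()]); `beta` may be the
#'   terminal sentinel.
#' @param i,j Site indices with `i < j`.
#' @return The (possibly fractional) count.
#' @export
cooc_count <- function(H, alpha, beta, i, j) {
  .check_pair_indices(H, i, j)
  a <- .sym_index(alpha)
  b <- .sym_index(beta, allow_sentinel = TRUE)
  H$counts[a, b, i, j]
}

#' Construct a single read observation
#'
#' A read reduced to the symbols it shows at the contiguous run of panel
#' sites its alignment spans. A panel site inside the aligned span where the
#' alignment shows a deletion carries `-`; an unknown base carries `N`.
#'
#' @param read_id Identifier (for diagnostics only).
#' @param first_index Panel index (1-based) of the first covered site.
#' @param symbols Character vector of symbols at the covered sites, in panel
#'   order; the terminal sentinel is not allowed.
#' @return An object of class `read_observation`.
#' @export
read_observation <- function(read_id, first_index, symbols) {
  first_index <- as.integer(first_index)
  stopifnot(length(first_index) == 1L, first_index >= 1L, length(symbols) >= 1L)
  .sym_index(symbols)  # validates
  structure(
    list(read_id = as.character(read_id), first_index = first_index,
         last_index = first_index + length(symbols) - 1L,
         symbols = as.character(symbols)),
    class = "read_observation"
  )
}

#' Record one read's evidence in the co-occurrence matrix
#'
#' Every ordered pair of sites the read covers contributes one count for its
#' symbol pair; additionally the last covered site is linked to the terminal
#' sentinel in the next (possibly virtual) column, so column `(j, j+1)`
#' always tallies every read covering site `j`.
#'
#' @param H A [cooc_matrix].
#' @param obs A [read_observation].
#' @return The updated matrix.
#' @examples
#' H <- cooc_matrix(4)
#' H <- observe_read(H, read_observation("r1", 1, c("A", "A", "C", "C")))
#' cooc_count(H, "A", "A", 1, 2)
#' @export
observe_read <- function(H, obs) {
  stopifnot(inherits(H, "cooc_matrix"), inherits(obs, "read_observation"))
  if (obs$first_index < 1L || obs$last_index > H$n) {
    stop(hap_error("panel_mismatch", sprintf(
      "observation covers sites %d..%d but the panel has %d site(s)",
      obs$first_index, obs$last_index, H$n)))
  }
  idx <- .obs_linear_indices(H$n, obs)
  H$counts[idx] <- H$counts[idx] + 1
  H
}

# linear indices into the flattened counts array for one observation:
# all ordered site pairs plus the terminal link. Pairs within one
# observation are distinct, so duplicated indices cannot occur.
.obs_linear_indices <- function(n, obs) {
  sites <- obs$first_index:obs$last_index
  sym <- .sym_index(obs$symbols)
  k <- length(sites)
  if (k >= 2L) {
    pr <- utils::combn(k, 2L)
    a <- sym[pr[1L, ]]; b <- sym[pr[2L, ]]
    i <- sites[pr[1L, ]]; j <- sites[pr[2L, ]]
  } else {
    a <- integer(0); b <- integer(0); i <- integer(0); j <- integer(0)
  }
  a <- c(a, sym[k]); b <- c(b, .SENTINEL_IDX)
  i <- c(i, sites[k]); j <- c(j, sites[k] + 1L)
  a + .N_SYM * (b - 1L) + .N_SYM^2 * (i - 1L) + .N_SYM^2 * n * (j - 1L)
}

#' Symbols observed at a site
#'
#' The set `V_i` of distinct symbols seen at site `i`, read from column
#' `(i, i+1)` (which tallies every read covering `i`). This set sizes the
#' Laplace smoothing of [conditional()] and defines the start set of the
#' traversal.
#'
#' @param H A [cooc_matrix].
#' @param i Site index in `1..n`.
#' @param eps Positivity tolerance; fractional counts below it count as
#'   absent.
#' @return Character vector of symbols in canonical order.
#' @export
variants_at <- function(H, i, eps = 1e-9) {
  stopifnot(i >= 1L, i <= H$n)
  sl <- H$counts[, , i, i + 1L]
  hap_symbols()[rowSums(sl)[seq_len(.N_SYM - 1L)] >= eps]
}

#' Marginal probability of a symbol at a site
#'
#' Estimated as the fraction of reads spanning site `j` that show `beta`
#' there, computed entirely from column `(j, j+1)` of the matrix (the
#' terminal-sentinel links make the denominator equal the number of reads
#' covering `j`).
#'
#' @param H A [cooc_matrix].
#' @param beta A symbol (not the sentinel).
#' @param j Site index in `1..n`.
#' @return A probability in `[0, 1]`.
#' @export
marginal <- function(H, beta, j) {
  stopifnot(j >= 1L, j <= H$n)
  b <- .sym_index(beta)
  sl <- H$counts[, , j, j + 1L]
  den <- sum(sl)
  if (den <= 0) {
    stop(hap_no_evidence(sprintf("no read spans site %d", j), site = as.integer(j)))
  }
  sum(sl[b, ]) / den
}

# all per-site marginals as a 6 x n matrix (rows = observable symbols);
# NA columns mark sites no read spans
site_marginals <- function(H) {
  out <- matrix(NA_real_, nrow = .N_SYM - 1L, ncol = H$n,
                dimnames = list(hap_symbols(), NULL))
  for (j in seq_len(H$n)) {
    sl <- H$counts[, , j, j + 1L]
    den <- sum(sl)
    if (den > 0) out[, j] <- rowSums(sl)[seq_len(.N_SYM - 1L)] / den
  }
  out
}

#' Laplace-smoothed conditional probability between sites
#'
#' Probability that symbol `alpha` sits at site `i` given `beta` observed at
#' the later site `j`. One dummy read is added for every possible pairing
#' (Laplace smoothing), so the result is strictly positive even for pairs
#' never co-covered by a read; the smoothing denominator uses the number of
#' distinct symbols observed at `i` (see [variants_at()]).
#'
#' @param H A [cooc_matrix].
#' @param alpha Symbol hypothesised at site `i`.
#' @param i,j Site indices with `i < j <= n`.
#' @param beta Symbol conditioned on at site `j` (not the sentinel).
#' @return A probability in `(0, 1]`.
#' @export
conditional <- function(H, alpha, i, beta, j) {
  if (j <= i) {
    stop(hap_error("bad_index", "conditional() requires i < j"))
  }
  stopifnot(i >= 1L, j <= H$n)
  a <- .sym_index(alpha)
  b <- .sym_index(beta)
  Vi <- length(variants_at(H, i, eps = .Machine$double.eps))
  (1 + H$counts[a, b, i, j]) / (Vi + sum(H$counts[, b, i, j]))
}

#' Symbols reachable at the next site
#'
#' For `i >= 1`, the symbols `beta` at site `i + 1` whose adjacent-column
#' evidence `sum_alpha H[alpha, beta, i, i+1]` clears the availability
#' threshold; for `i = 0` (path start), the symbols observed at site 1. An
#' empty return is a legal signal of a hole in the graph.
#'
#' @param H A [cooc_matrix].
#' @param i Site index in `0..n-1`.
#' @param eps Edge-availability threshold; evidence below it does not open
#'   an edge (guards against float dust left by repeated reweighting).
#' @return Character vector of symbols in canonical order (possibly empty).
#' @export
available_edges <- function(H, i, eps = 1e-9) {
  stopifnot(i >= 0L, i <= H$n - 1L)
  if (i == 0L) return(variants_at(H, 1L, eps = eps))
  sl <- H$counts[, , i, i + 1L]
  hap_symbols()[colSums(sl)[seq_len(.N_SYM - 1L)] >= eps]
}

#' Export the adjacent-transition graph
#'
#' The simple graph over per-site symbols whose edges connect symbols at
#' adjacent sites with positive co-occurrence evidence, each edge weighted
#' by its raw adjacent count. Because the graph only encodes adjacent
#' evidence, it typically contains paths no read supports; the traversal
#' avoids those by conditioning on non-adjacent evidence as well.
#'
#' @param H A [cooc_matrix].
#' @param file Optional path; when given, the edge list is written there.
#' @param format `"tsv"` (columns `from`, `to`, `weight`; nodes rendered
#'   `<symbol>@<index>`) or `"dot"` (Graphviz digraph).
#' @param eps Edge-availability threshold.
#' @return Invisibly, a data.frame of edges (`from_symbol`, `from_index`,
#'   `to_symbol`, `to_index`, `weight`).
#' @export
export_graph <- function(H, file = NULL, format = c("tsv", "dot"), eps = 1e-9) {
  format <- match.arg(format)
  rows <- list()
  for (i in seq_len(H$n - 1L)) {
    sl <- H$counts[seq_len(.N_SYM - 1L), seq_len(.N_SYM - 1L), i, i + 1L]
    hit <- which(sl >= eps, arr.ind = TRUE)
    if (nrow(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        from_symbol = hap_symbols()[hit[, 1L]], from_index = i,
        to_symbol = hap_symbols()[hit[, 2L]], to_index = i + 1L,
        weight = sl[hit], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from_symbol = character(0), from_index = integer(0),
               to_symbol = character(0), to_index = integer(0),
               weight = numeric(0))
  edges <- edges[order(edges$from_index, edges$from_symbol, edges$to_symbol), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(file)) {
    if (format == "tsv") {
      out <- data.frame(
        from = paste0(edges$from_symbol, "@", edges$from_index),
        to = paste0(edges$to_symbol, "@", edges$to_index),
        weight = edges$weight)
      utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      lines <- c("digraph H {",
                 sprintf("  \"%s@%d\" -> \"%s@%d\" [label=%g];",
                         edges$from_symbol, edges$from_index,
                         edges$to_symbol, edges$to_index, edges$weight),
                 "}")
      writeLines(lines, file)
    }
  }
  invisible(edges)
}

#' Dump or load a co-occurrence matrix as TSV
#'
#' Plain-text round-trip of all non-zero entries, columns
#' `(alpha, beta, i, j, count)`; the sentinel is rendered as `$`.
#'
#' @param H A [cooc_matrix].
#' @param file Path to write to / read from.
#' @return `write_cooc_tsv()` returns `file` invisibly; `read_cooc_tsv()`
#'   returns a [cooc_matrix].
#' @export
write_cooc_tsv <- function(H, file) {
  nz <- which(H$counts != 0, arr.ind = TRUE)
  ab <- .hap_alphabet()
  df <- data.frame(alpha = ab[nz[, 1L]], beta = ab[nz[, 2L]],
                   i = nz[, 3L], j = nz[, 4L], count = H$counts[nz])
  df <- df[order(df$i, df$j, df$alpha, df$beta), , drop = FALSE]
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cooc_tsv
#' @param n Site count of the matrix being loaded; defaults to the largest
#'   `i` present in the file.
#' @export
read_cooc_tsv <- function(file, n = NULL) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "integer", "integer", "numeric"))
  if (is.null(n)) n <- max(df$i)
  H <- cooc_matrix(n)
  a <- .sym_index(df$alpha, allow_sentinel = TRUE)
  b <- .sym_index(df$beta, allow_sentinel = TRUE)
  .check_pair_indices(H, df$i, df$j)
  H$counts[cbind(a, b, df$i, df$j)] <- df$count
  H
}
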