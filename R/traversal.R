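#' Traversal configuration
#'
#' @param lookback Number of trailing path nodes conditioned on when scoring
#'   a candidate edge (`L >= 1`). Larger values use more non-adjacent
#'   evidence and suppress chimeric paths, at the cost of conditioning on
#'   pairs few reads span; sensible values are tied to how many variant
#'   sites one read typically covers. Default 5.
#' @param max_iterations Cap on traversal rounds in [recover_all()];
#'   reweighting usually exhausts the evidence first. Default 100.
#' @param edge_epsilon Edge-availability threshold: adjacent evidence below
#'   it does not open an edge. Default `1e-9`, i.e. "strictly positive" with
#'   float safety.
#' @return An object of class `traversal_config`.
#' @export
traversal_config <- function(lookback = 5L, max_iterations = 100L,
                             edge_epsilon = 1e-9) {
  lookback <- as.integer(lookback)
  max_iterations <- as.integer(max_iterations)
  stopifnot(lookback >= 1L, max_iterations >= 1L, edge_epsilon > 0)
  structure(list(lookback = lookback, max_iterations = max_iterations,
                 edge_epsilon = edge_epsilon),
            class = "traversal_config")
}

.as_path <- function(symbols, n, complete, hole_index = NA_integer_,
                     iteration = NA_integer_, lambda_used = NA_real_,
                     log10_likelihood = NA_real_) {
  structure(list(symbols = symbols, n = n, complete = complete,
                 hole_index = hole_index, iteration = iteration,
                 lambda_used = lambda_used,
                 log10_likelihood = log10_likelihood),
            class = "hap_path")
}

#' @export
print.hap_path <- function(x, ...) {
  cat(sprintf("hap_path: %s%s\n", paste(x$symbols, collapse = ""),
              if (x$complete) "" else sprintf(" (aborted; hole at site %d)", x$hole_index)))
  if (!is.na(x$log10_likelihood)) {
    cat(sprintf("  log10 likelihood: %.6g; lambda: %.6g; iteration: %d\n",
                x$log10_likelihood, x$lambda_used, x$iteration))
  }
  invisible(x)
}

#' @export
format.hap_path <- function(x, ...) paste(x$symbols, collapse = "")

#' Lookback-conditioned log score of a candidate edge
#'
#' The greedy step objective: the log10 marginal of the candidate symbol at
#' the next site, plus log10 conditionals of each of the last
#' `min(L, i)` path nodes given the candidate. With an empty path the score
#' reduces to the marginal alone.
#'
#' @param H A [cooc_matrix].
#' @param path_symbols Character vector of the path so far (sites
#'   `1..length(path_symbols)`).
#' @param candidate Candidate symbol at the next site.
#' @param lookback Lookback window `L`.
#' @return The log10 score, or the `hap_no_evidence` condition is signalled
#'   when the candidate's site has no spanning read.
#' @export
edge_log_score <- function(H, path_symbols, candidate, lookback) {
  i <- length(path_symbols)
  s <- log10(marginal(H, candidate, i + 1L))
  nl <- min(lookback, i)
  for (l in seq_len(nl) - 1L) {
    s <- s + log10(conditional(H, path_symbols[i - l], i - l, candidate, i + 1L))
  }
  s
}

# pick the maximal candidate; candidates come ordered canonically so
# which.max resolves ties to the earliest symbol in A < C < G < T < N < -
.argmax_symbol <- function(candidates, scores) {
  best <- which.max(scores)
  tie <- sum(abs(scores - scores[best]) < 1e-12) > 1L
  list(symbol = candidates[best], tie = tie)
}

#' One greedy traversal of the evidence graph
#'
#' Starts at the highest-marginal symbol of site 1 and repeatedly appends
#' the available symbol with the highest lookback-conditioned score until
#' site `n` is reached, or aborts at the first hole (a site transition with
#' no available evidence). Deterministic given `H` and `config`; score ties
#' break by canonical symbol order.
#'
#' @param H A [cooc_matrix].
#' @param config A [traversal_config()].
#' @return A `hap_path`: complete (length `n`) or aborted (shorter, with
#'   `hole_index` set to the unreachable site).
#' @export
traverse <- function(H, config = traversal_config()) {
  n <- H$n
  eps <- config$edge_epsilon
  start <- available_edges(H, 0L, eps = eps)
  if (length(start) == 0L) {
    return(.as_path(character(0), n, complete = FALSE, hole_index = 1L))
  }
  sc <- vapply(start, function(s) marginal(H, s, 1L), numeric(1))
  path <- .argmax_symbol(start, sc)$symbol
  ties <- 0L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      cands <- available_edges(H, i, eps = eps)
      if (length(cands) == 0L) {
        return(.as_path(path, n, complete = FALSE, hole_index = i + 1L))
      }
      scores <- tryCatch(
        vapply(cands, function(b) edge_log_score(H, path, b, config$lookback),
               numeric(1)),
        hap_no_evidence = function(e) NULL)
      if (is.null(scores)) {
        return(.as_path(path, n, complete = FALSE, hole_index = i + 1L))
      }
      pick <- .argmax_symbol(cands, scores)
      if (pick$tie) ties <- ties + 1L
      path <- c(path, pick$symbol)
    }
  }
  out <- .as_path(path, n, complete = TRUE)
  attr(out, "tie_events") <- ties
  out
}

#' Reweight ratio of a recovered path
#'
#' The minimum per-site marginal along a complete path, evaluated on the
#' current (possibly already reweighted) matrix. It estimates the fraction
#' of the remaining evidence that this haplotype accounts for, and is the
#' ratio by which its adjacent evidence is depleted.
#'
#' @param H A [cooc_matrix].
#' @param path A complete `hap_path` (or character vector of `n` symbols).
#' @return A value in `[0, 1]`.
#' @export
compute_lambda <- function(H, path) {
  sym <- if (inherits(path, "hap_path")) path$symbols else path
  stopifnot(length(sym) == H$n)
  min(vapply(seq_len(H$n), function(i) marginal(H, sym[i], i), numeric(1)))
}

#' Deplete the adjacent evidence supporting a recovered path
#'
#' Every adjacent entry `H[path[i], path[i+1], i, i+1]` is multiplied by
#' `1 - lambda`; all other entries (including the non-adjacent pairs that
#' also supported the path) are untouched, and no count can become
#' negative.
#'
#' @param H A [cooc_matrix].
#' @param path A complete `hap_path` (or character vector of `n` symbols).
#' @param lambda Depletion ratio in `[0, 1]`.
#' @return The updated matrix.
#' @export
reweight <- function(H, path, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  sym <- if (inherits(path, "hap_path")) path$symbols else path
  stopifnot(length(sym) == H$n)
  if (H$n >= 2L) {
    idx <- .sym_index(sym)
    i <- seq_len(H$n - 1L)
    at <- cbind(idx[i], idx[i + 1L], i, i + 1L)
    H$counts[at] <- pmax(0, H$counts[at] * (1 - lambda))
  }
  H
}

#' Log-likelihood of a complete path
#'
#' The sum over sites of the log10 marginal of the path's symbol, evaluated
#' against the matrix state prior to any reweighting (supplied either as
#' the original matrix or as its cached per-site marginals). A zero
#' marginal yields `-Inf`; such a path is still rankable.
#'
#' @param path A complete `hap_path` (or character vector of symbols).
#' @param H_original The pre-reweighting [cooc_matrix], or the matrix of
#'   per-site marginals returned by the internal snapshot (rows = symbols).
#' @return The log10 likelihood (<= 0).
#' @export
score_path <- function(path, H_original) {
  sym <- if (inherits(path, "hap_path")) path$symbols else path
  marg <- if (inherits(H_original, "cooc_matrix")) site_marginals(H_original)
          else H_original
  stopifnot(length(sym) == ncol(marg))
  p <- marg[cbind(.sym_index(sym), seq_along(sym))]
  if (anyNA(p)) {
    stop(hap_no_evidence("path crosses a site with no spanning read"))
  }
  sum(log10(p))
}

#' Recover and rank all haplotypes supported by the evidence
#'
#' Iterates greedy traversal and evidence depletion: each complete path is
#' scored against the pre-reweighting marginals, its reweight ratio
#' computed on the current matrix, and its adjacent evidence depleted
#' before the next round. The loop stops when a traversal aborts (evidence
#' exhausted, or a hole from the outset) or after `max_iterations` rounds.
#' Duplicate paths (re-found when the ratio is small) are reported once,
#' keeping the first iteration index.
#'
#' @param H A [cooc_matrix].
#' @param config A [traversal_config()].
#' @return An object of class `traversal_result`: `haplotypes` (list of
#'   complete `hap_path`, ranked by log10 likelihood, ties by first
#'   recovery), `termination_reason` (one of `evidence_exhausted`,
#'   `max_iterations`, `hole_at_start`) and `diagnostics` (one row per
#'   iteration: path, completeness, hole index, lambda, score, tie events).
#' @export
recover_all <- function(H, config = traversal_config()) {
  snapshot <- site_marginals(H)
  paths <- list()
  diag_rows <- list()
  termination <- "max_iterations"
  for (it in seq_len(config$max_iterations)) {
    p <- traverse(H, config)
    if (!p$complete) {
      termination <- if (it == 1L && length(p$symbols) == 0L) "hole_at_start"
                     else "evidence_exhausted"
      diag_rows[[it]] <- data.frame(
        iteration = it, complete = FALSE,
        path = paste(p$symbols, collapse = ""), hole_index = p$hole_index,
        lambda = NA_real_, log10_likelihood = NA_real_, tie_events = NA_integer_,
        stringsAsFactors = FALSE)
      break
    }
    score <- tryCatch(score_path(p, snapshot),
                      hap_no_evidence = function(e) -Inf)
    lam <- compute_lambda(H, p)
    p$iteration <- it
    p$lambda_used <- lam
    p$log10_likelihood <- score
    key <- paste(p$symbols, collapse = "")
    if (is.null(paths[[key]])) paths[[key]] <- p
    diag_rows[[it]] <- data.frame(
      iteration = it, complete = TRUE, path = key, hole_index = NA_integer_,
      lambda = lam, log10_likelihood = score,
      tie_events = attr(p, "tie_events") %||% 0L, stringsAsFactors = FALSE)
    H <- reweight(H, p, lam)
  }
  haps <- unname(paths)
  if (length(haps)) {
    ord <- order(-vapply(haps, function(x) x$log10_likelihood, numeric(1)),
                 vapply(haps, function(x) x$iteration, integer(1)))
    haps <- haps[ord]
  }
  structure(
    list(haplotypes = haps, termination_reason = termination,
         diagnostics = do.call(rbind, diag_rows)),
    class = "traversal_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.traversal_result <- function(x, ...) {
  cat(sprintf("traversal_result: %d unique haplotype(s); termination: %s\n",
              length(x$haplotypes), x$termination_reason))
  for (k in seq_along(x$haplotypes)) {
    h <- x$haplotypes[[k]]
    cat(sprintf("  %2d. %s  log10L = %.4f  lambda = %.4f  (iteration %d)\n",
                k, paste(h$symbols, collapse = ""), h$log10_likelihood,
                h$lambda_used, h$iteration))
  }
  invisible(x)
}
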