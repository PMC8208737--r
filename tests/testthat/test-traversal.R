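test_that("edge scores on the toy match the hand computation", {
  H <- toy_H()
  # from path [A@1, A@2] with lookback 2 (0/1 encoding: [0@1, 0@2])
  expect_equal(edge_log_score(H, c("A", "A"), "A", 2L), log10(1 / 3))
  expect_equal(edge_log_score(H, c("A", "A"), "C", 2L), log10(2 / 9))
  # empty path: the score reduces to the marginal alone
  expect_equal(edge_log_score(H, character(0), "A", 5L), log10(1))
})

test_that("greedy traversal of the toy is deterministic and yields a genuine read", {
  H <- toy_H()
  cfg <- traversal_config(lookback = 2L)
  p <- traverse(H, cfg)
  expect_true(p$complete)
  expect_equal(path_string(p), "AAAC")   # 0001, one of the input reads
  expect_equal(path_string(traverse(H, cfg)), "AAAC")
})

test_that("every greedy step maximises the lookback score (brute-force oracle)", {
  # independent scorer working directly on the raw counts
  raw_marginal <- function(H, b, j) {
    sl <- H$counts[, , j, j + 1L]
    sum(sl[match(b, c(hap_symbols(), hap_sentinel())), ]) / sum(sl)
  }
  raw_conditional <- function(H, a, i, b, j) {
    ab <- c(hap_symbols(), hap_sentinel())
    Vi <- sum(rowSums(H$counts[, , i, i + 1L]) > 0)
    (1 + H$counts[match(a, ab), match(b, ab), i, j]) /
      (Vi + sum(H$counts[, match(b, ab), i, j]))
  }
  raw_score <- function(H, path, cand, L) {
    i <- length(path)
    s <- log10(raw_marginal(H, cand, i + 1L))
    for (l in seq_len(min(L, i)) - 1L) {
      s <- s + log10(raw_conditional(H, path[i - l], i - l, cand, i + 1L))
    }
    s
  }
  for (seed in 1:12) {
    n <- sample(3:8, 1L)
    H <- rand_full_H(n, sample(3:10, 1L), seed = seed,
                     symbols = c("A", "C", "G"))
    L <- sample(1:4, 1L)
    p <- traverse(H, traversal_config(lookback = L))
    expect_true(p$complete)
    for (i in seq_len(n - 1L)) {
      cands <- available_edges(H, i)
      scores <- vapply(cands, function(b)
        raw_score(H, p$symbols[seq_len(i)], b, L), numeric(1))
      expect_equal(raw_score(H, p$symbols[seq_len(i)], p$symbols[i + 1L], L),
                   max(scores), tolerance = 1e-12)
    }
  }
})

test_that("lambda is the minimum per-site marginal", {
  H <- toy_H()
  expect_equal(compute_lambda(H, strsplit("AACC", "")[[1L]]), 1 / 3)
  # single haplotype: all marginals are 1
  H1 <- build_matrix(lapply(1:4, function(r)
    read_observation(r, 1L, c("A", "C", "G"))),
    variant_panel("c", c(5L, 10L, 15L)))
  expect_equal(compute_lambda(H1, c("A", "C", "G")), 1)
})

test_that("reweighting depletes exactly the adjacent path entries", {
  H <- toy_H()
  path <- strsplit("AACC", "")[[1L]]  # 0011
  H2 <- reweight(H, path, 1 / 3)
  expect_equal(cooc_count(H2, "A", "A", 1, 2), 4 / 3)
  expect_equal(cooc_count(H2, "A", "C", 2, 3), 2 / 3)
  expect_equal(cooc_count(H2, "C", "C", 3, 4), 2 / 3)
  # non-adjacent and off-path entries untouched
  expect_equal(cooc_count(H2, "A", "C", 1, 3), cooc_count(H, "A", "C", 1, 3))
  expect_equal(cooc_count(H2, "A", "C", 1, 2), cooc_count(H, "A", "C", 1, 2))
  # boundary ratios
  expect_equal(reweight(H, path, 0)$counts, H$counts)
  H0 <- reweight(H, path, 1)
  expect_equal(cooc_count(H0, "A", "A", 1, 2), 0)
  expect_true(all(H0$counts >= 0))
})

test_that("path scores are marginal products against the pre-reweighting state", {
  H <- toy_H()
  expect_equal(score_path(strsplit("AACC", "")[[1L]], H), log10(4 / 27))
  expect_equal(score_path(strsplit("AAAC", "")[[1L]], H), log10(8 / 27))
  # dominance: site-wise >= marginals give a >= score
  expect_gt(score_path(strsplit("AAAC", "")[[1L]], H),
            score_path(strsplit("ACAA", "")[[1L]], H))
})

test_that("scoring via the cached snapshot equals scoring via the full matrix", {
  for (seed in 41:44) {
    H <- rand_full_H(6L, 8L, seed = seed, symbols = c("A", "C", "G"))
    res <- recover_all(H, traversal_config(max_iterations = 5L))
    for (h in res$haplotypes) {
      expect_equal(h$log10_likelihood, score_path(h$symbols, H),
                   tolerance = 1e-12)
    }
  }
})

test_that("the toy recovery never emits the unsupported chimeras", {
  res <- recover_all(toy_H(), traversal_config(lookback = 2L))
  got <- result_paths(res)
  expect_false(any(c("AAAA", "ACAC") %in% got))      # 0000, 0101
  # while well-supported paths remain, only genuine reads are emitted
  expect_setequal(res$diagnostics$path[1:3], c("AAAC", "AACC", "ACAA"))
  # ranked by likelihood, scores match the hand computation
  expect_equal(got[1L], "AAAC")
  expect_equal(res$haplotypes[[1L]]$log10_likelihood, log10(8 / 27))
  expect_equal(res$haplotypes[[1L]]$lambda_used, 2 / 3)
  expect_equal(res$haplotypes[[2L]]$log10_likelihood, log10(4 / 27))
  expect_equal(res$haplotypes[[3L]]$log10_likelihood, log10(2 / 27))
})

test_that("recovery is byte-deterministic given the same matrix and config", {
  H <- rand_full_H(6L, 10L, seed = 7, symbols = c("A", "C", "G"))
  cfg <- traversal_config(lookback = 3L, max_iterations = 20L)
  expect_identical(recover_all(H, cfg), recover_all(H, cfg))
})

test_that("counts never increase across iterations and adjacent evidence strictly drops", {
  H <- rand_full_H(5L, 12L, seed = 13)
  adjacent_total <- function(H) {
    sum(vapply(seq_len(H$n - 1L), function(i)
      sum(H$counts[, seq_len(6L), i, i + 1L]), numeric(1)))
  }
  cfg <- traversal_config()
  prev <- H
  for (it in 1:15) {
    p <- traverse(prev, cfg)
    if (!p$complete) break
    lam <- compute_lambda(prev, p)
    nxt <- reweight(prev, p, lam)
    expect_true(all(nxt$counts <= prev$counts + 1e-12))
    if (lam > 0) expect_lt(adjacent_total(nxt), adjacent_total(prev))
    prev <- nxt
  }
})

test_that("recovery halts within the iteration cap and reports the cap as reason", {
  H <- toy_H()
  res1 <- recover_all(H, traversal_config(max_iterations = 1L))
  expect_length(res1$haplotypes, 1L)
  expect_equal(res1$termination_reason, "max_iterations")
  res <- recover_all(H, traversal_config(max_iterations = 50L))
  expect_lte(nrow(res$diagnostics), 50L)
})

test_that("a hole aborts the traversal at exactly the unreachable site", {
  set.seed(19)
  obs <- lapply(1:8, function(r)
    read_observation(r, 1L, sample(c("A", "C"), 6L, replace = TRUE)))
  # one read ends at site 3, so site 3 keeps terminal bookkeeping even
  # after the transition evidence is removed
  obs <- c(obs, list(read_observation("end3", 1L, c("A", "A", "A"))))
  H <- build_matrix(obs, variant_panel("c", seq_len(6L) * 10L))
  # remove all pair evidence linking sites 3 and 4 (terminal links at site
  # 3 are per-site bookkeeping, not transition evidence)
  H$counts[, seq_len(6L), 3L, 4L] <- 0
  p <- traverse(H, traversal_config())
  expect_false(p$complete)
  expect_equal(p$hole_index, 4L)
  expect_length(p$symbols, 3L)
  res <- recover_all(H, traversal_config())
  expect_equal(res$termination_reason, "evidence_exhausted")
  expect_length(res$haplotypes, 0L)
})

test_that("an empty matrix reports a hole at the start", {
  res <- recover_all(cooc_matrix(4L), traversal_config())
  expect_equal(res$termination_reason, "hole_at_start")
  expect_length(res$haplotypes, 0L)
})

test_that("a degenerate single-site panel returns the best symbol", {
  H <- build_matrix(list(read_observation("a", 1L, "A"),
                         read_observation("b", 1L, "A"),
                         read_observation("c", 1L, "C")),
                    variant_panel("c", 5L))
  p <- traverse(H, traversal_config())
  expect_true(p$complete)
  expect_equal(p$symbols, "A")
})
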