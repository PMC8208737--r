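test_that("observing a read increments every ordered site pair plus the terminal link", {
  H <- cooc_matrix(4L)
  H <- observe_read(H, read_observation("r1", 1L, c("A", "A", "C", "C")))
  # six real pairs
  expect_equal(cooc_count(H, "A", "A", 1, 2), 1)
  expect_equal(cooc_count(H, "A", "C", 1, 3), 1)
  expect_equal(cooc_count(H, "A", "C", 1, 4), 1)
  expect_equal(cooc_count(H, "A", "C", 2, 3), 1)
  expect_equal(cooc_count(H, "A", "C", 2, 4), 1)
  expect_equal(cooc_count(H, "C", "C", 3, 4), 1)
  # terminal link at the virtual column
  expect_equal(cooc_count(H, "C", hap_sentinel(), 4, 5), 1)
  expect_equal(sum(H$counts), 7)
})

test_that("a single-site read contributes only its terminal link", {
  H <- observe_read(cooc_matrix(4L), read_observation("r", 3L, "G"))
  expect_equal(cooc_count(H, "G", hap_sentinel(), 3, 4), 1)
  expect_equal(sum(H$counts), 1)
})

test_that("the three-read toy matrix matches the hand enumeration", {
  H <- toy_H()
  expect_equal(cooc_count(H, "A", "A", 1, 2), 2)
  expect_equal(cooc_count(H, "A", "C", 1, 2), 1)
  # 3 reads x choose(4, 2) pairs + 3 terminal links
  expect_equal(sum(H$counts[, -7L, , ]), 18)
  expect_equal(sum(H$counts[, 7L, , ]), 3)
})

test_that("symbol and index validation rejects bad input", {
  H <- cooc_matrix(4L)
  expect_error(read_observation("r", 1L, c("A", "Z")), class = "hap_invalid_symbol")
  expect_error(read_observation("r", 1L, c("A", hap_sentinel())),
               class = "hap_invalid_symbol")
  expect_error(observe_read(H, read_observation("r", 3L, c("A", "C", "G"))),
               class = "hap_panel_mismatch")
  expect_error(cooc_count(H, "A", "A", 2, 2), class = "hap_bad_index")
  expect_error(cooc_count(H, "A", "A", 3, 1), class = "hap_bad_index")
  expect_error(conditional(H, "A", 3, "A", 2), class = "hap_bad_index")
})

test_that("upper-triangularity rejects random bad index pairs", {
  H <- rand_H(6L, 10L, seed = 1)
  set.seed(2)
  for (rep in 1:25) {
    i <- sample.int(7L, 1L)
    j <- sample.int(i, 1L)  # j <= i
    expect_error(cooc_count(H, "A", "A", i, j), class = "hap_bad_index")
  }
})

test_that("toy marginals match the worked example", {
  H <- toy_H()
  expect_equal(marginal(H, "A", 1), 1)
  expect_equal(marginal(H, "A", 2), 2 / 3)
  expect_equal(marginal(H, "C", 3), 1 / 3)
  expect_equal(marginal(H, "C", 4), 2 / 3)
})

test_that("marginal with no spanning read signals a no-evidence condition", {
  H <- cooc_matrix(3L)
  H <- observe_read(H, read_observation("r", 1L, "A"))
  expect_error(marginal(H, "A", 2), class = "hap_no_evidence")
})

test_that("marginals sum to one at every covered site", {
  for (seed in 1:20) {
    H <- rand_H(sample(2:8, 1L), sample(3:25, 1L), seed = seed)
    for (j in seq_len(H$n)) {
      tot <- tryCatch(
        sum(vapply(hap_symbols(), function(s) marginal(H, s, j), numeric(1))),
        hap_no_evidence = function(e) NA_real_)
      if (!is.na(tot)) expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("toy conditionals match the worked example and smoothing floors them", {
  H <- toy_H()
  expect_equal(conditional(H, "A", 1, "A", 2), 1)
  expect_equal(conditional(H, "A", 2, "C", 3), 2 / 3)
  # a pair never observed: strictly positive via the Laplace dummy read
  expect_equal(conditional(H, "C", 1, "C", 2), 1 / 2)  # numerator 1, V_1 = 1, col sum 1
  expect_equal(conditional(H, "G", 1, "G", 4), 1)      # 1 / V_1, nothing observed
})

test_that("smoothed conditionals over observed symbols sum to one", {
  for (seed in 21:35) {
    H <- rand_H(sample(3:7, 1L), sample(4:20, 1L), seed = seed)
    n <- H$n
    for (rep in 1:4) {
      i <- sample.int(n - 1L, 1L)
      j <- if (i + 1L == n) n else sample((i + 1L):n, 1L)
      vi <- variants_at(H, i)
      if (length(vi) == 0L) next  # site i uncovered by this random stream
      for (beta in c("A", "C")) {
        tot <- sum(vapply(vi, function(a) conditional(H, a, i, beta, j),
                          numeric(1)))
        expect_equal(tot, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("pair counts conserve the number of jointly covering reads", {
  n <- 6L
  obs <- rand_obs(n, 30L, seed = 5)
  H <- build_matrix(obs, variant_panel("c", seq_len(n) * 7L))
  first <- vapply(obs, function(o) o$first_index, integer(1))
  last <- vapply(obs, function(o) o$last_index, integer(1))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    expect_equal(sum(H$counts[, seq_len(6L), i, j]),
                 sum(first <= i & last >= j))
  }
  # terminal bookkeeping: column (j, j+1) totals the reads covering j
  for (j in 1:n) {
    expect_equal(sum(H$counts[, , j, j + 1L]), sum(first <= j & last >= j))
  }
})

test_that("available edges reflect observed symbols and vanish with the evidence", {
  H <- toy_H()
  expect_equal(available_edges(H, 1L), c("A", "C"))
  expect_equal(available_edges(H, 0L), "A")
  expect_length(available_edges(cooc_matrix(3L), 1L), 0L)
  # single read, reweighted away entirely
  H1 <- observe_read(cooc_matrix(3L), read_observation("r", 1L, c("A", "C", "G")))
  H1 <- reweight(H1, c("A", "C", "G"), 1)
  expect_length(available_edges(H1, 1L), 0L)
  expect_length(available_edges(H1, 2L), 0L)
})

test_that("the adjacent-only graph admits unsupported paths", {
  H <- toy_H()
  edges <- export_graph(H)
  has_edge <- function(a, i, b) {
    any(edges$from_symbol == a & edges$from_index == i & edges$to_symbol == b)
  }
  # chimera AAAA (0000): every adjacent step exists although no read shows it
  expect_true(has_edge("A", 1, "A") && has_edge("A", 2, "A") && has_edge("A", 3, "A"))
  # chimera ACAC (0101)
  expect_true(has_edge("A", 1, "C") && has_edge("C", 2, "A") && has_edge("A", 3, "C"))
})

test_that("a single read exports a linear chain and files are written", {
  H <- observe_read(cooc_matrix(4L), read_observation("r", 1L, c("A", "C", "G", "T")))
  edges <- export_graph(H)
  expect_equal(nrow(edges), 3L)
  expect_equal(edges$from_symbol, c("A", "C", "G"))
  tsv <- tempfile(fileext = ".tsv"); dot <- tempfile(fileext = ".dot")
  export_graph(H, tsv, "tsv")
  export_graph(H, dot, "dot")
  tab <- read.delim(tsv)
  expect_equal(tab$from, c("A@1", "C@2", "G@3"))
  expect_true(any(grepl("digraph", readLines(dot))))
})

test_that("matrix TSV dump/load round-trips counts exactly", {
  H <- rand_H(5L, 12L, seed = 9)
  f <- tempfile(fileext = ".tsv")
  write_cooc_tsv(H, f)
  H2 <- read_cooc_tsv(f, n = 5L)
  expect_equal(H2$counts, H$counts)
})
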