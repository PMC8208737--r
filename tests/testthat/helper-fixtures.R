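# Shared fixtures, built in code.

# The three-read worked example over four biallelic sites, encoded 0 -> A,
# 1 -> C. Site-symbol strings: AACC (0011), AAAC (0001), ACAA (0100).
toy_symbol_reads <- function() c("AACC", "AAAC", "ACAA")

toy_panel <- function() variant_panel("toy_contig", c(11L, 21L, 31L, 41L), 1L, 60L)

toy_obs <- function() {
  lapply(seq_along(toy_symbol_reads()), function(k) {
    read_observation(paste0("r", k), 1L, strsplit(toy_symbol_reads()[k], "")[[1L]])
  })
}

toy_H <- function() build_matrix(toy_obs(), toy_panel())

# random observation streams over contiguous spans, for property tests
rand_obs <- function(n_sites, n_reads, seed, symbols = c("A", "C", "G", "T")) {
  set.seed(seed)
  lapply(seq_len(n_reads), function(r) {
    f <- sample.int(n_sites, 1L)
    l <- if (f == n_sites) f else sample(f:n_sites, 1L)
    read_observation(paste0("r", r), f,
                     sample(symbols, l - f + 1L, replace = TRUE))
  })
}

rand_H <- function(n_sites, n_reads, seed, symbols = c("A", "C", "G", "T")) {
  build_matrix(rand_obs(n_sites, n_reads, seed, symbols),
               variant_panel("c", seq_len(n_sites) * 10L))
}

# a fully spanned random matrix: every adjacent site pair covered by at
# least one read (every read covers all sites)
rand_full_H <- function(n_sites, n_reads, seed, symbols = c("A", "C")) {
  set.seed(seed)
  obs <- lapply(seq_len(n_reads), function(r) {
    read_observation(paste0("r", r), 1L,
                     sample(symbols, n_sites, replace = TRUE))
  })
  build_matrix(obs, variant_panel("c", seq_len(n_sites) * 10L))
}

# study-condition community used by the recovery checks: 1 kb region,
# evenly spaced SNVs so reads span several adjacent sites, 30x depth for
# the rarest haplotype
study_community <- function(K, seed, n_snvs = 15L, error_rate = 0.01,
                            coverage = NULL) {
  ab <- (K:1) / sum(K:1)
  if (is.null(coverage)) coverage <- 30 / min(ab)
  spec <- community_spec(
    K = K, n_snvs = n_snvs, region_length = 1000L,
    snv_positions = as.integer(seq(50L, 950L, length.out = n_snvs)),
    read_length = 250L, coverage = coverage, error_rate = error_rate,
    seed = seed)
  generate_community(spec)
}

# community -> co-occurrence matrix via the full file pipeline
community_matrix <- function(comm, dir = tempfile("comm")) {
  paths <- write_community(comm, dir)
  panel <- read_panel_vcf(paths$sites_vcf, comm$spec$contig)
  obs <- extract_observations(paths$sam, panel)
  H <- build_matrix(obs, panel)
  attr(H, "panel") <- panel
  attr(H, "paths") <- paths
  H
}

path_string <- function(h) paste(h$symbols, collapse = "")
result_paths <- function(res) vapply(res$haplotypes, path_string, character(1))
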