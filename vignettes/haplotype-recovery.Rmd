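---
title: "Recovering community haplotypes from pairwise SNV co-occurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering community haplotypes from pairwise SNV co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopath)
```

## The problem and the model

A metagenomic assembly yields consensus contigs; the reads aligned back to
a contig region of interest mix fragments from every community member that
carries that region. Over the region's variant sites, each member
contributes a haplotype — an ordered sequence of alleles — and the number
of haplotypes is unknown. `haplopath` recovers a ranked set of candidate
haplotypes from the alignment alone.

All evidence is condensed into the pairwise SNV co-occurrence matrix `H`:
for sites `i < j` and symbols `α, β` from `{A, C, G, T, N, -}`,
`H[α, β, i, j]` counts reads showing `α` at `i` and `β` at `j`. Reads are
discarded as units; only pair counts remain. Two bookkeeping rules matter:

* Only the strict upper triangle in `(i, j)` exists. Reversed or diagonal
  entries are redundant and any access with `j <= i` is an error.
* After the last site a read covers, a terminal sentinel is recorded in the
  next (virtual for `i = n`) column. Column `(j, j+1)` therefore tallies
  *every* read covering `j`, which makes the marginal estimator's
  denominator — "reads spanning site `j`" — a pure matrix lookup.

From `H` we estimate, per site, the marginal probability of each symbol
(its frequency among spanning reads), and between sites the conditional
probability of a symbol at `i` given a symbol at a later site `j`,
Laplace-smoothed by one dummy observation per possible pairing so that
unobserved pairs keep small positive probability. The smoothing
denominator uses `V_i`, the number of distinct symbols actually observed at
`i`; consequently the conditionals over the observed symbols at `i` sum to
exactly one, a property the test suite asserts to 1e-12.

### Why not just a graph?

Adjacent-site entries of `H` define a graph over per-site symbols whose
paths are candidate haplotypes. But a graph can only encode adjacent
evidence: with reads `0011, 0001, 0100` over four biallelic sites, the
paths `0000` and `0101` exist in the graph although no read supports them.
The traversal therefore scores a candidate symbol `v` at site `i+1` with
the lookback rule

```
score(v) = log10 P(v) + sum_{l=0}^{min(L,i)-1} log10 P(path[i-l] | v)
```

pulling in non-adjacent pair evidence up to `L` sites back. Starting from
the highest-marginal symbol at site 1, the greedy argmax runs to site `n`
or aborts at a *hole* — a transition with no available evidence, which is a
data property (unspanned adjacent sites), not an algorithmic failure.

### Finding more than one haplotype

A single traversal is deterministic, so after reporting a path ĥ the
evidence must shift. The depletion ratio `λ = min_i P(ĥ[i])` — the
least-supported site's marginal, an estimate of the fraction of the
remaining evidence this haplotype explains — multiplies every adjacent
entry on ĥ by `(1 − λ)`. Iterating traversal + depletion surfaces
alternative haplotypes until a traversal aborts (evidence exhausted) or an
iteration cap is hit. Completed paths are scored by the sum of log10
marginals *against the pre-depletion state*, and duplicates (re-found when
λ is small) are merged, keeping the first iteration index.

Two asymmetries are implemented exactly as the model defines them, not
"fixed":

* Depletion touches only adjacent entries, while scoring conditions on
  non-adjacent entries; non-adjacent support of a recovered haplotype
  persists.
* λ on later iterations is computed on the current (partially depleted)
  matrix, since the ratio is defined within the iteration loop.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `lookback` (L) | 5 | trailing path nodes conditioned on per step (unitless count of sites). Useful conditioning reaches only as far as reads do: with 250 bp reads and ~65 bp site spacing a read links ~4–5 sites, so 5 captures what the data can support. Larger L adds smoothed, evidence-free terms. |
| `max_iterations` | 100 | traversal rounds; depletion usually exhausts the evidence first. |
| `edge_epsilon` | 1e-9 | availability threshold on adjacent evidence; "strictly positive" with float safety, so repeated multiplicative depletion cannot leave dust edges. |
| caller `min_depth` / `min_minor_count` | 2 / 1 | the literal disagreement rule; thresholds exist because per-column disagreement otherwise floods the panel on noisy data. Explicit package policy, not model prescription. |
| ingest `min_mapq` / `min_sites` | 0 / 1 | no read is silently dropped by default. |

Tie-breaks: equal-score candidates resolve by fixed symbol order
`A < C < G < T < N < -`; tie events are counted in the diagnostics. The
start node (site 1) is chosen by maximum marginal — the only evidence
available before a path exists. Degenerate inputs: a single-site panel
returns the best symbol; an empty matrix reports `hole_at_start`; a path
through a zero-marginal site scores `-Inf` but remains rankable.

## The simulator, and what passing tests show

`community_spec()`/`generate_community()`/`simulate_reads()` emulate the
study conditions the package is validated under: a 1 kb region carried by
K haplotypes at unequal abundances (default weights K:1), differing at
planted SNV sites; 250 bp reads drawn per haplotype proportional to
abundance with uniform starts and independent substitution errors (default
1%); alignments emitted directly as SAM since coordinates are known by
construction — deliberately bypassing an aligner so tests isolate this
package's computation. Deletion alleles produce real `D` CIGAR operations
and exercise the `-` symbol end to end.

Two allele layouts are provided:

* `distinct` (default): every haplotype gets its own symbol at each site,
  so each SNV separates every haplotype pair (K = 5 uses `-` as the fifth
  symbol). This is the regime in which full recovery is a fair ask.
* `biallelic`: two alleles per site, assigned at random. Realistic, but
  haplotypes agreeing across a window longer than the read span are
  information-theoretically indistinguishable there — no method working
  from read-pair evidence can separate them, and greedy traversal then
  produces locally-consistent chimeras.

The simulator does not model platform error profiles, indels as errors,
chimeric fragments, coverage bias, alignment or assembly artifacts.
Passing tests therefore show the estimators, traversal and depletion are
implemented to contract and behave as designed on clean, well-linked data;
they do not show robustness to misalignment or to haplotypes sharing long
identical stretches.

Problem sizes used by the suite and the acceptance script: 15-site panels
over 1 kb, 30× depth per haplotype, K up to 5 (up to ~1800 reads); the
estimator and greedy-step property checks run on hundreds of small random
matrices (n ≤ 8).

## Known limitations

* **The ranking is marginal-only.** The likelihood of a path is a product
  of per-site marginals and carries no linkage information. A path that
  assembles majority alleles — a single-error variant of an abundant
  haplotype, or a chimera of abundant haplotypes — outscores a genuinely
  rare haplotype: with abundance ratio `a_max/a_min` and `m` sites
  separating them, the rare truth trails by `m·log10(a_max/a_min)`, while
  one noise site costs only about `log10(err_frequency)`. At 1%
  substitution error, emitted noise variants routinely rank above the
  rarest truth haplotype even though every truth is recovered. Downstream
  filtering should treat the ranking as "more probable first", not as a
  truth/artifact separator.
* **Depletion can stall on noise.** λ of a noise-containing path is the
  noise site's tiny marginal, so such paths are barely depleted and can be
  re-found; duplicates are merged but iterations are spent. The iteration
  cap bounds this.
* **Holes end traversal by design**; sparse panels with reads too short to
  bridge adjacent sites stop at the first gap. Restricting analysis to
  gene-scale regions with adequate coverage is the intended use.
* Insertions are not modelled; paired mates are treated as independent
  observations (overlapping mates double-count shared sites).
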