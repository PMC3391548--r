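---
title: "Quality-score refinement of amplicon pyroreads: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-score refinement of amplicon pyroreads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroqc)
```

## The problem and the procedure

Pyrosequencing errors inflate α-diversity estimates: a read with a few
miscalled bases can sit more than 3 % away from every true sequence and
found a spurious singleton OTU, and singletons drive Chao1. Quality-score
refinement removes error-prone reads *before* clustering, using only the
per-base Phred scores (`Q`, 0–40; error probability `10^(-Q/10)`) that
accompany the base calls.

The pipeline applies four stages in a fixed order, each counting its own
removals so that stage attribution is well defined (a read failing several
criteria is charged to the earliest stage):

1. **Length** — all reads trimmed from the 5′ end to
   `L = floor(mean − sd)` of the raw length distribution; shorter reads
   removed. The sample standard deviation (n−1) and floor are used; neither
   is forced by the underlying procedure, and both err toward a shorter
   `L`, which keeps more reads. `trim_rule = "fixed:L"` overrides.
2. **Quality** — *fraction mode* keeps a read iff
   `#{i : Q_i < c} / L ≤ f`. "Below the cutoff" is strict (`<`), and the
   allowance boundary is inclusive, so a read with exactly `f·L`
   sub-threshold bases is kept. Since all reads share length `L` here, the
   fraction is interchangeable with an absolute count. *End-trim mode*
   truncates at the first base with `Q < c` — not the longest clean window —
   and drops reads that became shorter than `L`. This is deliberately the
   harsher published variant.
3. **Ns** — any read containing `N` is removed.
4. **Primer** — the 5′ prefix must match the barcoded primer under IUPAC
   degeneracy with zero mismatches; matching is case-insensitive, reads are
   assumed in primer orientation (as in 454 amplicon runs), and the matched
   prefix is optionally stripped. Whether the original pipelines checked Ns
   before or after primer stripping is not documented; we follow the order
   in which removals are conventionally tabulated (Ns first).

## Distances and OTU clustering

OTUs at 97 % similarity are complete-linkage clusters cut at distance
0.03. The pairwise distance is computed from a global Needleman–Wunsch
alignment (match +2, mismatch −4, gap −5 per base, compiled) as
`(mismatches + internal gap columns) / columns`, with terminal-gap columns
excluded from both numerator and denominator. Excluding terminal gaps makes
a read that is a clean prefix of another read distance 0 — essential when
read lengths vary; counting internal gaps as differences charges
homopolymer indels, the dominant 454 error, to the distance. A pure
ends-free *scoring* scheme was rejected: with free end gaps the optimal
alignment of e.g. `AAAA`/`AAAT` is a shifted perfect 3-mer overlap, which
would hide terminal substitutions entirely.

Complete linkage guarantees every output cluster's maximum intra-cluster
distance is at most the threshold, which is directly assertable and is
asserted in the tests. Merge ties are broken toward the pair containing the
lexicographically smallest read id, making the partition invariant to input
order. Identical sequences are collapsed before alignment — they sit at
distance 0 and always co-cluster, so the collapse is exact, and it reduces
a refined read set (where most reads are error-free copies of a template
prefix) to a far smaller unique set. The all-vs-all computation is
quadratic and intended for desk scale (a few thousand reads); no k-mer
prescreen is attempted.

## Diversity statistics

* **Rarefaction** is analytic (hypergeometric expectation), not
  resampled: `E[S_n] = Σ_i [1 − C(N−N_i, n)/C(N, n)]`, with binomial
  coefficients in log space (finite up to N ≈ 10⁶). Resampling survives
  only as a Monte-Carlo test oracle.
* **Chao1** uses the classic form `S_obs + F₁²/(2F₂)` when doubletons
  exist and the bias-corrected `S_obs + F₁(F₁−1)/(2(F₂+1))` when `F₂ = 0`.
  The 95 % CI uses the standard variance of the unseen-species count
  `T = chao1 − S_obs` with the log-normal construction
  `(S_obs + T/K, S_obs + T·K)`, `K = exp(1.96·sqrt(ln(1 + var/T²)))`; with
  no singletons the interval collapses to a point. This is the construction
  used by the mainstream richness-estimation software.
* **Shannon/evenness** uses natural logarithms and Pielou's
  `J = H / ln S_obs`, with `J ≡ 1` for a single OTU (limit convention). The
  log base is a documented choice, not a mathematical necessity.
* **Bias**: `R² = 1 − Σ(yᵢ−xᵢ)²/Σ(yᵢ−ȳ)²` measures goodness of fit of the
  post-filter taxon fractions (y) to the pre-filter fractions (x) against
  the *fixed* identity line — no slope or intercept is fitted, because the
  null hypothesis is "filtering changed nothing", not "filtering acted
  linearly". The statistic may be negative and is reported unclamped.

## The synthetic-read generator

No real 454 data ships with the package, so every claim is exercised on a
simulated world with known ground truth. The generator emulates:

* **Templates**: random sequences at a guaranteed pairwise divergence
  (rejection sampling), each starting with a concrete resolution of the
  degenerate barcoded primer; taxon labels assigned round-robin.
* **Abundance**: geometric series (ratio 0.8 by default) — realistic
  unevenness while still sampling the rarest of 10 templates ~15 times in
  500 reads, so richness recovery is testable; `uniform` is available.
* **Quality trajectories**: `Q(pos) = q_start + read_offset − q_slope·pos
  + noise`, rounded and clipped to [0, 40]. Defaults: `q_start = 34`,
  `q_slope = 0.02` (≈ 5 Phred units lost over a 250 nt read, matching the
  observed rise of mean Q upon 3′ trimming), per-base jitter sd 2.
* **Per-read offset** (`q_read_sd = 4`): real titanium runs contain whole
  reads of high and of mediocre quality; without a read-level component the
  per-base noise averages out and *no* read passes Q30₁₀ or Q32₁₀ under the
  mean trajectory, which contradicts the graded removal percentages the
  grid is meant to exhibit. The offset gives the observed gradient
  (~40 % removal at Q25₁₅ to ~90 % at Q32₁₀).
* **Degraded sub-population**: a fraction `frac_bad_reads = 0.2` of reads
  has the whole trajectory lowered by `bad_q_penalty = 20` Phred units
  (start ≈ Q14, error rate ≈ 4 %). These reads accumulate ~10 substitutions
  over 250 nt, found spurious singleton OTUs when unfiltered, and fail
  every cutoff of the grid — they are the planted ground truth for both
  richness inflation and filter efficacy.
* **Errors**: a substitution is planted at each position with probability
  `10^(-Q/10)` — the link between low quality and error is purely
  probabilistic, never forced per-base, because that probabilistic link is
  exactly the assumption quality filtering relies on. Each homopolymer run
  of length ≥ 4 gains or loses one base with probability
  `rate·(run_length − 3)` (longer runs are harder to resolve); inserted
  bases inherit the local quality. Note the substitution channel is never
  exactly zero: even at the Q40 cap the model says `P = 10⁻⁴`, so an
  "error-free" world of 500 × 290 nt still contains ~15 substitutions —
  harmless for OTU recovery (they perturb a read by < 1 % divergence) but
  worth knowing when asserting exact prefixes.
* **Determinism**: all randomness flows from the single config seed;
  identical configs give byte-identical FASTA/QUAL output.

Not emulated: flowgram-level signal, PCR chimeras (the config carries a
`chimera_rate` hook fixed at 0, since chimera detection is out of scope),
N calls, multi-sample barcodes, and real reference templates. A green
simulation test therefore establishes that the *pipeline machinery* behaves
as specified under the stated error model — not that any particular Q
cutoff is right for a given gene region, which is precisely the
sample-dependent question the methodology leaves to the analyst.

## Numerical and degenerate-input choices

* Quality values outside 0–40 on FASTQ input are rejected, not clipped: an
  out-of-range value almost always means a different FASTQ dialect, and
  silent clipping would corrupt the Q-fraction statistics downstream.
* An empty condition (every read removed) yields a valid ledger and simply
  carries no clustering/diversity entry; `run_grid` continues with the
  other conditions and records per-condition failures.
* `R²` to the identity line errors out when all y are identical (zero
  total sum of squares) rather than returning ±Inf.
* Chao1's CI construction degenerates gracefully: `T = 0` (no singletons,
  or a single singleton with no doubletons) gives a point interval.
* Distance ties in clustering are resolved by the smallest member id; the
  tolerance for "equal" merge heights is 1e−12, well below any meaningful
  distance difference at read lengths of a few hundred bases.

## Known limitations

* The alignment scoring (linear gap −5) is a convention, not a fit to 454
  chemistry; distances near the 0.03 boundary can differ from other
  aligners' by a column or two. The equivalence of this distance with any
  specific historical pipeline's aligner is not claimed.
* Complete linkage is O(n³) in unique sequences; beyond a few thousand
  uniques a heuristic clusterer (not in scope) would be needed.
* The removal-by-cluster profile conditions on the trimmed, non-quality-
  checked clustering; if trimming itself is disabled the profile follows
  whatever baseline clustering exists.
* Chao1 on very sparse remnants (a few dozen reads) is noisy; small
  non-monotonicities along a stringency ladder can appear for particular
  seeds purely through singleton bookkeeping — a sampling artifact of the
  estimator, not of the filter.
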