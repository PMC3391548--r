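# pyroqc

Quality-score refinement and diversity assessment for SSU rRNA amplicon
pyrosequencing reads.

## The problem

454-style pyrosequencing of small-subunit rRNA gene amplicons samples
microbial communities orders of magnitude more deeply than clone libraries,
but its intrinsic errors — substitutions tied to declining per-base Phred
quality, and indels at homopolymer runs — inflate species-richness
estimates, sometimes by an order of magnitude. A quick, widely used remedy
is quality-score refinement of the read set before OTU clustering:

1. **Length**: trim every read to `L = floor(mean − sd)` of the raw length
   distribution; remove reads shorter than `L`.
2. **Quality**: keep a read iff at most a fraction *f* of its bases have
   Phred quality `Q < c` (the grid crosses cutoffs `c ∈ {25, 27, 30, 32}`
   with allowances `f ∈ {10%, 15%}`, written Q27₁₅ etc.); alternatively,
   *end-trim* each read at its first base below the cutoff.
3. **Ns**: remove reads containing ambiguous bases.
4. **Primer errors**: remove reads whose 5′ prefix does not match the
   barcoded primer under IUPAC degeneracy (zero mismatches).

`pyroqc` implements this pipeline with per-stage removal ledgers, plus the
evaluation apparatus used to judge a cutoff: complete-linkage OTU
clustering at 97 % similarity from pairwise alignment distances, analytic
(hypergeometric) rarefaction `E[S_n] = Σᵢ (1 − C(N−Nᵢ,n)/C(N,n))`, the
Chao1 estimator `S_obs + F₁²/(2F₂)` with its classic log-normal 95 % CI,
Shannon `H = −Σ pᵢ ln pᵢ` and Pielou evenness `J = H/ln S`, a
phylogenetic-bias check (R² of pre/post-filter taxon fractions against the
identity line `y = x`), attribution of removed reads to pre-filter cluster
sizes, and homopolymer-run tabulation. A seeded synthetic 454-style read
simulator with full ground truth makes every stage testable without
external data.

## Worked example

```r
library(pyroqc)

cfg <- simulation_config(seed = 1)   # 10 templates, 500 titanium-like reads
man <- run_grid(cfg)                 # simulate -> refine grid -> cluster -> diversity
grid_summary(man)
```

Selected rows of the printed summary (seed 1):

```
  condition remaining pct_removed s_obs chao1 shannon_h evenness
   trim_noQ       365        27.0    29   200     2.357    0.700
     Q25_15       289        42.2    10    10     2.095    0.910
     Q27_15       232        53.6    10    10     2.092    0.909
     Q30_10       119        76.2    10    10     2.150    0.934
     Q32_10        63        87.4    10    10     2.159    0.938
```

Reading it: without a quality check the trimmed reads cluster into 29 OTUs
and Chao1 projects ~200 species although the simulated community contains
exactly 10 — the richness inflation that motivates quality filtering. Every
quality condition recovers the true 10 OTUs, removal grows with stringency
(42 → 87 % of reads), and evenness rises as erroneous singletons disappear.
`report(man, "out/")` writes these tables (ledgers, diversity, rarefaction,
taxon bias, cluster-removal profile, homopolymer matrix) as plain TSV.

A file-based CLI with the same stages is installed at
`system.file("cli", "pyroqc", package = "pyroqc")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pyroqc",package="pyroqc"))')" \
    simulate --n-reads 500 --seed 1 --out-dir sim/
```

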