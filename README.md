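# crmscan

Expression-coupled screening of cis-regulatory elements (CREs) and pairwise
CRE modules (CRMs) in fixed-length promoter sets.

## What it does, and for whom

Given promoters (fixed-length regions ending at the transcription start
site), an expression catalog assigning each differentially expressed gene to
exactly one category (e.g. the six 4-hour Zeitgeber-time bins of a circadian
experiment), and a list of candidate motifs, `crmscan` identifies the motifs
and motif pairs whose gene sets are enriched in particular expression
phases, and characterizes the positional grammar of candidate pairs. It is
aimed at regulatory-genomics analyses where expression follows an OR logic —
each gene peaks in one condition — and where a user-curated motif list
(known CRE databases, de novo predictions) is to be tested rather than
discovered.

The decision engine works against a **randomized-motif background**: for a
query motif the distribution of expression maxima (DEM) — the percentage of
its matched genes per category — is compared with the all-genes background,
in units of the per-category standard deviation of DEMs of random 5–8 bp
motifs. A background replicate *flags* the query when any category deviates
by at least `threshold_sd`; 100 replicates vote, and a query matching at
least `min_matches` promoters that is flagged by a strict majority is a
**candidate**.

For candidate pairs, three positional features are computed per co-occurring
promoter set:

* an exact binomial **order test** of which member lies TSS-proximal
  (null p = q = 0.5, doubled upper tail:
  `p = min(1, 2·Σ_{i=X..n} C(n,i)·0.5^n)`),
* a two-sided two-sample Kolmogorov–Smirnov **distance test** of member
  spacings against a 10,000-draw stochastic null of uniformly placed
  occurrences,
* **Bowley's quartile skewness** `S = (Q3 + Q1 − 2·Q2)/(Q3 − Q1)` of module
  positions (negative = TSS-proximal clustering).

An evolutionarily trained ensemble of two-class feedforward networks
(sigmoid hidden layer, Heaviside output) then groups candidate pairs by
these three statistics, scored by positive-to-random inclusion ratio with a
negative-control veto, until every candidate pair is categorized at least
once. See `vignette("crmscan-methods")` for the full model description.

## Worked example

Everything below runs on synthetic data shipped as code — no downloads.

```r
library(crmscan)

fixtures <- standard_fixtures(seed = 42)   # promoters + catalogs + planted signals
fx <- fixtures$single_cre                  # evening element planted in 30/100 promoters

set.seed(1)
model <- build_background_model(fx$promoters, fx$catalog)
model
#> <background_model> 100 replicates x 100 random CREs (lengths 5-8), 11 rejected draws
#> per-category sd (mean over replicates):
#>   ZT0-ZT4   ZT4-ZT8  ZT8-ZT12 ZT12-ZT16 ZT16-ZT20  ZT20-ZT0
#>     7.563     6.922    12.273     6.182     7.690     7.969

call <- evaluate_query("AAAATATCT", fx$promoters, fx$catalog, model)
call
#> <candidate_call> 'AAAATATCT': CANDIDATE (100/100 background votes, 30 matching promoters)
#> flagged categories: ZT0-ZT4, ZT4-ZT8, ZT8-ZT12, ZT12-ZT16, ZT16-ZT20, ZT20-ZT0

tidy(call)
#> # A tibble: 6 × 6
#>   category  dem_pct background_pct direction median_sd_ratio vote_frac
#>   <chr>       <dbl>          <dbl>     <dbl>           <dbl>     <dbl>
#> 1 ZT0-ZT4      3.33             11        -1            1.05      0.59
#> 2 ZT4-ZT8      0                 9        -1            1.36      0.92
#> 3 ZT8-ZT12    96.7              50         1            3.78      1
#> 4 ZT12-ZT16    0                 7        -1            1.20      0.75
#> 5 ZT16-ZT20    0                11        -1            1.48      0.95
#> 6 ZT20-ZT0     0                12        -1            1.56      0.95
```

The evening element's genes peak almost exclusively in `ZT8-ZT12` (96.7% of
matched genes against a 50% background, 3.8 background-sds away, flagged in
all 100 replicates); the depletion of every other phase bin is the flip side
of the same signal, with the deviation direction reported per category.

Positional statistics of a planted pair (TSS-proximal, strongly ordered,
spacing drawn from the null):

```r
pfx <- fixtures$pair_order
set.seed(2)
pair_positional_stats("CCACGTGGC,ACAGTACT", pfx$promoters)
#>                query n_promoters n_ordered      order_p distance_p     bowley
#> 1 CCACGTGGC,ACAGTACT          60        60 3.176279e-15  0.4751079 -0.5474453
```

The same member is TSS-proximal in nearly every promoter (order p ≈ 3·10⁻¹⁵),
module positions cluster at the TSS (S = −0.55), and the spacing shows no
preference (KS p = 0.48) — the classic pattern of an ordered, TSS-proximal
module without a fixed internal gap.

File-based drivers (`run_edcc()`, `run_pairs()`, `run_cng()`) wire these
steps over FASTA/TSV inputs and write plain-text bundles; a thin CLI lives at
`inst/scripts/crmscan.R` with `edcc`, `pairs`, `cng` and `simulate`
subcommands.

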