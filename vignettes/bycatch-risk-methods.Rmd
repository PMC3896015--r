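---
title: "Methods: turtle use intensity, gear-adjusted effort, and the interaction index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turtle use intensity, gear-adjusted effort, and the interaction index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bycatchr)
```

## Scope and assumptions

`bycatchr` estimates *relative* bycatch risk for satellite-tracked marine
populations exposed to pelagic longline fleets. Its core assumptions:

* Daily positions are already filtered and regularized (one estimate per
  day, e.g. from a state-space model). The package does not fit movement
  models; its simulator only emulates their output.
* Space-time patterns are stable enough across years that all years can
  be pooled into a 5°×5° grid crossed with four annual quarters.
* Gear-specific capture probability is spatially constant; only two gear
  classes (tuna-configured and billfish-configured sets) are
  distinguished, proxied by the billfish share of the local catch.
* The output is a relative co-occurrence surface. It predicts neither
  bycatch counts nor rates.

## The procedure

### 1. Track preprocessing (`preprocess_tracks`)

Relative track day is *calendar* days since the first position
(day 1 = deployment day). Positions strictly inside an inter-observation
gap of more than `max_gap_days` (default 20 days, the conventional cutoff
for unacceptable interpolation uncertainty) are removed; the bounding
observation days are kept, and relative days are **not** renumbered, so
removed spells persist as holes. Renumbering would silently misalign
"individuals tracked on the same relative day" across turtles with
different gap histories, which is why the calendar convention was chosen
for the open question of post-removal numbering. When raw transmission
dates are unavailable, gaps are inferred from missing dates in the daily
series, so pre-regularized gap-free input passes through unchanged.

### 2. Inverse-sample-size weighting (`weight_positions`)

A position of population $j$ at relative day $t$ receives
$\omega = 1/n_{jt}$, with $n_{jt}$ the number of individuals of $j$
having a position at day $t$. Because late days are observed for few
individuals, raw $1/n_{jt}$ would hand the longest tracks enormous
leverage; beyond a threshold day $T_j$ the weight is therefore frozen at
$1/n_{j,T_j}$.

$T_j$ is defined on the **position-day distribution**: the smallest day
$d$ such that $\sum_{t \le d} n_{jt} / \sum_t n_{jt} \ge q$, with
$q = 0.85$. The alternative reading (85th percentile of per-individual
track durations) was rejected because the weighting itself operates on
position-days; with no interpolation, the smallest-day-reaching-$q$ rule
with $\ge$ keeps $T_j$ an actual observed day. For $t \le T_j$ the
weights of the $n_{jt}$ individuals present sum to exactly one unit per
population-day (exact in rational arithmetic; floating-point sums agree
to well below $10^{-12}$).

### 3. Quarterly inflation (`quarter_inflation`)

Within each quarter the population with fewer **raw** position estimates
(counts, not weights — the inflation compensates sampling effort, which
is what raw counts measure) is multiplied by $x/y$, the larger over the
smaller count; the other population, or a population alone in a quarter,
gets 1. Inflation multiplies $\omega$ at accumulation time. Thresholding
and inflation act on different factors of each position's contribution,
so their order is immaterial; they are implemented independently.

### 4. Effective effort (`catchability_index`, `adjust_effort`)

The catchability index divides per-hook capture rates:
$c = (r_b / h_b)/(r_t / h_t)$ with defaults $r_b = 0.0246$,
$r_t = 0.0048$ turtles/set and $h_b = 850$, $h_t = 1124$ hooks/set,
giving $c \approx 6.78$ (tuna hooks are the reference gear). The default
`mix` adjustment treats the billfish catch fraction $p$ per cell-quarter
as the share of hooks fished billfish-style:
$E = \text{hooks}\,(p\,c + (1-p))$. A literal "multiply all hooks by
$c$" mode is provided as a configuration switch; with spatially constant
$p$ both modes give identical *normalized* effort probabilities, and the
`mix` mode was made the default because a composition-independent
scaling cancels entirely under normalization, leaving the billfish
fraction — introduced precisely as an effort-targeting estimate — unused.
Cells with hooks but no catch data receive the basin-wide pooled
fraction (configurable via `fill_p`) rather than being dropped, so patchy
catch reporting does not shrink the risk surface.

### 5. Normalization and interaction (`relative_probability`, `interaction_index`)

Use and effective-effort fields are each divided by their total over all
non-masked cell-quarters, so each sums to one across space *and* the four
quarters jointly — this is what makes seasonal panels comparable. The
interaction index is the cell-quarter product of the two probabilities
renormalized by the sum of products over the jointly non-masked support
(the sum-to-one requirement forces this normalized-product form; a
product of sums would not sum to one). It is scale-invariant in both raw
inputs and strictly increasing in any cell's joint intensity.

**Missing-data semantics.** A cell-quarter absent from a field is
no-data, distinct from a stored zero (zero effort is real information).
Masked-in-either means masked-in-output and excluded from denominators.
Zero joint support is an error carrying an overlap diagnostic rather
than a NaN surface.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cell_size` | 5 | degrees | resolution of public effort statistics |
| `max_gap_days` | 20 | days | interpolation-uncertainty cutoff for track gaps |
| `q` | 0.85 | cumulative fraction | threshold-day percentile capping long-track leverage |
| gear rates | 0.0246 / 0.0048 | turtles·set⁻¹ | published fleet-average capture rates |
| hooks per set | 850 / 1124 | hooks | typical billfish / tuna set sizes |
| `adjustment_mode` | `"mix"` | — | composition-weighted gear adjustment (see above) |

Grid cells are half-open `[lo, lo+5)`, anchored at multiples of 5° from
0° (the registration is a convention; nothing downstream depends on the
anchor), with latitude 90° folded into the top row and longitudes kept
on [0, 360) so the Pacific is contiguous across the antimeridian.

## What the synthetic worlds do and do not emulate

The track generator produces staggered deployments over 1992–2008, one
position per day, truncated-lognormal durations (meanlog log 157,
sdlog 0.9, truncated to [4, 948] days, mean ≈ 209 — matching published
Pacific leatherback tracking summaries of 135 animals), geometric
transmission gaps with mass beyond 20 days, and a two-state switching
correlated random walk: fast, directionally persistent transiting toward
waypoints versus slow, high-turning area-restricted search inside each
population's foraging region. Steps are taken in degrees with a
cos(latitude) longitude correction — at 5° resolution, projection error
is immaterial. Default geographies keep the East Pacific and West
Pacific populations in envelopes that share no 5° cell, mirroring the
observed non-overlap of the real nesting stocks.

Deliberately **not** emulated: satellite location error and its classes,
posterior uncertainty of track filters, oceanographic habitat drivers,
inter-annual (e.g. ENSO) variability, and fleet/flag structure in
effort. Passing tests on these worlds therefore demonstrate the
*pipeline's* correctness (weight conservation, normalization, hotspot
recovery, determinism), not that real turtle and effort data would yield
any particular map.

The `planted_hotspot` scenario makes its ground truth unambiguous by
construction: the population's foraging box is exactly one 5° cell, and
that cell's hooks in one quarter are raised to 10× the pre-planting
field maximum (a multiplier relative to the field maximum, so the
planted cell-quarter is the effort maximum by construction regardless of
the gamma draw it would otherwise have received).

## Numerical choices

* Normalization assertions use a tolerance of $10^{-9}$; the brute-force
  oracle comparison for the interaction index uses $10^{-12}$. Field
  totals are accumulated with `sum()`'s extended-precision accumulator.
* Weight conservation is exact in rational arithmetic ($n_{jt}$ copies
  of $1/n_{jt}$); floating-point summation of such sets is not always
  bit-exactly 1, so programmatic checks compare at $10^{-12}$.
* Hotspot ties break by ascending quarter, then cell latitude, then
  longitude, making rankings deterministic on degenerate (all-equal)
  surfaces.
* Degenerate inputs fail loudly: all-zero or all-masked fields, empty
  joint support, zero tuna capture rate, duplicate track dates and
  non-finite coordinates are all rejected with messages naming the
  offending record.
* All generators are deterministic given a seed; pipeline reruns with
  the same configuration are bit-identical (checksummed in the run
  manifest).

## Problem sizes used in the test and acceptance runs

The two-population world uses the full study dimensions (80 + 55
turtles, ≈ 28–30k daily positions, ≈ 2 200 effort cell-quarters) and
runs in seconds. Unit tests use 2–40 turtle fixtures built in code;
the oracle-equivalence check uses 100 random fields of at most 4×4
cells; hotspot recovery uses 24 seeds of an 18-turtle scenario. These
sizes were chosen to exercise every rule (gaps beyond 20 days, both
threshold regimes, partial coverage) at interactive runtimes.

## Limitations

Relative, not absolute: the surface allocates co-occurrence shares and
cannot confirm bycatch occurrence or rate. Constant catchability across
the basin, two gear classes, pooled years and quarters, and equal-area
treatment of 5° cells (cells shrink poleward; at the latitudes involved
the distortion is modest but real) are all simplifications a
regional analysis would want to revisit. Uncertainty bands on the index
are not defined — inputs are treated as fixed surfaces.
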