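# bycatchr

Where and when are wide-ranging, satellite-tracked marine animals most at
risk of being caught on industrial longlines? Direct bycatch observations
are sparse and unevenly reported, so `bycatchr` takes the indirect route
used in fisheries risk assessment: combine the animals' relative
space-time distribution (from telemetry) with the fleet's relative effort
distribution (from public hook statistics), adjusted for how catchable the
animal is in each gear configuration. It was built for Pacific leatherback
turtles and pelagic longline fleets, but applies to any tracked population
and gridded effort source.

The package is aimed at movement ecologists and fisheries scientists who
have daily, regularized track positions (e.g. output of a state-space
filter) for one or two populations, plus 5°×5° quarterly effort (hooks)
and catch-composition (tonnes by species group) tables.

## The model

Everything lives on a 5°×5° grid crossed with the four annual quarters
(Q1 = Jan–Mar, …), pooled across years. Write *i* for a grid cell and *t*
for a quarter.

**Use intensity.** Tracks end at different times (battery, tag loss,
mortality), so late track days are observed for fewer individuals. Each
daily position of an animal in population *j* at relative track day *t*
gets weight

&nbsp;&nbsp;&nbsp;&nbsp;ω = 1 / n<sub>jt</sub>,

where n<sub>jt</sub> is the number of individuals of population *j* still
providing a position at relative day *t*, so every tracked
population-day contributes one unit in total. Beyond a threshold day
T<sub>j</sub> — the 85th percentile of the population's position-day
distribution — the weight is frozen at 1 / n<sub>j,T<sub>j</sub></sub>
to cap the leverage of the few longest tracks. Within each quarter, the
population with fewer raw positions is inflated by x/y (larger over
smaller count) so the two populations carry equal weight per quarter.
Weighted positions are summed per (cell, quarter) into a use-intensity
field; cells never visited are no-data (masked), not zero.

**Effective effort.** Turtles are far likelier to be caught on shallow
billfish-configured sets than on deep tuna sets. From per-set capture
rates (0.0246 vs 0.0048 turtles/set) and typical set sizes (850 vs 1124
hooks), the per-hook catchability ratio is

&nbsp;&nbsp;&nbsp;&nbsp;c = (0.0246/850) / (0.0048/1124) ≈ 6.8.

Each cell-quarter's hooks are scaled by the local billfish fraction *p*
of the catch (by weight): E = hooks × (p·c + (1 − p)), i.e. effort in
tuna-hook equivalents. A `literal` mode applying ×c uniformly is also
provided.

**Interaction index.** Both surfaces are normalized to relative
probabilities P<sub>turtle</sub> and P<sub>effort</sub> summing to one
over all cells and all four quarters combined, and the bycatch-risk
surface is the normalized product

&nbsp;&nbsp;&nbsp;&nbsp;I(i,t) = P<sub>turtle</sub>(i,t) · P<sub>effort</sub>(i,t) / Σ P<sub>turtle</sub> · P<sub>effort</sub>,

again summing to one, so values are directly comparable across cells
*and* seasons. A cell-quarter masked in either input is masked in the
output. `top_hotspots()` ranks cell-quarters with deterministic
tie-breaking.

The package also ships seeded synthetic-world generators (two-state
correlated-random-walk tracks with transmission gaps, gamma-dispersed
effort fields with configurable billfish composition, and scenarios with
a planted ground-truth hotspot) used throughout the tests.

## Worked example

Simulate a world with a known hotspot (a single foraging cell at 0–5°N,
180–185°E, with effort in quarter 3 raised to ten times the field
maximum), run the analysis, and rank hotspots:

```r
library(bycatchr)

round(catchability_index(gear_params()), 2)
#> [1] 6.78

world  <- simulate_scenario(make_scenario("planted_hotspot", 7))
tracks <- preprocess_tracks(world$tracks)          # 20-day gap rule
use    <- use_intensity_fields(tracks)             # weights + inflation
pe     <- relative_probability(adjust_effort(
            world$hooks, billfish_fraction(world$catch),
            catchability_index(gear_params())))
surf   <- interaction_index(relative_probability(use$fields$EP), pe)
top_hotspots(surf, k = 3)
#>   rank lat_lo lon_lo quarter      value
#> 1    1      0    180       3 0.93719758
#> 2    2      0    180       1 0.03318491
#> 3    3      0    180       2 0.01621076
```

The top-ranked cell-quarter is exactly the planted truth
(`world$truth`: lat 0, lon 180, quarter 3), and its value — 94% of all
risk — is the share of total turtle–hook co-occurrence attributed to
that cell-quarter; the whole surface sums to 1. `run_pipeline()` wraps
the same steps end to end and writes fields, hotspot tables and a JSON
manifest with checksums; `inst/cli/bycatchr.R` exposes each stage as a
shell subcommand.

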