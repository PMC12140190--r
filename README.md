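# gyreflow

Underway flow-cytometry transect analysis across ocean gyre boundaries.

Subtropical gyres are bounded by salinity fronts across which the small
phytoplankton community (< 5 µm) reorganizes: the picocyanobacterium
*Prochlorococcus* dominates the nutrient-poor gyre interior, while pico-
and nanoeukaryotes take over in the richer waters beyond the front.
gyreflow is for oceanographers working with hourly shipboard
flow-cytometry data (SeaFlow-style) who want to quantify that transition:
it turns per-population light-scatter and abundance series into cell
size, carbon biomass and daily growth rates, locates the gyre boundary
from the underway salinity record, and tests regional contrasts and
correlations with multiple-testing control.

## What it computes

**Scatter → carbon.** Bead-normalized forward scatter is converted to
equivalent spherical diameter (ESD) through a calibration table,
interpolated log-log between nodes. The working refractive index is
chosen per cruise from candidates n ∈ {1.35, 1.38, 1.41}: the table whose
median *Prochlorococcus* ESD is closest to the 0.6 µm reference wins.
Then V = (π/6)·ESD³, the allometric carbon quota

> Q_C = 0.261 · V^0.86  (pgC cell⁻¹, V in µm³),

and biomass = abundance × Q_C (µgC L⁻¹).

**Diel kinetics.** Hourly quota series are detrended with a
multiplicative 24-h moving-average decomposition. For each population-day
the daily growth rate comes from ordinary least squares on the daytime
log-quota increase,

> ln Q_C(t) = r·t + ln Q_C,0,

with t in hours since sunrise (daytime = PAR > 10 µmol photons m⁻² s⁻¹)
and r converted to d⁻¹ by the daylight duration. Fits are accepted when
they use more than 6 hourly observations (abundance ≥ 0.02 × 10⁶
cells L⁻¹) and the slope p-value is ≤ 0.01.

**Gyre geometry.** A smoothing spline of salinity against haversine
along-track distance yields |dS/dx|; candidate fronts are its local
maxima, and among candidates the one with salinity closest to 35 PSU is
the gyre boundary. Distances from the boundary are signed (negative
inside the gyre) and a transition-zone width (gradient ≥ ½ peak) is
reported.

**Regional statistics.** 24-h bin means feed Welch t-tests
(inside vs outside) and a pairwise-complete Pearson correlation screen
with Benjamini–Hochberg FDR control at 0.01.

A synthetic-cruise generator (`simulate_cruise()`) with known ground
truth — logistic front, half-sine PAR, diel quota dynamics, lognormal
noise — backs every stage with parameter-recovery tests.

## Worked example

```r
library(gyreflow)

cruise <- simulate_cruise(cruise_config(), seed = 42)
report <- run_pipeline(cruise$underway, cruise$populations,
                       cruise$nutrients)
report
#> <cruise_report>
#>   refractive index: 1.38
#>   gyre boundary: 4000.3 km along track (transition zone 45.9 km)
#>   growth fits: 60 attempted, 34 accepted
#>   24-h bins: 15; correlation pairs: 65 (36 significant)

report$summary$growth_by_region
#> # A tibble: 8 x 3
#>   population      region  r_daily
#> 1 nanoeukaryote   inside    0.176
#> 2 picoeukaryote   inside    0.218
#> 3 Prochlorococcus inside    0.444
#> 4 Synechococcus   inside    0.256
#> 5 nanoeukaryote   outside   0.171
#> 6 picoeukaryote   outside   0.231
#> 7 Prochlorococcus outside   0.321
#> 8 Synechococcus   outside   0.249

report$summary$biomass_fraction_inside
#> # A tibble: 4 x 3
#>   population      biomass fraction
#> 1 nanoeukaryote      1.98   0.151
#> 2 picoeukaryote      1.04   0.0799
#> 3 Prochlorococcus    8.73   0.669
#> 4 Synechococcus      1.30   0.0995
```

The generating truth for this cruise put the front at 4000 km,
*Prochlorococcus* growth at 0.43 d⁻¹ inside / 0.28 d⁻¹ outside, and a
within-gyre *Prochlorococcus* biomass of ≈ 7.7 µgC L⁻¹: the pipeline
recovers the boundary to a third of a kilometre and the regional growth
and dominance structure within sampling noise (34 of 60 population-days
pass the acceptance filters at this noise level; the report's `log`
accounts for every rejected fit). `report$correlations` holds the
FDR-screened correlation table, e.g. *Prochlorococcus* biomass correlates
positively with temperature and negatively with DIN/DIP across 24-h bins.

A thin command-line wrapper ships in `inst/scripts/gyreflow-cli.R`
(`simulate` and `run` subcommands).

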