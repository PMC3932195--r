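# cdrisk

Probability mapping of soil cadmium pollution under a **composite**
environmental quality standard — one whose Cd threshold depends on the
local soil pH interval and land-use type — using conditional sequential
Gaussian simulation (SGS).

The package is written for environmental geostatisticians and soil
scientists who have point samples of topsoil Cd and pH, a categorical
land-use map, and a regulatory table of pH- and land-use-dependent
thresholds, and who need a per-cell probability that the soil is actually
polluted (i.e. that Cd exceeds its *locally applicable* threshold), plus
priority-remediation masks derived from that probability.

## The method

A composite standard partitions the pH scale into `S` intervals with
breakpoints `α_0 < … < α_S` and gives, for each land use, a threshold
`β_i` per interval. The packaged default is the Chinese grade-II standard
for Cd (mg/kg), four intervals × three land uses:

| | 0 ≤ pH < 5.5 | 5.5 ≤ pH < 6.5 | 6.5 ≤ pH < 7.5 | 7.5 ≤ pH ≤ 14 |
|---|---|---|---|---|
| paddy field | 0.25 | 0.30 | 0.50 | 1.00 |
| dry farmland | 0.25 | 0.30 | 0.45 | 0.80 |
| nonfarmland | 10.00 | 10.00 | 10.00 | 10.00 |

Both Cd and pH are uncertain away from the sample points, so the
applicable threshold is itself uncertain. Each attribute is normal-score
transformed, its omnidirectional variogram is fitted (spherical /
Gaussian / exponential, weighted least squares), and `L` equiprobable
conditional realizations are simulated on a regular grid by SGS. With the
land use known per cell, the standard-exceeding probability at cell `x`
is the mixture over pH intervals

    P[Z(x) > z_c(x)] = Σ_{i=1..S}  P[α_{i-1} ≤ z_pH(x) < α_i] · P[z_Cd(x) > β_i(x)]

with both factors estimated as counting frequencies over the `L`
realizations (`product` mode; valid because Cd and pH are simulated
independently, a choice supported by their sample cross-correlogram). A
`joint` mode that counts paired realizations directly is also provided.
Cells with probability at or above a critical value `p_c` (0.90 and 0.95
by default) form the priority-remediation mask; raising `p_c` can only
shrink the mask.

Because no sample data ship with the package, a first-class synthetic
generator builds a realistic study area (independent Gaussian random
fields by circulant embedding mapped to literature-style Cd and pH
marginals, a patchy three-class land-use map, and a 150-point sample
draw), so the whole chain is testable end to end.

## Worked example

```r
library(cdrisk)
cfg <- run_config(list(seed = 1, L = 100,
                       grid = list(nx = 60, ny = 60, cell_size = 60),
                       n_samples = 150))
res <- run_pipeline(cfg, quiet = TRUE)
descriptive_stats(res$samples$cd)
res$cd_fit$vm
res$prob_map
res$masks$`p0.90`
res$masks$`p0.95`
```

```
  attribute   n  min      max    median      mean        sd   cv_pct variability
1        cd 150 0.26 1.745133 0.5801554 0.6155414 0.2342102 38.04947    moderate
variogram_model: spherical, C0 = 0.4318, C = 0.6175, a = 1689 m (nugget ratio 0.41)
grid_map 'p_exceed': 60 x 60 cells; range [0, 1], mean 0.5784
risk_mask: p_c = 0.90; 1091 cells flagged (3.928 km2)
risk_mask: p_c = 0.95; 759 cells flagged (2.732 km2)
```

Reading the output: the 150 synthetic samples show moderate variability
(CV 38%); the fitted normal-score variogram has a nugget ratio of 0.41
(moderate spatial autocorrelation), so kriging inside the simulation has
real structure to work with. The probability map assigns each 60 m cell
the frequency with which its simulated Cd exceeded its simulated
pH-and-land-use threshold over `L = 100` realizations; 1091 cells
(3.93 km²) exceed with probability ≥ 0.90, shrinking to 759 cells at
`p_c = 0.95`. On this scenario every nonfarmland cell has probability 0
— its 10 mg/kg threshold is far above any simulated concentration —
while farmland cells carry most of the risk.

The same workflow is available from a shell:

```sh
Rscript inst/cli/cdrisk.R pipeline --seed 1 --L 500 --out run1
Rscript inst/cli/cdrisk.R synth --seed 1 --out scenario   # write a scenario to files
Rscript inst/cli/cdrisk.R delineate --prob run1/probability.asc --pc 0.90,0.95 --out run1
```

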