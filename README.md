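# phytopart

Two-community vertical partitioning of phytoplankton biomass profiles.

Ocean-colour satellites observe, at best, the first optical depth of the
ocean. In seasonally or permanently stratified water columns a second
phytoplankton community lives below the mixed layer — usually expressed as
a deep chlorophyll maximum (DCM) — invisible to the satellite.
`phytopart` is for oceanographers working with profiling-float
(BGC-Argo-style) chlorophyll and backscattering data who want to split a
vertical profile into the satellite-visible, mixed-layer community and the
hidden subsurface community, follow both through a seasonal cycle, and tie
them to their physical environment.

## The model

In dimensionless coordinates — optical depth `τ = z·Kd`, chlorophyll
normalised by its surface value `B_s` — the profile is the sum of a
sigmoid (community 1, mixed layer) and a Gaussian (community 2, DCM):

```
B*(τ) = 1 − 1 / (1 + exp(−(P1/τ1)(τ − τ1)))  +  B*₂,m · exp(−((τ − τ2)/σ)²)
```

with constraints `P1 ≥ 4.6` (community 1 exceeds 99% of the surface
signal) and `τ2 ≥ 3σ` (community 2 stays below 1% at the surface), so the
surface total is pinned to 1 within 1%. A two-step tuning fits the sigmoid
alone first and adds the Gaussian only when the sigmoid explains less than
90% of the variance *and* the AIC improves; parameters are bootstrap
medians (1,000 case resamples) with 95% percentile intervals. The same
community shapes then partition particle backscattering at 700 nm,

```
b*bp(τ) = (1 − b*bp,k)·B1*(τ) + ω2·B2*(τ) + b*bp,k ,
```

yielding each community's chlorophyll-specific backscattering coefficient
and a non-algal background `b^k_bp = b*bp,k · b_bp,s`. Bloom phenology
(initiation, termination, duration) comes from cumulative sums of
anomalies of each community's column-integrated series against a
1.05 × median threshold with a 15-day persistence rule.

The package also derives the per-profile context (Beer–Lambert `Kd`,
euphotic depth `Zp = 4.6/Kd`, daily PAR from a sinusoidal light cycle,
EOS-80 density, Brunt–Väisälä stratification index, Holte–Talley-style
mixed-layer depth) and ships a synthetic-profile generator with embedded
ground truth that emulates a winter-mixing-to-summer-DCM seasonal cycle.

## Worked example

```r
library(phytopart)

rec <- make_profile(                    # stratified summer profile, DCM at 100 m
  list(P1 = 7.8, tau1 = 2.9, B2m_star = 3, tau2 = 5, sigma = 0.8),
  Kd = 0.05, B_s = 0.08, Zm = 20, seed = 101
)
ctx <- derive_context(rec)
ctx
#> <optical_context> Kd=0.0499 m-1 (fitted)  Z_p=92.1 m  Z_m=17.9 m
#>   B_s=0.079 mg m-3  b_bp_s=0.00070 m-1  N2 index=1.301e-04 s-2

fit <- partition_profile(rec, ctx, boot_n = 1000)
fit
#> <chl_partition> mode=two_community  P1=7.72 tau1=2.84  B2m*=3.07 tau2=4.99 sigma=0.80
#>   r2(step1)=0.428  AIC -158.6 -> -1062.5  (n=186)

partition_bbp(rec, ctx, fit, boot_n = 1000)
#> <bbp_partition> mode=two_community  b*bp,k=0.502 omega1=0.498 omega2=0.094
#>   bbp1B=4.40e-03  bbp2B=8.28e-04  bbpk=3.51e-04 m-1  (n=301)
```

Reading the output: the sigmoid alone explains only 43% of this profile's
variance, so the Gaussian is added and retained (AIC drops), recovering
the generating DCM (amplitude 3.07 vs 3, position τ2 = 4.99 vs 5, i.e.
100 m at this `Kd`). Half the surface backscattering is non-algal
background (`b*bp,k = 0.50`, `bbpk = 3.5e-4 m⁻¹`), and community 1 carries
about five times more backscattering per unit chlorophyll than
community 2 (`bbp1B` vs `bbp2B`) — the DCM is rich in chlorophyll but
comparatively poor in carbon.

`run_pipeline()` chains the whole workflow (read/simulate → context →
chlorophyll partition → backscattering partition → community series →
phenology → output tables); a command-line front end with `simulate`,
`fit`, `phenology` and `report` subcommands is installed at

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/phytopart.R", package = "phytopart"))')" \
    simulate --out profiles.csv --cadence 5 --seed 42
```

Input profiles are a long-format CSV (one row per cycle and depth level;
see `?read_profiles_csv` for the column dialect and Argo-style QC-flag
handling).

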