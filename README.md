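# terrasoc

Quantifying and attributing changes in soil organic carbon (SOC) stocks
caused by agricultural terracing.

Terrace construction excavates topsoil upslope (*cut* positions) and buries
it downslope (*fill* positions). Whether the soil ends up storing more or
less carbon depends on how fast plant inputs replace the excavated carbon
and how well the buried carbon is stabilized — both governed by climate
through soil geochemistry and plant productivity. `terrasoc` implements the
full computational workflow for this question, aimed at soil
biogeochemists and carbon-cycle modellers working with depth-explicit
profile data and gridded soil products:

- **Stock accounting** — per-horizon SOC density
  `SOC/100 · BD_fine · 10` (kg C m⁻² cm⁻¹), pedotransfer bulk density
  `BD = a·SOC + b·clay + c·silt + d` where unmeasured, gravel correction
  above a 3 % mass threshold, profile integration, and depth
  harmonization of 6-/7-layer gridded stock profiles. The headline metric
  is `ΔSOC = 100 · (SOC_terraced − SOC_control)/SOC_control` (%).
- **Monte Carlo control imputation** — for sites without field-measurable
  controls: calibrate the bias `field = α + β·gridded + N(0, σ)` on
  measured sites, draw M = 1000 realizations per site
  (`α + β(g ± SE) + N(0, σ)`, with optional propagation of the
  calibration parameters' own sampling uncertainty), merge measured and
  imputed ensembles, and report site credible intervals plus
  uncertainty-propagated ΔSOC–aridity regressions.
- **FTIR organic chemistry** — reflectance → absorbance (`log₁₀(1/R)`),
  mineral-region masking, chord-baseline peak heights for aliphatic,
  carboxylic and aromatic bands, area-normalized composition ratios.
- **Attribution** — climate stratification at AI = MAP/PET = 1,
  varimax-rotated PCA (retain eigenvalue > 1 and > 5 % variance), linear
  mixed models with marginal/conditional R², variation partitioning among
  ligand-exchange / cation-bridging / SOC-chemistry blocks, VIF-pruned
  random-forest Monte Carlo cross-validation, and a composite path model
  ΔTPP → geochemistry → ΔSOC with bootstrap and 10-fold-CV stability.
- **Productivity & synthesis** — Savitzky-Golay smoothing, growing-season
  TPP integrals, vegetation indices, a five-rule literature-synthesis
  filter and the loess ΔSOC–aridity trend.
- **Synthetic world** — a seeded generator with known ground truth
  (climate gradient, profiles, gridded bias structure, spectra,
  phenology, synthesis records) backing every test.

## Worked example

```r
library(terrasoc)

world <- generate_world(world_config(), seed = 1)   # 14 sites, AI 0.32-2.17
fit   <- impute_deltas(world$site_delta, world$gridded$sites,
                       M = 1000, seed = 42)
print(fit$bias)
#> Bias model: field = 11.159 + 0.661 * gridded + N(0, 12.466)  [n = 9, R2 = 0.888]

post <- posterior_summaries(fit$ensemble)
reg  <- posterior_regression(fit$ensemble, n_rep = 1000)
print(reg)
#> Posterior dSOC-AI regression over 1000 repetitions:
#>   slope: median 54.87 [43.01, 65.96]
#>   R2:    median 0.790 [0.622, 0.885]
#>   P:     median 2.138e-05; fraction p < 0.05 = 1.000
```

The bias model says the gridded product under-states ΔSOC at the high end
(slope 0.661) with a ±12.5 % residual; the posterior regression says ΔSOC
rises by ~55 percentage points per unit of aridity index and the
relationship survives the full imputation uncertainty (every one of the
1000 repeated regressions is significant). Stratum means from `post` for
this world are +71.7 % (humid, n = 9) versus +14.4 % (arid, n = 5) —
terracing gains carbon consistently in humid climates and inconsistently
in arid ones.

The numbered drivers under `analysis/` run the whole study in order
(`01_simulate.R` … `06_productivity_synthesis.R`), writing tidy tables
under `results/`; `run_pipeline()` performs the same sequence in one call
and `make_report()` lays the outputs out as a plain-text report.

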