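# crococompete

Quantitative tools for asking how competitive the unicellular
N₂-fixing cyanobacterium *Crocosphaera watsonii* is for **combined
nitrogen** (NH₄⁺ and NO₃⁻) — the nutrients a diazotroph can, in
principle, do without. The package is aimed at marine microbial
ecologists and biogeochemical modellers working with short bottle
incubations, flow-cytometry population summaries and acetylene-reduction
assays.

It provides four connected pieces:

1. **Growth kinetics** — per-group growth as a sum of Monod terms,

   μᵢ = Vᴺᴴ⁴ₘₐₓ,ᵢ·[NH₄⁺]/([NH₄⁺]+Kᴺᴴ⁴ᵢ) + Vᴺᴼ³ₘₐₓ,ᵢ·[NO₃⁻]/([NO₃⁻]+Kᴺᴼ³ᵢ),

   with bottle dynamics dNᵢ/dt = (μᵢ − mᵢ)Nᵢ under an empirically fitted
   quadratic nutrient forcing, and an optional diazotrophy floor
   (μ ≥ 0.31 d⁻¹) when N₂ fixation is enabled.
2. **Ecosystem competition** — a three-pool
   phytoplankton–phytoplankton–zooplankton model with *kill-the-winner*
   grazing, Gᵢ ∝ Nᵢ²/(N²_Cro+N²_Oth), quadratic grazer mortality, and the
   three canonical nutrient scenarios (replete, depleted, depleted +
   fixation).
3. **Biomass & nitrogen budgets** — bead-calibrated forward-scatter →
   cell volume → carbon (235 fg C μm⁻³ volumetric, or the modified
   Strathmann law log₁₀C = 0.94·log₁₀V − 0.6) → nitrogen (molar C:N) →
   population nmol N L⁻¹, plus drawdown-vs-biomass budgets and the
   fixation share of N demand from acetylene reduction (4:1
   ethylene : N₂).
4. **Fitting & synthetic data** — bounded multistart least-squares
   parameter recovery, and a fully seeded synthetic-experiment generator
   with ground-truth sidecars, so the whole pipeline is testable with no
   field data.

Everything is tibble-in / tibble-out and pipe-friendly; results carry
`autoplot()` methods, fits support `tidy()`/`glance()`.

## Worked example

```r
library(crococompete)
library(dplyr)

# growth rates at 100/100 nmol L^-1
g <- default_phyto_params()
monod_growth_rate(g$cro, nutrient_pair(100, 100))   # 3.533333 d^-1
monod_growth_rate(g$oth, nutrient_pair(100, 100))   # 1.583333 d^-1

# a complete synthetic incubation experiment, then the budget chain
exp  <- generate_experiment(generator_config(seed = 1))
cal  <- calibrate_size(exp$beads)
bio  <- estimate_biomass(exp$fcm, cal)
nitrogen_budget(exp$nutrients, bio, arr = exp$arr) |>
  select(treatment, drawdown_nmol_l, biomass_increment_nmol_l,
         ratio, pct_fixation)
#>   treatment drawdown_nmol_l biomass_increment_nmol_l ratio pct_fixation
#> 1   control            18.7                     8.75 0.467         4.59
#> 2       nh4           130.7                    60.06 0.460         5.02
#> 3       no3           113.5                    55.43 0.488         5.94
#> 4         p            18.1                     5.39 0.297         6.22
```

The `ratio` column says biomass growth explains roughly half of the
measured combined-N drawdown (the generator's unexplained-sink truth is
0.5), and `pct_fixation` is the share of *Crocosphaera*'s gross N demand
met by N₂ fixation (truth 5 %). The remainder of the drawdown is the
unexplained sink — luxury uptake plus estimation error.

```r
scenario_suite(t_end = 10) |>
  filter(time == 10) |>
  tidyr::pivot_wider(id_cols = scenario, names_from = group,
                     values_from = n_nmol_l)
#>   scenario      Cro      Oth   Zoo
#> 1        A 2.19e+15 7.49e+06 9.94
#> 2        B 1.59     1.86     0.81
#> 3        C 6.15     1.72     5.21
```

Read relative, not absolute, abundances (nutrients are held constant per
scenario): at replete nutrients (A) *Crocosphaera* dominates on raw
uptake capacity; at 1 nmol L⁻¹ (B) it is slightly outcompeted; with the
fixation floor active (C) it keeps growing where its competitor cannot.

A single call runs the whole chain — generate → calibrate → biomass →
budget → forcing fit → incubation replay → parameter fit → scenarios —
and writes every stage plus a checksum manifest:

```r
res <- run_pipeline("out", seed = 1)
```

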