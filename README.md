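# dopaflow

Knowledge-driven design-build-test-learn (DBTL) analysis for a two-enzyme
dopamine pathway in *Escherichia coli*.

Dopamine is made heterologously from l-tyrosine in two steps:
4-hydroxyphenylacetate 3-monooxygenase (HpaBC) hydroxylates l-tyrosine to
l-DOPA, and l-DOPA decarboxylase (Ddc) decarboxylates l-DOPA to dopamine.
Productivity hinges on *balancing* the two enzymes: too little Ddc
accumulates l-DOPA (lost to spontaneous melanin formation), too much wastes
expression capacity. `dopaflow` is aimed at metabolic engineers prototyping
such balances; it implements the full loop in silico:

- **`simulate_mix()` / `titrate()` / `optimal_ratio()`** — the in vitro
  crude-lysate experiment as a two-step Michaelis-Menten cascade with
  fixed-total-volume mixing (HpaBC fraction *r*/(*r*+1), Ddc 1/(*r*+1)) and
  an optional first-order l-DOPA oxidation sink:

  d[TYR]/dt = −v₁, d[DOPA]/dt = v₁ − v₂ − k_ox·[DOPA], d[DA]/dt = v₂,
  with v₁, v₂ the fraction-scaled Michaelis-Menten rates.

- **`enumerate_sd_space()` / `strategy_a_match()` / `strategy_b_sample()` /
  `assemble_design_sheet()`** — translate the optimal enzyme ratio into
  bi-cistronic RBS pairs over the 6-nt Shine-Dalgarno space (4⁶ = 4,096
  variants per gene; 16.8 million ordered pairs) by matching translation
  initiation rate (TIR) ratios in log space (strategy A), plus seeded,
  GC-stratified boundary exploration (strategy B).

- **`success_rate()` / `fold_change()` / `specific_yield()` /
  `gc_stratified_analysis()` / `dopa_accumulation_flags()` /
  `recover_optimal_ratio()`** — the test-and-learn stage: build-funnel
  accounting, benchmarking, GC-content trend analysis and recovery of the
  optimal HpaBC:Ddc expression ratio from a measured cohort.

- **`gen_rbs_library()` / `gen_strain_results()` / `gen_build_log()`** — a
  synthetic-data module with a planted, documented response surface
  (`response_surface_truth()`), so the whole pipeline runs and is tested
  without any wet-lab data.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects
support `tidy()`/`glance()`, and each result type has a plot builder
(`autoplot()`, `plot_titration()`, `plot_design_space()`,
`plot_gc_trend()`). See the methods vignette
(`vignettes/dopamine-dbtl-methods.Rmd`) for the models, parameter defaults
and their rationale.

## Worked example

```r
library(dopaflow)

# 1. In vitro: titrate the HpaBC:Ddc lysate ratio (1 mM l-tyrosine, 20 h)
titration <- titrate(kinetic_params())
titration
#> # A tibble: 7 × 4
#>   ratio dopamine_mM   dopa_mM dopamine_mg_per_L
#>   <dbl>       <dbl>     <dbl>             <dbl>
#> 1     1       0.180 0.0000328              27.6
#> 2     2       0.239 0.0000651              36.6
#> 3     5       0.298 0.000161               45.6
#> 4    10       0.324 0.000322               49.6
#> 5    20       0.339 0.000644               51.9
#> 6    50       0.348 0.00162                53.2
#> 7   100       0.349 0.00330                53.5
optimal_ratio(titration)
#> [1] 100
```

Dopamine rises monotonically with HpaBC excess and converges at high
ratios — the cascade rewards strong HpaBC over-representation because Ddc
is by far the more efficient enzyme.

```r
# 2. Design: 15 ratio-matched pairs + 41 boundary pairs = 56 designs
lib <- gen_rbs_library(n_per_context = 60, seed = 1)
sheet <- assemble_design_sheet(
  strategy_a_match(lib, targets = c(1, 2, 5, 10, 20, 50, 100),
                   n_per_target = c(2, 2, 2, 2, 2, 2, 3),
                   distinct_across_targets = TRUE),
  strategy_b_sample(lib, n = 41, seed = 2)
)
nrow(sheet)
#> [1] 56

# 3. Test + learn on a synthetic cohort (triplicates, planted optimum 2.6)
cohort <- gen_strain_results(sheet, response_surface_truth(), seed = 3)
gc_stratified_analysis(cohort, "hpaBC", c(0.8, 1))
#> # A tibble: 1 × 6
#>   fixed_context free_context direction    rho  p_value     n
#>   <chr>         <chr>        <chr>      <dbl>    <dbl> <int>
#> 1 hpaBC         ddc          negative  -0.924 1.63e-19    45
recover_optimal_ratio(sheet, cohort, lib)
#> # A tibble: 1 × 4
#>   optimal_ratio curvature     n method
#>           <dbl>     <dbl> <int> <chr>
#> 1          2.72    -0.832   168 quadratic
```

With the hpaBC RBS held at high GC (80–100%), titre falls as ddc RBS GC
rises (Spearman ρ = −0.92 over 45 strains): a *low*-GC (strong) ddc RBS
amplifies dopamine production. The learn step fits strength models to the
library, predicts each design's expression ratio, and locates the titre
peak at 2.72 — within 5% of the planted optimum of 2.6.

```r
# 4. Build accounting
success_rate(51, 56)     # constructed / designed
#> [1] 91.1
fold_change(69.03, 27)   # best titre vs the 27 mg/L literature benchmark
#> [1] 2.6
```

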