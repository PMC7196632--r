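# nadreg

Quantitative models of the regulation of glutamine-dependent NAD
synthetase (NadE2) by PII signal-transduction proteins.

NadE2 catalyses the last step of NAD⁺ biosynthesis (NaAD → NAD⁺) and is
feedback-inhibited by its product. Trimeric PII proteins (GlnB/GlnZ/GlnK)
bind NadE2 as a dissociable regulatory subunit and reshape that feedback:
the free enzyme follows a hyperbolic inhibition curve
*v = v₀(1 − I/(Kᵢ+I))* with Kᵢ = 1 mM NAD⁺, while the PII-bound enzyme
follows a sigmoidal Hill curve *v = v₀(1 − Iⁿ/(IC₅₀ⁿ+Iⁿ))* with
IC₅₀ = 2.5 mM and n = 2.2 — so PII relieves inhibition exactly in the
physiological NAD⁺ range. Complex formation (K_d ≈ 300 nM with ATP,
measured by biolayer interferometry from k_ON = 9.09×10⁴ M⁻¹s⁻¹ and
k_OFF = 2.72×10⁻² s⁻¹) is antagonised by 2-oxoglutarate with a strong
history dependence: 2-OG blocks complex *formation* with a half-effect of
15.5 µM but dissociates a *pre-formed* complex only at ~1 mM — a
regulatory memory. PII uridylylation removes it from the binding pool
altogether.

The package provides, as a tidyverse-native toolkit (data frames in,
tibbles out, `tidy()`/`glance()`/`autoplot()` on fitted objects):

- **Kinetics** — six closed-form rate/dose–response models, multi-start
  bounded nonlinear least squares (`fit_model()`), AICc / F-test model
  discrimination (`compare_models()`), mechanism classification from
  paired saturation fits (`classify_inhibition()`), and initial-velocity
  reduction of assay traces (`initial_velocity()`).
- **BLI binding** — sensorgram simulation, reference subtraction +
  Savitzky–Golay smoothing, global 1:1 and 2:1 heterogeneous fits
  (`fit_binding_global()`), `kd_from_rates()`, and the 2-OG half-effect
  constant from plateau responses (`og_inhibition_constant()`).
- **Regulatory switch** — a two-state population model
  (`predicted_activity()`) mixing the two inhibition curves by the
  tight-binding complex fraction, with history-dependent effective K_d
  and hysteresis scans (`hysteresis_scan()`).
- **Genomic islands** — the PII–nadE gene-neighbourhood pipeline on
  homology hit tables: genome dereplication, ±10 kb island calling at
  e ≤ 1e-5, strict <2000 bp midpoint pairing, dereplication, taxonomy
  roll-up (`islands_pipeline()`).
- **Similarity clustering** — all-vs-all similarity graphs, seeded
  force-directed 2-D layout, connected-component cluster extraction.
- **Enrichment** — ligand-fishing log₁₀ bait/control ranking.
- **Synthetic data** — seeded generators with ground truth for every
  stage (`sim_dose_response()`, `sim_sensorgrams()`, `sim_genome_set()`,
  `sim_protein_families()`, `sim_lfq_table()`).

## Worked example

Simulate a PII-bound NAD⁺ dose–response at an 8-level triplicate design
with 3 % noise, fit it, and ask whether the sigmoidal model beats the
hyperbola:

```r
library(nadreg)

d <- sim_dose_response("hill_inhibition",
  c(v0 = 100, Imax = 1, IC50 = 2.5, n = 2.2),
  concentrations = c(0, 0.25, 0.5, 1, 2, 4, 7, 10),
  noise_cv = 0.03, replicates = 3, seed = 42
)
fit <- fit_model(d, "hill_inhibition", fixed = c(Imax = 1), seed = 1)
fit
#> <nadreg_fit> hill_inhibition
#>   v0 = 102.000 +/- 0.7540
#>   Imax =   1.000 (fixed)
#>   IC50 =   2.441 +/- 0.0457
#>   n =   2.254 +/- 0.0755
#>   rss = 91.27 on n = 24

compare_models(
  fit_model(d, "hyperbolic_inhibition", fixed = c(Imax = 1), seed = 1),
  fit, "f_test"
)
#> # A tibble: 1 × 4
#>   criterion preferred       statistic  p.value
#>   <chr>     <chr>               <dbl>    <dbl>
#> 1 f_test    hill_inhibition      764. 5.35e-18
```

The recovered IC₅₀ (2.44 ± 0.05 mM) and Hill coefficient (2.25 ± 0.08)
sit on the generating truth, and the extra-sum-of-squares F test
decisively prefers the sigmoid — the same discrimination that
distinguishes the PII-bound from the free enzyme.

A global 1:1 fit of a five-concentration sensorgram set recovers the
binding rates and hence the equilibrium constant:

```r
sg <- sim_sensorgrams(binding_params(9.09e4, 2.72e-2, Rmax = 2),
  noise_sd = 0.02, seed = 42
)
fit_binding_global(sg, "one_to_one", n_starts = 4, seed = 1)
#> <bli_fit> one_to_one
#>   site 1: kON = 93230 M-1 s-1, kOFF = 0.02632 s-1, Rmax = 1.99 nm, Kd = 282.4 nM
#>   rss = 2.122 on n = 2255
```

And the switch model predicts the physiological consequence: at 2.5 mM
NAD⁺ with 2 µM PII trimer, 86 % of the enzyme is complexed and activity
is held at 47 % instead of the 29 % the free enzyme would show:

```r
predicted_activity(
  hub_state(NAD = 2.5, PII_total = 2, NadE_total = 0.1),
  switch_params()
)
#> # A tibble: 1 × 4
#>   activity complex_fraction Kd_eff PII_avail
#>      <dbl>            <dbl>  <dbl>     <dbl>
#> 1     47.1            0.864    0.3         2
```

`plot_hysteresis(hysteresis_scan(hub_state(NAD = 2.5, PII_total = 2)))`
draws the 2-OG memory loop; `autoplot()` works on any fit object.

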