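---
title: "Models and methods behind nadreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nadreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadreg)
```

# The biological system

Glutamine-dependent NAD synthetase (NadE2) catalyses the final, committed
step of NAD⁺ biosynthesis, the amidation of NaAD to NAD⁺. In many
proteobacteria the trimeric PII signal-transduction proteins (GlnB, GlnZ,
GlnK) bind NadE2 and act as a dissociable regulatory subunit: PII binding
reshapes the enzyme's response to its feedback inhibitor NAD⁺, and PII
itself integrates the cellular carbon/nitrogen state through
2-oxoglutarate (2-OG), ATP/ADP, and uridylylation of its T-loop. nadreg
implements the quantitative layers of that picture: the dose–response
models and their fitting, biolayer-interferometry (BLI) binding kinetics,
an integrated two-state activity model with complex-history hysteresis,
and the comparative-genomics pipeline that finds PII–nadE gene
neighbourhoods, plus seeded synthetic-data generators for every stage.

# Dose–response and rate models

The package defines six closed forms (`rate_model()`):

* Michaelis–Menten: $v = V_{max} S/(K_m+S)$
* noncompetitive MM: $v = \frac{V_{max}}{1+I/K_i}\cdot\frac{S}{K_m+S}$ —
  the inhibitor lowers apparent $V_{max}$ and leaves $K_m$ untouched
* hyperbolic inhibition: $v = v_0\,(1 - I_{max}\, I/(K_i+I))$
* Hill (sigmoidal) inhibition: $v = v_0\,(1 - I_{max}\, I^n/(IC_{50}^n+I^n))$
* hyperbolic activation: $v = v_{floor} + (v_{ceil}-v_{floor})\,A/(K_{act}+A)$
* effector inhibition (percent-inhibition scale):
  $f = B + (T-B)\,E/(K_E+E)$

$K_i$ and $IC_{50}$ are treated as the same kind of quantity — empirical
half-effect constants of the respective curve — not mechanistic binding
constants. $I_{max}$, the maximum fractional inhibition, is a free
parameter in principle: NAD⁺ inhibition of the free enzyme leaves a
residual activity near 17 % at 2.5 mM NAD⁺, which a full-inhibition
hyperbola with $K_i = 1$ mM cannot produce (it predicts ≈ 29 %); either a
sub-unity $I_{max}$ or extra cooperativity can reconcile the two, and the
package exposes both without deciding. Default fits fix $I_{max}=1$
unless the user frees it.

Units follow the assay conventions: enzyme concentrations per monomer
(NadE2 activity assays) or per dimer (BLI analyte), PII per trimer,
NAD⁺/NaAD in mM, 2-OG in µM, rates in µmol s⁻¹.

## Fitting

`fit_model()` minimises the unweighted residual sum of squares with
Levenberg–Marquardt under box bounds (`minpack.lm::nls.lm`), restarted
from multiple seeded starting points; the lowest-RSS solution wins, so
the Hill curve's local minima are handled robustly. The first start is a
data-driven heuristic ($v_0$ from the response at zero dose, half-effect
constants from the median positive dose); the remaining draws are
log-uniform within the bounds for strictly positive scale parameters and
uniform otherwise. Log-uniform draws were chosen because the default
bounds span several decades and linear-uniform sampling would almost
never propose starts near small true values. Standard errors come from
the Gauss–Newton curvature, $\hat\sigma^2 (J^\top J)^{-1}$ with $J$ the
residual Jacobian at the optimum — adequate for the well-conditioned
designs used here. Fits are bit-reproducible given data, options, and
seed; the global RNG stream of the caller is saved and restored so
fitting never perturbs a simulation protocol.

Model discrimination (`compare_models()`) offers AICc (with the error
variance counted as a parameter) and, for nested pairs such as
hyperbola-vs-Hill, the extra-sum-of-squares F test.
`classify_inhibition()` formalises the competitive/noncompetitive call
from paired saturation fits by Wald confidence-interval overlap of $K_m$
and $V_{max}$: $V_{max}$ down with $K_m$ unchanged is the
allosteric/noncompetitive signature.

## Initial velocities

`initial_velocity()` reduces a progress trace to a rate using the
longest ≥ 3-point prefix whose refitted slope drifts less than a
tolerance (default 5 %) when the prefix grows — a deliberately simple,
brute-force-checkable definition of "the linear phase". Coupled-assay
absorbance slopes are converted via Beer–Lambert with
$\varepsilon_{NADH} = 6220$ M⁻¹ cm⁻¹ and a 1-cm path by default
(standard values for 340 nm).

# Biolayer interferometry

Sensorgrams are modelled with simple Langmuir kinetics: association
$R(t) = R_{eq}\,(1-e^{-(k_{ON}C+k_{OFF})t})$ with
$R_{eq} = R_{max}C/(C+K_d)$, dissociation decaying exponentially from
the association end point at $k_{OFF}$, and $K_d \equiv k_{OFF}/k_{ON}$.
Mass-transport limitation is ignored; Langmuir is the standard baseline
and the measured rates (about $9\times10^4$ M⁻¹ s⁻¹) are far from the
transport-limited regime. The 2:1 heterogeneous-ligand model is the sum
of two independent 1:1 sites sharing the analyte concentration, each
with its own amplitude — the standard vendor definition.

`fit_binding_global()` fits all concentrations simultaneously with
shared rates and amplitude (per site), on log-parameters so positivity
is structural, multi-start as above. Association phases are zeroed to
their first point and dissociation time is measured from the
association end; baseline and loading are carried but not modelled.
Preprocessing (`bli_preprocess()`) is pointwise reference-sensor
subtraction followed by Savitzky–Golay smoothing (default window 11,
order 3 — gentle enough to leave a cubic untouched, strong enough to
halve white noise).

The 2-OG half-effect constant on complex formation
(`og_inhibition_constant()`) is fitted to *plateau* responses with a
hyperbolic decay; amplitudes or observed rates would be alternative
read-outs, and the plateau choice is documented here precisely because
it is a choice.

# The regulatory switch

`predicted_activity()` integrates the measured constants into a
two-state population model. The NadE2 pool splits into a PII-bound
fraction $f$ and a free fraction $1-f$; each state follows its own NAD⁺
feedback curve (Hill with $IC_{50} = 2.5$ mM, $n = 2.2$ when bound;
hyperbola with $K_i = 1$ mM when free) and the observed activity is the
linear mixture. Linear mixing is the simplest model consistent with a
two-state enzyme population and slow exchange on the assay timescale.

$f$ comes from the exact tight-binding quadratic for 1 trimer : 1 dimer
binding — necessary because the working concentrations (0.1–2 µM) are
comparable to the 0.3 µM complex $K_d$, where the excess-ligand
hyperbola misestimates occupancy. A 1:1 stoichiometry is assumed; no
stoichiometry measurement exists to contradict it.

2-OG enters as a competitive multiplier on the dissociation constant,
$K_{d,eff} = K_d\,(1 + \mathrm{OG}/K_{OG})$, rather than through an
explicit effector-site binding polynomial: only half-effect constants
are measured, not site occupancies. The regime constant $K_{OG}$ is
15.5 µM while the complex is forming and 1 mM once it is pre-formed.
That three-order-of-magnitude asymmetry, switched by a discrete
`history` flag, produces the memory effect: `hysteresis_scan()` runs an
ascending 2-OG branch in the pre-formed regime and a descending branch
in the forming regime, and the enclosed loop area is positive exactly
in the window between the two constants. History is a flag, not a
kinetic ODE, because two regimes are demonstrated, not interconversion
rates. Uridylylated PII simply leaves the binding pool
(`available_pii()`); ATP versus ADP is represented only through the
choice of `Kd_complex` (0.3 vs 0.15 µM).

Whether PII relief saturates below 100 % activity is left configurable
(the Hill curve's ceiling), not decided.

# PII–nadE genomic islands

The pipeline consumes precomputed homology hit tables (BLAST outfmt-6
layout via `read_hits_outfmt6()`) rather than shelling out to a search
engine, which keeps the bespoke logic deterministic and testable. The
rules, in order:

1. `dedupe_genomes()` — one assembly per species, type strains first,
   then assembly completeness, ties broken lexicographically by
   accession.
2. `call_islands()` — PII hits with e-value ≤ 1e-5 (the threshold value
   itself is retained) whose locus ± 10 kb fits entirely on the contig;
   windows truncated by a contig edge are discarded with a logged
   reason.
3. `pair_nade_with_pii()` — nadE hits inside an island are paired to
   the closest PII locus on the same contig by gene-midpoint distance
   (`floor((start+end)/2)`, strand ignored), kept when the distance is
   *strictly* below 2000 bp. Equidistant ties resolve to the
   lower-coordinate island. The distance reference is the PII *gene*
   midpoint by default with an `"island"` option, since the window
   midpoint is an equally defensible reading of the criterion.
4. `dereplicate_pairs()` — duplicates removed on identical protein
   sequence when sequences are supplied, else on protein id, first
   occurrence kept under a canonical (genome, contig, coordinate) sort.
5. `taxonomy_rollup()` — counts per lineage rank, unknown taxids in an
   `"unclassified"` bucket.

Coordinates are 1-based inclusive throughout (GFF3/BLAST convention).
Multiple PII paralogs per genome (glnB and glnK side by side) each
nucleate their own island; nadE genes are paired to the closest.

# Similarity clustering

`build_similarity_graph()` either ingests a hit table directly (the
exact-compatibility path) or aligns sequences pairwise (Smith–Waterman,
BLOSUM62, gap open 11 / extend 1) and converts scores to approximate
E-values with fixed Karlin–Altschul parameters (λ = 0.267, K = 0.041,
the standard gapped-BLOSUM62 values). Edge attraction is
$\min(-\log_{10} E, \text{cap})/\text{cap}$.

The 2-D embedding (`force_layout()`) is a seeded force-directed
relaxation — weighted attraction along edges, inverse-square repulsion
between all pairs regularized by an ε offset at coincident points,
damped and step-clipped, nodes processed in canonical order so the
result is bit-reproducible and input-order invariant. The layout is for
visualisation; cluster *assignment* (`extract_clusters()`) is by
connected components of the cutoff-filtered graph, labelled by
decreasing size with ties to the smallest member id. Components were
chosen over convex map-based clustering because they are deterministic
and brute-force checkable; on well-separated families the two coincide.

# Enrichment ranking

`enrichment_ranking()` scores ligand-fishing label-free intensities as
$\log_{10}((\text{bait}+c)/(\text{control}+c))$ per protein per elution
fraction. Base 10 and the pseudocount are this package's choices; the
default pseudocount is the smallest nonzero intensity in the table,
which is scale-free and avoids an arbitrary constant. As the
pseudocount shrinks the ratio diverges only for zero-control proteins —
the intended behaviour, since those are the unambiguous hits.

# Synthetic data and what passing tests mean

Each generator is a pure function of parameters and seed, and emits its
ground truth (`"truth"` attribute) alongside the data; one global seed
fans out to substreams via `substream_seed()` so adding a scenario
never shifts an existing one.

* `sim_dose_response()` applies multiplicative Gaussian noise (3 % CV
  by default, triplicate — typical for the discontinuous PPi assay) to
  any rate model.
* `sim_sensorgrams()` covers the Kd-determination design: analyte
  30–2000 nM, 150 s association, 300 s dissociation, 0.02 nm Gaussian
  noise and optional linear drift.
* `sim_genome_set()` plants PII–nadE pairs at controlled midpoint
  distances (< 2000 bp) with probability 0.6 per genome, plus decoys
  that exercise every discard rule: distant nadE genes (≥ 3 kb),
  edge-truncated PII windows, weak hits above the e-value threshold,
  and duplicate lower-priority assemblies. The taxonomy mix defaults to
  a β/γ-proteobacterial skew, echoing where these gene neighbourhoods
  are actually concentrated.
* `sim_protein_families()` point-mutates seeded random ancestors
  (within-family identity ≈ 90 % by default, between-family ≈ random);
  no indels or selection.
* `sim_lfq_table()` plants fold-enriched proteins on a log-normal
  background.

The generators emulate the *designs* of the underlying assays, not
their pathologies: no pipetting serial correlation, no BLI
mass-transport or sensor decay, no genome rearrangements or split
genes, no realistic sequence evolution. Recovery and recall/precision
tests therefore demonstrate correctness of the estimators and rules
under the stated noise models — not robustness to everything a real
instrument or database can produce.

## Reference studies and problem sizes

`recovery_study()` packages the simulate-then-fit round trips used to
verify each constant: median recovered value over 50 seeded replicates
at the assay-like designs listed in its help page. These sizes (8-level
dose ladders in triplicate, five-concentration sensorgram sets,
50-genome sets) were chosen to match the scale of the corresponding
experiments while keeping the full suite runnable on a laptop in well
under a minute per study.

# Numerical choices and degenerate inputs

* Optimizer: `nls.lm`, 200 (dose) / 300 (BLI) iteration cap; a fit is
  flagged `converged = FALSE`, never silently dropped, when no start
  terminates cleanly.
* Single-concentration BLI input warns and flags `confounded` (Kd and
  Rmax cannot be separated).
* `complex_fraction()` clamps its discriminant at zero and its output
  to [0, 1] against floating-point excursions; `NadE_total = 0` is
  defined as $f = 0$.
* Hill evaluation defines $0^n/(IC_{50}^n + 0^n) = 0$ for all $n > 0$.
* All-equal plateau responses raise a non-identifiability error rather
  than returning an arbitrary constant.
* Layout repulsion uses an ε = 10⁻⁶ offset so coincident seeds cannot
  produce infinite forces.

# Known limitations

Progress curves are reduced to initial velocities, never fitted
globally; the glutaminase/ammonia-tunnel chemistry is not modelled; the
switch model has no time axis (no uridylylation/deuridylylation
kinetics); BLI loading-phase kinetics and vendor file formats are out
of scope; the built-in aligner's E-values are approximate and meant for
synthetic benchmarks, with hit-table ingestion as the path of record;
and the genome pipeline deliberately stops at hit tables — it does not
reproduce any database-wide census, whose counts depend on the database
snapshot searched.
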