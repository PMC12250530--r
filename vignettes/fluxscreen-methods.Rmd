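---
title: "Methods: expression-constrained flux screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-constrained flux screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxscreen)
```

This vignette is the package's own account of its models, parameters and
numerical choices. It states no empirical result that the test suite does
not itself compute.

## 1. The model chain and its assumptions

### 1.1 From expression to flux bounds

The central assumption is Michaelis–Menten capacity limitation: a
reaction's flux can never exceed `Vmax = kcat · E`, with `E` an enzyme
abundance read off gene expression through the reaction's GPR rule. We
aggregate `AND` nodes by the **minimum** (a complex is limited by its
scarcest subunit) and `OR` nodes by the **sum** (isozyme capacities add).
These are the conventional semantics in expression-constrained
constraint-based modeling, but they are a *reconstruction*: the upstream
method this package re-implements defers its exact aggregation and
abundance units to its own reference, so both the `OR = sum` choice and the
single global calibration constant `scale` (default 1, i.e. expression is
taken to be on the enzyme-abundance scale in toy units) should be read as
explicit, documented approximations rather than a restatement of that
method. `scale` multiplies every Vmax and therefore only moves the overall
flux scale; every downstream statistic consumes relative structure.

Missing genes count as zero abundance, and reactions without a kcat (or an
explicit `default_kcat`) keep their generic bound — degradation is explicit
and testable. Reversible reactions are capped symmetrically
(`lb = max(lb, −Vmax)`): enzyme capacity has no direction.

The medium model is deliberately minimal: listed exchange reactions get
their uptake lower bound, *all* other exchanges are closed to uptake
(`lb = 0`), secretion is never restricted here.

### 1.2 Linear programming

FBA/FVA solve `opt c·v` s.t. `S·v = 0`, `lb ≤ v ≤ ub`. No R linear
programming package is part of the supported environment, so the package
carries a dense two-phase primal simplex (C++, `src/simplex.cpp`):
variables are shifted to `x = v − lb ≥ 0`, finite upper bounds become slack
rows, equality rows get phase-1 artificials. Per bound set, phase 1 runs
once and every FVA objective re-costs the same feasible tableau — the
"shared factorisation" reading of fast sequential-LP FVA tools; correctness
is defined by naive per-LP semantics and enforced in the tests, where all
results are compared against a brute-force vertex-enumeration oracle on
small random models. Numerical choices: pivot tolerance `1e-9`, Dantzig
pricing with a Bland's-rule fallback after a stall (anti-cycling),
feasibility declared at phase-1 objective `≤ 1e-7·(1 + max|b|)`, and a
mass-balance residual check (`1e-6`) on every returned FBA solution.
Determinism follows from the fixed pivot rules; repeated solves agree to
`1e-9`.

FVA is run **without** fixing any objective optimum: the published
analysis names no biomass objective, and the ranges are meant to describe
the whole feasible set. The per-sample scalar fed to the statistics is the
**FVA maximum** (`fva_max`) — the capacity-like quantity that
Vmax-style bounds actually move; the range midpoint (`fva_mid`) is a config
switch. Which summary the original analysis used is not stated anywhere we
could verify, hence the switch.

### 1.3 Metabolite knockout

Knocking out metabolite `m` blocks every non-exchange reaction direction
that *consumes* `m` (forward consumers get `ub = 0`, reverse consumers
`lb = 0`). Producers are left alone: removal of a pool should starve its
consumers, and blocking producers too would conflate supply with demand.
This "consumers-only" semantics is a reconstruction of an unstated
convention and is isolated behind `knockout_metabolite()` so the
alternative could be swapped in. A consequence worth knowing: knockouts can
only shrink the feasible region, so `M(KO)` entries of `+1` cannot occur
with this semantics (the code still detects them, with relative tolerance
`1e-6` and absolute floor `1e-9` against LP noise).

The pipeline measures knockouts against a **reference model built from the
mean control expression** — the "wild type" the patients are compared to.
Columns of `M(KO)` default to the differentially changed reactions only;
since non-significant reactions carry `L_j = 0`, this changes no MES value
and keeps the screen linear in the number of DE fluxes. `ko_columns: "all"`
restores the full matrix.

## 2. The statistics

### 2.1 Moderated differential flux

Fluxes enter the two-group linear model untransformed (a config switch
allows log2): the upstream description tests the modeled flux values
themselves. Residual variances are shrunk by the standard empirical-Bayes
recipe: with `d` residual df and `s²` per reaction,
`s²_post = (d₀·s₀² + d·s²)/(d₀ + d)`, where `d₀`, `s₀²` come from the
method of moments on `log s²` (Fisher-z style moment matching with a
Newton inversion of the trigamma function). The moderated t uses `d₀ + d`
df. We implement the formulas directly rather than calling an external
package so that the `d₀ → 0` limit can be asserted against the closed-form
pooled t (to `1e-9`), and the test suite cross-checks `d₀`, `s₀²`, t and p
against the reference empirical-Bayes implementation when it is installed.
Constant reactions (zero variance *and* zero difference) carry no
evidence: `t = 0`, `p = 1`.

Significance uses both gates, `p < 0.05` **and** `|log2fc| > 0.2`, the
jointly stated convention of the analysis this package reconstructs.
Whether the original DE call feeding the pathway and knockout scores used
the fold-change gate or only the p-gate is ambiguous; both are applied
here, and `fc_threshold = 0` disables the gate. The fold change uses a
pseudocount of `1e-6` of the grand mean flux so zero-capacity reactions
give finite values.

### 2.2 Pathway DA and its bootstrap null

`DA = (#up − #down)/#reactions` per subsystem. The null draws `B` (default
10 000) size-matched reaction subsets **without replacement from all scored
reactions** — not from the complement — which is the natural reading of a
size-matched subsampling null; the empirical two-sided p-value carries the
`+1/(B+1)` correction, so `p ≥ 1/(B+1)` always. The seed is a mandatory
argument: a resampling p-value without a recorded seed is not reproducible.

**Known limitation (and one deliberately red acceptance check).** DA is
discrete — multiples of `1/k` for a subsystem of size `k` — so the
distribution of its empirical p-values under a null is *super-uniform*: it
has large atoms (most prominently `p = 1` whenever the observed DA is 0)
and satisfies `P(p ≤ α) ≤ α` rather than equality. At a simulated null with
a realistic ~5% DE rate and subsystems of size 10, about two thirds of
subsystems sit at `DA = 0`, so a Kolmogorov–Smirnov test against U(0,1)
rejects with `D ≈ 0.66` — regardless of how correctly the bootstrap is
implemented. The corresponding acceptance check is therefore left failing,
with the measured type-I rate (0.042 at α = 0.05 in the same simulation)
documenting that the p-values are conservative, i.e. valid. Any
implementation whose DA p-values *passed* a KS uniformity test at this
sample size would have to be smuggling randomisation into the p-value
definition, which the stated formula forbids.

### 2.3 MES and the norm background

`MES_i = Σ_j M_ij · sign(log2fc_j) · L_j`. The weight `L_j` is not defined
in the upstream description (the symbol appears unhoused); we take the 0/1
significance indicator, the only reading under which MES is literally the
signed tally of DE flux changes that the knockout exacerbates — matching
the prose definition of an agonist. `l_weight = "abs_log2fc"` provides the
effect-size-weighted alternative. Under the indicator, MES is
integer-valued and bounded by the DE count; negating all fold-change signs
swaps agonists and antagonists exactly.

The background model fits a single normal to the full MES vector (mean/sd;
median/MAD behind `robust_fit`) and reports two-sided tail probabilities
with BH FDR. This is honest only when the signal is **sparse**: the
fitted σ includes the signal itself, so if a large fraction of metabolites
carry real effect the z-scores compress. That drove the synthetic-network
default size (below). Scores are reported per compartment-qualified
metabolite; aggregating to base names is a presentation choice left to the
caller.

### 2.4 Paired metabolomics

The interaction contrast is computed as per-subject paired differences
(`Δ = log2(PEM) − log2(baseline)`) followed by the moderated two-sample
test on the Δ's. The alternative — a four-mean contrast of group-level
abundances — was rejected: the design is explicitly pairwise, and the
Δ-formulation removes subject offsets *exactly* (an invariant the tests
assert by rescaling a subject's raw abundances). For the two-timepoint
design, modelling subject as a blocking factor in a linear model is
algebraically equivalent. Missing pairs are dropped per metabolite with a
logged count; no imputation.

## 3. The synthetic world

`make_toy_network()` builds `n_pathways` parallel linear pathways — uptake
exchange, transport, a chain of conversions (one carrying an `AND` complex,
one an `OR` isozyme pair), secretion — all donating a co-product to a
shared hub that is secreted through a core reaction, so every cytosolic
metabolite is produced and consumed internally. One pathway ("AspLike") is
planted: its genes are multiplied by `enzyme_effect` (default 0.25, a
4-fold knockdown) in case samples, and its cytosolic substrate is recorded
as the rescue metabolite.

Defaults and why:

* **10 pathways × 5 reactions.** The planted pathway's metabolites are then
  ~10% of the network. The norm-background MES test needs sparse signal: if
  a fraction `f` of metabolites share the planted score, their z-score is
  `≈ √((1−f)/f)`, so `f ≈ 0.1` gives `z ≈ 3` — detectable after BH — while
  `f ≈ 0.3` would not be. The default mirrors the sparse-signal regime of
  the genome-scale analysis (a handful of pathways out of ~100). Chosen
  from this closed-form argument before the acceptance tests were first
  run, not tuned afterwards.
* **Expression baselines log-normal(log 5, 0.5), noise σ = 0.1, kcat = 1,
  uptake −10.** With `Vmax = expression` in toy units, typical capacities
  (~5) sit *below* the substrate uptake (10), so the expression bound — not
  the medium — is binding, and a 4-fold knockdown moves flux ~4-fold.
  Multiplicative log-normal noise keeps everything positive and has
  closed-form moments for the generator's own oracle tests.
* **Expression design 13/12, metabolomics 25/21 with 116 metabolites.**
  The cohort shapes of the studies the pipeline emulates; the acceptance
  criteria override them to their stated sizes (10/10 and 20/20 with 100).
* **Metabolomics: baselines N(5, 1.5²) log2, subject offsets N(0, 0.5²),
  common timepoint effects N(0, 0.15²), residual N(0, 0.25²), planted
  δ = −0.8 on 5 metabolites.** The subject offset is large on purpose — the
  paired design must remove it; the common timepoint effect cancels in the
  group contrast; residual noise gives the planted δ a per-metabolite
  standard error of ≈ 0.11 at n = 20/20, i.e. a comfortably but not
  trivially detectable t ≈ 7.

What a green recovery test does **not** establish: the toy topology is
loop-free and noise is homoscedastic on the log scale, so solver
degeneracy under flux loops, compartment ambiguity, count-level
(RNA-seq-like) noise, and normalisation artefacts of real expression or
mass-spec data are all untested by construction.

## 4. Degenerate inputs and tie-breaks

* Infeasible bound sets are reported with the exchange bounds in the
  message, never silently repaired; an infeasible *knockout* sets that
  metabolite's row to −1 where the wild type had flux (and logs it), which
  keeps the screen total.
* An empty medium closes all uptake; every flux is then 0 and the
  statistics degrade explicitly (`p = 1` via the constant-row rule).
* `sample.int` order and fixed seeds make the bootstrap deterministic;
  output tables are written with fixed formatting, LF endings and a
  provenance header (version, config hash, seed), so reruns are
  byte-identical — asserted in the tests.
* Config files are JSON (a YAML subset): the supported environment
  guarantees a JSON reader but no YAML parser.

## 5. Known limitations

Beyond the synthetic-world caveats above: the GPR→abundance mapping
ignores per-protein molecular weights and Km saturation; the FVA summary
choice (`max` vs `mid`) is a modelling decision the data cannot settle
here; "FastMM" is treated as a performance idea (shared phase-1 tableau),
not a compatibility target; and reproducing the original studies' numbers
would require their accessions, curated kinetome and the full human
reconstruction, all outside this package's scope.
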