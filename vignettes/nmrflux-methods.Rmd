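---
title: "nmrflux: methods, models and design choices"
author: "nmrflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nmrflux: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrflux)
```

## What the package models

`nmrflux` implements a complete desk-scale analysis chain for
$^1$H-NMR metabolomics of cultured cells, their conditioned media and the
extracellular vesicles (EVs) they secrete — the kind of study that contrasts
glioblastoma lines (LN18, A172, U118) against normal astrocytes (NHA) across
the three sample sources. The chain is:

1. **Spectral preprocessing** — exponential apodization of the time-domain
   signal, Fourier transform, normalization (reference peak or total area),
   region handling.
2. **Alignment** — global FFT cross-correlation against a reference, and
   interval-wise co-shifting of a spectrum set.
3. **Relative quantification** — fitting a library of unit-intensity
   standard spectra to each sample spectrum under a non-negativity
   constraint.
4. **Statistics** — one-way ANOVA feature ranking with an F-threshold panel
   rule, PCA, hierarchical leaf ordering, correlation-difference maps, and
   hypergeometric pathway over-representation.
5. **Context-specific flux simulation** — flux balance analysis (FBA) and
   GIMME on stoichiometric models, driven by boolean protein presence.

Because raw spectra from such studies are rarely redistributable, the
package treats its synthetic-data generator as a first-class module: every
downstream stage is exercised — and its accuracy quantified — on simulated
inputs with known ground truth.

## The synthetic-data generator

**What it emulates.** Reference spectra are sums of Lorentzian lines (the
natural NMR line shape for exponentially decaying signals), normalized to a
total summed intensity of one — the same convention used for library
standards, so fitted coefficients share one relative-concentration scale.
Mixtures are non-negative linear combinations of references plus three
perturbations with direct experimental analogues: additive Gaussian noise
(thermal/receiver noise), a rigid per-metabolite chemical-shift jitter
(pH- and ionic-strength-driven shift variation; applied to the whole
reference, matching how a metabolite's resonances move together), and a
low-order (cubic) polynomial baseline (the smooth distortion that baseline
polynomial correction removes in practice). Cohorts follow a cell-line ×
source design with lognormal replicate-to-replicate variation and
multiplicative planted group effects.

**Defaults and why.** The grid is 32,768 points over −0.5..10 ppm, the
spectral region conventionally retained for aqueous extracts. The built-in
library holds 20 metabolites commonly profiled in glioma studies, at
literature-typical chemical shifts with synthetic amplitudes and linewidths
(0.014–0.03 ppm FWHM, i.e. a few Hz at 600 MHz). Replicates default to 3
per group — a realistic size for EV metabolomics, where material is scarce —
and the biological coefficient of variation defaults to 0.1 (lognormal),
small enough not to drown 3-fold planted effects at n = 3 but large enough
that recovery is not trivial. Shift jitter is rounded to whole grid bins so
that alignment recovery can be asserted exactly.

**What it does not emulate.** J-coupling multiplet structure, solvent
ridges, phase errors and time-domain acquisition artifacts are out of
scope; a minimal synthetic FID exists only to exercise apodization and the
transform. Passing tests therefore demonstrate correctness of the numerics
on idealized line shapes, not robustness to every artifact of measured
spectra.

## Quantification: constrained least squares

Each preprocessed spectrum $s$ is modelled as $s \approx \sum_i c_i m_i$
with $m_i$ the unit-total-intensity standard of metabolite $i$ and
$c_i \ge 0$ its relative concentration. The fit minimizes
$\lVert s - c^\top M \rVert_2^2$ subject to $c \ge 0$:

* **Starting point.** A NIPALS PLS1 regression of the spectrum on the
  library rows (default `min(10, n_metabolites)` latent components)
  supplies the initial coefficients; negative entries are clipped to zero.
  PLS is implemented in-package — it is a ~40-line starting-point
  generator here, not a fitted model anyone interprets.
* **Constrained refinement.** The bound constraint is folded into an
  unconstrained Levenberg–Marquardt iteration through the exact
  reparameterization $c = u^2$, starting from $u = \sqrt{\text{init}}$
  (with a tiny floor, since $u_j = 0$ is a stationary point of the squared
  parameterization). The analytic Jacobian $-2 u_j m_j$ is supplied.
* **Boundary handling.** Coordinates whose optimum lies on the $c_j = 0$
  boundary converge only linearly under the squared parameterization, so
  the LM core runs inside a small active-set outer loop: after each pass,
  coordinates whose cost gradient $\partial C/\partial c_j$ is positive at
  $c_j \approx 0$ are fixed at zero and the remainder refit; a zeroed
  coordinate re-enters if its gradient turns negative. This is a
  convergence accelerator, not a change of optimum: because the forward
  model is linear, the constrained optimum is unique on well-conditioned
  libraries and the tests require agreement with an independent
  active-set non-negative least-squares solver (`pracma::lsqnonneg`) to
  1e-6 relative on every coefficient.
* **Convergence and conditioning.** Relative cost-change tolerance 1e-10,
  500 iterations; libraries with condition number above 1e8 trigger a
  warning, and degenerate (collinear) libraries are excluded from the
  oracle-equivalence contract, where ties among equivalent solutions are
  resolved arbitrarily.

Quantification is intended to run on spectra sharing one normalization
mode; `quantifyCohort()` refuses mixed normalization histories since the
resulting columns would not share a scale. Reference-peak normalization
(DSS at 0 ppm) is the mode that puts samples on a common reference
concentration; any common mode (including none, for simulations) preserves
relative comparisons.

## Preprocessing and alignment choices

* Apodization multiplies the FID by $e^{-\pi \cdot lb \cdot t}$; `lb` is in
  Hz and defaults to 1, the conventional reading of an "exp 1" setting.
* Shifts are whole grid bins, with vacated edge points filled by the
  boundary value (never zeros, which would distort normalized spectra).
  Integer bins keep the exhaustive-search oracle exact; sub-bin
  interpolation is deliberately out of scope.
* Correlation ties are broken toward the smallest absolute lag, then the
  negative one, so alignment is deterministic even on featureless input.
* The default maximum shift is 50 bins, ample for the simulated jitter.
* The residual water region (4.5–5.0 ppm) can be excluded before
  spectra-level statistics via `excludeRegion()`; exclusion is this
  package's default recommendation rather than a universal convention, so
  it is a flag, not hard-wired.
* Phase correction is a recorded no-op hook: simulated spectra are
  generated phased, and the hook marks the extension point for measured
  data.

## Statistics

The ANOVA ranking computes the classic one-way F (between-group over
within-group mean square) per metabolite and keeps features above a
threshold — 5 for the main panels, 3 selectable for subtler contrasts. The
F statistic is invariant under per-metabolite affine transforms, which the
property tests assert. Zero within-group variance with a real between-group
difference yields `Inf`, which deliberately sorts first.

Scaling for heat-map display supports both readings of "mean 0, sd 1
across samples and metabolites": per-metabolite columns (the default, which
gives every metabolite equal visual weight) and one global standardization
of the whole matrix. Hierarchical ordering defaults to Euclidean distance
with average linkage; correlation distance and complete linkage are
options. Correlation-difference maps use Pearson correlation on unscaled
relative concentrations, pooling each contrasted group's samples; the
choice of coefficient and pooling is stated here because display
conventions differ between studies.

Pathway over-representation is the standard upper-tail hypergeometric test
on identifier sets (GMT input), exact by construction; the tests verify it
against exhaustive enumeration for universes up to 12. No multiple-testing
correction is applied by default (panels in this field are typically
reported raw); Benjamini–Hochberg is available behind a flag.

PCA is plain column-centered SVD. t-SNE-style embeddings are out of scope:
they are stochastic, add no testable quantity, and PCA carries the
structure analysis.

## Flux modeling

Models are stoichiometric: metabolites × reactions matrix $S$, flux bounds,
one objective (biomass/maintenance) reaction, and boolean
gene–protein–reaction rules evaluated with AND = min, OR = max (the
standard convention for enzyme complexes vs isozymes). Expression is
boolean protein presence: observed genes 100, unobserved 0. Reactions
without a rule (transport, spontaneous) are never penalized — no protein
evidence can be absent for them.

FBA maximizes the objective flux over $\{S v = 0,\ lb \le v \le ub\}$.
GIMME then minimizes $\sum_{i:\,e_i < \tau} (\tau - e_i)\,|v_i|$ subject to
the same constraints plus $v_{obj} \ge f \cdot z^\*$, with reversible
reactions split into non-negative forward/backward parts so $|v|$ is
linear. Defaults: cutoff $\tau = 50$ (under the 100/0 scheme any value
strictly between 0 and 100 selects the same reactions) and objective
fraction $f = 0.9$; both are configurable and logged, since the maintained
fraction is a modelling choice rather than a measured quantity. The
attained penalty is the inconsistency score; zero means the context's
proteins can carry the required objective alone.

The linear programs are solved by an in-package dense two-phase simplex
with Bland's rule. Steady-state toy networks routinely produce degenerate
polytopes (zero-width bounds, all-zero right-hand sides), and Bland's rule
guarantees termination there; infeasible and unbounded outcomes are
reported through the solution status, never as exceptions. Among degenerate
optima only the objective value and the inconsistency score are
contractual — the flux vector itself may differ between equally optimal
bases — and the test suite checks both against an independent
vertex-enumeration oracle on every toy network (all of which have at most
eight reactions precisely so that brute force stays exact). Bounds at
$\pm\infty$ are clamped to $\pm 1000$ flux units to keep the programs
bounded.

The four toy networks stand in for the subsystems a genome-scale analysis
would highlight: a linear chain (bottleneck arithmetic), a branched network
with two gene-gated alternative routes (context selection), a TCA-cycle
fragment `cit → icit → akg → succ → fum → mal` (whose succinate-processing
branch distinguishes contexts), and a glutathione-like branch
(`gthrd ⇌ gthox` plus a 5-oxoproline drain). Genome-scale reconstructions
(Recon3D-class, ~10,600 reactions) can be read from SBML-FBC or the JSON
dialect — the stoichiometric matrix is stored sparse — but tests and
acceptance run on the toys.

## Pipeline, configuration and provenance

One YAML file drives `simulate → preprocess → quantify → statistics →
flux`; YAML was chosen as the configuration syntax because it is the
established human-editable config format with a robust parser in the R
ecosystem. Unknown keys are rejected and all validation problems are
reported in a single pass. Every artifact gets a JSON provenance sidecar
(package version, canonical config hash, seed, stage parameters,
timestamp); data artifacts themselves are byte-identical across runs under
a fixed seed, which the tests assert. A thin command-line wrapper
(`inst/scripts/nmrflux-cli.R`) exposes the same functions as subcommands;
the R API is the primary interface.

## Problem sizes used in the checks

The oracle-equivalence and recovery checks run on the full default grid
(32,768 points, 20 metabolites, 100 random mixtures; cohorts of 4 groups ×
3 replicates). The ANOVA/PCA recovery study uses a 4,096-point grid with
the same 20-metabolite library over 3 simulation seeds, and the alignment
checks use 4,096 points with shifts up to 30 bins. These sizes make every
oracle exact and keep a full verification run comfortably on a laptop.

## Known limitations

* Lorentzian singlets only; real multiplets overlap differently and can
  degrade deconvolution in crowded regions.
* Relative, not absolute, quantification: coefficients share the library's
  unit-intensity scale and are comparable across samples, not in mM.
* GIMME is the only context-specific method implemented (no iMAT or
  FASTCORE), flux variability analysis is not included, and the reported
  flux vector is one of possibly many degenerate optima.
* The demo cohort sizes are small by design; statistical power at n = 3
  depends on the planted effect size, as in the real experiments the
  design mirrors.
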