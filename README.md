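# nmrflux

Tools for ¹H-NMR metabolomics of cultured cells, conditioned media and
extracellular vesicles (EVs), with context-specific metabolic flux
simulation. The package covers the full desk-scale analysis chain for
studies that profile glioblastoma cell lines (LN18, A172, U118) against
normal astrocytes (NHA) across cell, media and EV samples:

* **simulate** — Lorentzian-line reference spectra, mixtures with known
  ground truth, replicate cohorts with planted group effects, and small
  stoichiometric toy networks with gene–protein–reaction (GPR) rules;
* **preprocess** — exponential apodization, Fourier transform,
  reference-peak / total-area normalization, region trimming and water
  exclusion;
* **align** — global FFT cross-correlation and interval-wise co-shifting
  (integer-bin shifts, deterministic tie-breaks);
* **quantify** — relative metabolite concentrations by fitting a library of
  unit-intensity standard spectra: PLS-initialised, non-negativity
  constrained Levenberg–Marquardt least squares, solving

  $$\hat c = \arg\min_{c \ge 0} \lVert s - c^\top M \rVert_2^2$$

  via the exact reparameterization $c = u^2$;
* **statistics** — one-way ANOVA feature ranking with the F > 5 panel rule,
  PCA, hierarchical ordering, correlation-difference maps, hypergeometric
  pathway over-representation (GMT input);
* **flux** — flux balance analysis ($\max v_{obj}$ s.t. $S v = 0$,
  $lb \le v \le ub$) and GIMME context-specific optimisation from boolean
  protein presence (present = 100, absent = 0): minimise
  $\sum_{i:\,e_i<\tau}(\tau - e_i)\,|v_i|$ while keeping
  $v_{obj} \ge f \cdot z^\*$, plus active-subnetwork extraction with
  dead-end metabolite flagging. Models read/write SBML Level 3 + FBC v2
  and a JSON dialect.

## Worked example

```r
library(nmrflux)

# simulate a 12-sample cohort with 3-fold lactate/choline effects in U118
cfg <- validateConfig(system.file("extdata", "demo_config.yaml",
                                  package = "nmrflux"))
arts <- runPipeline(cfg, outDir = "demo_out")
#> [nmrflux] simulate: 12 spectra on 4096 grid points
#> [nmrflux] preprocess: normalization=none alignment=none
#> [nmrflux] quantify: 12 samples x 12 metabolites
#> [nmrflux] statistics: 3/12 metabolites selected (threshold 5)
#> [nmrflux] flux[LN18]: objective 9, inconsistency 0, 7 active reactions
#> [nmrflux] flux[U118]: objective 9, inconsistency 900, 7 active reactions

head(read.csv(file.path("demo_out", "anova_ranking.csv")), 3)
#>   metabolite fStatistic rank selected
#> 1    lactate 289.125512    1     TRUE
#> 2    choline 130.744410    2     TRUE
#> 3 phosphocholine 7.610098  3     TRUE
```

The planted 3-fold effects put lactate and choline at the top of the ANOVA
ranking (F ≫ 5). The flux stage contrasts two protein-presence contexts on
a TCA-cycle fragment: the LN18-like context carries the full
citrate → … → succinate → fumarate → malate route at zero inconsistency,
while the U118-like context, lacking the succinate-processing enzymes,
must route 9 flux units through two zero-evidence reactions and pays a
GIMME inconsistency score of 2 × 50 × 9 = 900.

Individual stages are plain functions on S4 objects:

```r
lib <- makeSpectralLibrary(defaultMetabolites(20), defaultGrid())
mx  <- makeMixture(defaultMetabolites(20), runif(20, 0, 3),
                   defaultGrid(), noiseSd = 1e-4, seed = 1)
fit <- fitConcentrations(lib, mx$spectrum)
fit$diagnostics
#> FitDiagnostics: residual 0.01811 after 68 iterations (converged)
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/nmrflux-cli.R` (subcommands `run`, `simulate`, `quantify`,
`rank`, `pca`, `ora`, `fba`, `gimme`, `subnet`).

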