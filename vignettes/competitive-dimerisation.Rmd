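---
title: "Methods: coupled dimerisation equilibria, interface contacts and differential HDX"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled dimerisation equilibria, interface contacts and differential HDX}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerfit)
```

This vignette is the package's account of the science it implements:
the models, the assumptions behind them, the tunable parameters and
why their defaults are what they are, what the synthetic-data
generators do and do not emulate, and the numerical and design choices
a maintainer would want written down.

## The competitive dimerisation model

A client protein F homo-dimerises through the same interface a
chaperone H binds, so the two equilibria

$$\mathrm{F_2 \rightleftharpoons 2F}, \qquad
  K_\mathrm{D}^\mathrm{homo} = \frac{[F]^2}{[F_2]};\qquad
  \mathrm{FH \rightleftharpoons F + H}, \qquad
  K_\mathrm{D}^\mathrm{het} = \frac{[F][H]}{[FH]}$$

are coupled through the free monomer. The model assumes: (i) only the
four species F, F$_2$, H, FH exist — no higher oligomers, and no
chaperone self-dimer (HSPB7 constructs are monomeric at the working
concentrations, unlike most small heat-shock proteins); (ii) the
system is at equilibrium (no kinetics); (iii) activities equal
concentrations.

Substituting the equilibrium expressions into the F mass balance gives
a single scalar equation in the free monomer concentration,

$$g([F]) = [F] + \frac{2[F]^2}{K_\mathrm{D}^\mathrm{homo}}
 + \frac{[F]\,H_\mathrm{tot}}{K_\mathrm{D}^\mathrm{het} + [F]}
 - F_\mathrm{tot},$$

which is strictly increasing on $[0, F_\mathrm{tot}]$ with
$g(0) \le 0 \le g(F_\mathrm{tot})$, so the solution exists and is
unique. `solve_species()` brackets it with `stats::uniroot()`
(tolerance $10^{-12} F_\mathrm{tot}$, 200 iterations) and polishes
with up to five Newton steps so the mass-balance residual reaches
machine level; the test suite verifies mass balance to $10^{-9}$
relative on a thousand random systems. At $H_\mathrm{tot} = 0$ the
quadratic root `homodimer_closed_form()` is the analytic oracle the
solver is checked against. All concentrations are carried in molar
internally; `as_molar()` and the `unit` argument of
`titration_data()` handle nM/µM input.

## Signal model and KD fitting

Native MS reports per-species peak intensities; converting them to
fractions requires a response assumption the experiment itself does
not pin down. The default (`signal_model = "species-molar"`) takes
intensity proportional to the molar concentration of each species —
the simplest defensible choice; `"per-subunit"` weights dimers twice,
for sensitivity analysis. Fractions from the two models differ most
where dimer content is high, so a fitted KD should always state which
model produced it.

`fit_kd()` minimises squared residuals over $\log_{10} K_\mathrm{D}$
in a fixed bracket ($10^{-12}$–$10^{-2}$ M) with `stats::optimize()`;
the 1-D residual surface of this model is unimodal, so no multi-start
is needed. Homodimer fits use the dimer-signal fraction among F
species; heterodimer fits use all four species fractions
simultaneously, with the homodimer KD held fixed from its own
independent titration — co-fitting both constants from one dataset
puts them on a ridge. The homodimer KD's uncertainty is propagated by
refitting at $K_\mathrm{D}^\mathrm{homo} \pm \mathrm{SD}$ and adding
half the spread in quadrature with the replicate SD.

Replicates are fitted independently by default and summarised as
mean ± SD, matching how triplicate titrations are usually reported; a
weighted fit to replicate means (`replicates = "mean"`) and a seeded
bootstrap over replicates (`bootstrap_kd()`, ≥100 resamples) are
alternatives. Whether the original analyses fitted replicates jointly
or separately is not documented anywhere we could follow; offering
both, with per-replicate as default, is the neutral reading. Estimates
at the bracket edge or from curvature-free data (all-monomer or
all-dimer) are flagged `"boundary"` with a warning rather than failing
silently. The 1:1 peptide isotherm is fitted with slope and maximum
fixed at 1 (`free_ligand_approx`, i.e. $L/(K_\mathrm{D}+L)$); an
`exact_depletion` mode solves the single-site quadratic because
receptor depletion at tens-of-µM domain concentrations is plausible.

**Titration design used in the recovery benchmarks.** Concentration
series span $0.1\times$–$100\times$ the dimer KD in 8 log-spaced
points — the standard design rule for an informative binding
titration — with $H_\mathrm{tot} = 5\times K_\mathrm{D}^\mathrm{het}$
in heterodimer runs so the competition regime, where the data carry
KD information, is actually sampled. Benchmarks use 3 replicates and
fraction noise SD 0.02, triplicate-native-MS-like conditions; the
recovery study runs 100 seeds × 6 truth KDs (the six measured
constants spanning 2.2 nM–4 µM).

## Free energies

$\Delta G = RT\ln(K_\mathrm{D}/c^\circ)$ at the 1 M standard state,
$R = 8.31446$ J mol$^{-1}$ K$^{-1}$; lower is more stable.
Differences between complexes are
$\Delta\Delta G = RT\ln(K_{\mathrm{D},a}/K_{\mathrm{D},b})$, with
errors propagated to first order and no covariance assumed between
independently fitted KDs. No temperature is attached to the published
constants; 298.15 K reproduces the quoted 5.4/9.9/3.2 kJ mol$^{-1}$
differences to one decimal and is the (configurable) default. One
quoted value resists exact reproduction: the Y2683E heterodimer
stabilisation prints as 1.5 kJ mol$^{-1}$, but the rounded constants
3.9/2.2 nM give 1.4 — almost certainly because unrounded fit values
were used upstream. The package computes, it does not force.

## Native-MS bookkeeping

Positive-ion protonation only: $m/z = (M + z\,m_p)/z$ with
$m_p = 1.00728$ Da; no adducts or charge reduction. Peak assignment
matches each observed peak against all candidate (species, charge)
positions within a ppm tolerance; peaks matching more than one
species are flagged ambiguous and excluded from quantification rather
than split — splitting would require a response model for the
overlap. Species fractions are summed raw intensities over assigned
charges, normalised; no charge normalisation is applied, since
whether the original quantification normalised by charge is unstated.

## Trajectory analysis

Trajectories are multi-model PDB (frames delimited by MODEL/ENDMDL),
read and written through `bio3d`; binary formats are out of scope.
Residues are keyed by (chain, residue number); insertion codes are
rejected. Hydrogen bonds require explicit hydrogens and use geometric
criteria only: donor–hydrogen ≤ 1.2 Å, hydrogen···acceptor ≤ 3.0 Å,
donor–hydrogen–acceptor angle ≥ 150°, donors N/O/S, acceptors N/O
(S behind a flag). All cutoffs are **inclusive** at the boundary —
a deliberate choice so threshold-exact geometries behave
deterministically in tests. Donor chemistry is inferred from geometry
(a hydrogen within the D–H cutoff of an N/O/S heavy atom) rather than
from residue template libraries, so toy systems and non-standard
residues work identically.

Occupancy is the percentage of frames in which a residue pair forms
at least one qualifying bond: a pair forming two simultaneous bonds
in a frame still counts that frame once, reading "account for
multiple bonds" as awareness of multiple geometries rather than
summation. The summing variant (`count = "bonds"`, values can exceed
100%) is available because the original counting rule is ambiguous.
Frames are weighted equally, with no time-decorrelation correction.
Difference maps are `occupancy_b − occupancy_a` over the union of
pairs (absent = 0) and are exactly antisymmetric.

Contact profiles report, per query-chain residue, the minimum and
mean over frames of the per-frame shortest heavy-atom distance to the
partner chain; saturation for surface colouring maps the mean
linearly onto [0, 1] over a configurable 3–15 Å range (clamped).
Superposition RMSD fits each frame to the reference with
`bio3d::fit.xyz()` and computes the deviation from the fitted
coordinates at full precision (the convenience `bio3d::rmsd()` value
is rounded to three decimals, too coarse for identity checks at
$10^{-8}$ Å). A worked subtlety: displacing one atom of a 100-atom
rigid set by 1 Å gives an RMSD of $\sqrt{99}/100 \approx 0.0995$ Å
under optimal superposition, not the naive $\sqrt{1/100} = 0.1$ —
the optimal translation absorbs the centroid shift. The tests pin
this against an independent quaternion (Horn) superposition oracle.

## Differential HDX

The theoretical maximum uptake of a peptide excludes the N-terminal
residue and prolines at positions ≥ 2 (the common DynamX-style
convention — stated explicitly because conventions differ). Uptake
differences are replicate means, `state_a − state_b`, antisymmetric
in the states; called as (complex, free), negative values denote
protection in the complex, which is the Woods-plot convention the
package follows throughout. No back-exchange correction is applied:
all comparisons are state-vs-state on identical peptides.

Significance is per peptide-timepoint, two-tailed, α = 0.01. The
default test is the pooled-variance Student t
(df $= n_a + n_b - 2$): for the balanced triplicate designs HDX uses,
it is exactly calibrated — its measured type-I rate on a simulated
null sits at the nominal 0.01. Welch's unequal-variance test is
provided (`method = "welch"`) but runs conservative at triplicate
depth (measured size ≈ 0.006 at nominal 0.01, because its
Satterthwaite degrees of freedom fall below the pooled value), which
is why it is not the default; a Deuteros-style global pooled
threshold (`method = "pooled"`) and optional Bonferroni correction
are also available. No multiple-testing correction is applied by
default, matching per-peptide α reporting practice. Zero-variance
records with a nonzero difference are significant by convention and
flagged.

Residue projection assigns each residue the aggregate of
fraction-of-maximum values from the significant peptides covering it;
digestion limits resolution, so overlapping peptides can disagree and
the rule (`max_protection` default, `mean`, `min_abs`) resolves them.
Residues with no significant coverage are `NA`, never 0 — absence of
evidence is not absence of protection.

## Synthetic-data generators

Each generator is seeded, bit-reproducible, leaves the caller's RNG
untouched, and returns a machine-readable truth record alongside the
data.

* `gen_titration()` draws Gaussian noise in fraction space (truncated
  at zero, renormalised to the simplex) — the simplest model
  consistent with manually extracted peak intensities; multiplicative
  intensity-space noise is behind a flag.
* `gen_trajectory()` builds glycine-like N–H donors against carbonyl
  acceptors, bonded frames at H···A = 2.0 Å and ∠ = 175°, broken
  frames at 5 Å, pairs spaced 25 Å apart so they cannot interact; the
  frame quota is ⌊occupancy × N⌋, recorded in the truth table when
  rounding occurs. No force field is claimed — the geometry is the
  point, not the physics.
* `gen_hdx()` uses single-exponential exchange,
  $u(t) = u_\mathrm{max}(1 - e^{-k_0 t / P})$, protection factor
  $P = 1$ free and $P > 1$ on designated interface peptides when
  bound. The default $k_0 = 5\times10^{-3}$ s$^{-1}$ makes the
  standard 30–5000 s time course span ~14%–100% of plateau, a
  realistic uptake-curve shape. `gen_peptide_map()` tiles a random
  sequence with overlapping peptides and can respect region
  boundaries, which is how recovery-of-protected-region tests define
  their ground truth sharply.
* `gen_spectrum()` places charge-state peaks (default z = 8–15,
  native-like, Gaussian envelope of SD 1.5 charges) with intensities
  proportional to species fractions, plus optional ppm jitter.

What the generators do **not** emulate: correlated noise between
species sharing a spectrum, charge-state-dependent response,
overlapping isotope envelopes, EX1/bimodal exchange, back-exchange
gradients, or real conformational dynamics. Passing the recovery
tests therefore demonstrates the estimators are correct under their
stated model, not that real instruments satisfy that model.

## Scope and problem sizes

The package is a library: its interface is the fitting and analysis
functions plus `scripts/acceptance.R`, not a shell tool —
`energy_report()` on `flnc_kd_estimates()` is the one-call pipeline
from measured constants to the free-energy ledger. Test and benchmark
sizes are chosen to be decisive yet quick: 1000 random systems for
solver validation, 600 fits for the recovery study, 20-frame toy
trajectories with ≤ 500 atoms for occupancy/contact oracles, 10 000
null trials for test calibration. The published experimental
quantities that require the original raw data — instrument-scale
titration spectra, microsecond trajectories, digest coverage — are
not recomputable at these scales; where they appear (the measured
KD table, the 71%/26% occupancy anchors) they enter as inputs or
format anchors, and every claim the package makes about its own
correctness is computed by its tests or the acceptance script.

## Known limitations

Higher-order oligomers and chaperone self-assembly are outside the
model; fits assume the chosen signal model; H-bond detection needs
explicit hydrogens and will not infer them; periodic-boundary imaging
is assumed done upstream; HDX analysis is peptide-level (no isotope
envelope deconvolution, no EX1 detection); and the per-replicate SD
with three replicates is itself noisy — the 3-SD coverage statements
in the benchmarks are about the ensemble, not any single fit.
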