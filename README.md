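# dimerfit

Quantitative analysis of competitive protein dimerisation equilibria,
with companion tools for the structural readouts that localise the
shared interface. The motivating system is the interaction between the
C-terminal dimerisation domain of filamin C (FLNC d24) and the small
heat-shock protein HSPB7: HSPB7 binds the same β-strand interface FLNC
uses to homo-dimerise, so a single chaperone molecule caps a filamin
monomer and shifts the monomer–dimer balance. Phosphorylation-mimicking
substitutions in the interface (T2677D, Y2683E) retune both equilibria
in opposite directions. The package is for structural biologists and
biophysicists who need to fit and compare such coupled equilibria from
native mass-spectrometry titrations, and to corroborate the interface
with MD contact maps and differential HDX-MS.

## The model

Two coupled equilibria share the free monomer F:

```
F2 <-> 2F        K_D(homo)   = [F]^2 [F2]^-1
FH <-> F + H     K_D(hetero) = [F][H] [FH]^-1
```

with mass balances `F_tot = [F] + 2[F2] + [FH]` and
`H_tot = [H] + [FH]` (the chaperone is monomeric on its own).
Substituting the equilibrium expressions reduces the system to one
strictly increasing scalar equation in `[F]`, solved by bracketed
root-finding. Dissociation constants are estimated by least squares on
species signal fractions in log10 K_D, each technical replicate fitted
independently and reported as mean ± SD. Binding free energies follow
as `ΔG = RT ln(K_D / 1 M)` and differences between complexes as
`ΔΔG = RT ln(K_D,a / K_D,b)` with first-order error propagation.

Around this core the package provides: charge-state bookkeeping for
turning native-MS peak lists into species fractions; hydrogen-bond
occupancy maps and signed difference maps from multi-model PDB
trajectories (criteria: D–H ≤ 1.2 Å, H···A ≤ 3.0 Å, ∠DHA ≥ 150°,
inclusive); per-residue shortest heavy-atom contact profiles and
superposition RMSD; differential HDX-MS statistics (per-peptide
two-tailed t-test at α = 0.01, Woods-plot export, residue projection);
and seeded synthetic-data generators that emit ground-truth sidecars
for every pipeline stage.

## Worked example

Simulate a homodimer titration at the wild-type K_D with triplicate
noise, refit it, and build the free-energy ledger from the measured
constants:

```r
library(dimerfit)

d <- gen_titration(kd_homo = 75.9e-9,
                   f_total_series = 75.9e-9 * 10^seq(-1, 2, length.out = 8),
                   noise_sd = 0.02, seed = 101)
fit <- fit_kd(d, mode = "homodimer")
fit
#> KD fit (homodimer, least-squares/independent)
#>   KD = 7.847e-08 M (78.47 nM)  +/- 1.87e-09 M
#>   replicates: 3, residual RMS: 0.0104

energy_report()
#> Free-energy ledger (T = 298.15 K)
#>   WT       homodimer   KD 7.59e-08 M  dG   -40.6 +/- 0.3 kJ/mol
#>   T2677D   homodimer   KD  8.5e-09 M  dG   -46.1 +/- 0.3 kJ/mol
#>   Y2683E   homodimer   KD 4.047e-06 M  dG   -30.8 +/- 0.3 kJ/mol
#>   WT       heterodimer KD  3.9e-09 M  dG   -48.0 +/- 0.6 kJ/mol
#>   T2677D   heterodimer KD 1.41e-08 M  dG   -44.8 +/- 0.1 kJ/mol
#>   Y2683E   heterodimer KD  2.2e-09 M  dG   -49.4 +/- 0.7 kJ/mol
#> Within-species differences (ddG = RT ln(kd_a / kd_b)):
#>   homodimer   WT vs T2677D:   5.4 +/- 0.4 kJ/mol
#>   homodimer   WT vs Y2683E:  -9.9 +/- 0.4 kJ/mol
#>   ...
#> Homodimer - heterodimer gap per variant:
#>   WT         7.4 +/- 0.6 kJ/mol
#>   T2677D    -1.3 +/- 0.3 kJ/mol
#>   Y2683E    18.6 +/- 0.8 kJ/mol
```

The refit recovers the generating constant (78.5 ± 1.9 nM against a
truth of 75.9 nM). The ledger reads: T2677D tightens homodimerisation
by 5.4 kJ/mol and loosens the heterodimer by 3.2 kJ/mol, Y2683E does
the reverse (9.9 kJ/mol weaker homodimer), and for the wild type the
heterodimer is the more stable complex by 7.4 kJ/mol — so the
chaperone wins the competition unless T2677 is phosphorylated, which
flips the gap's sign (−1.3 kJ/mol, homodimer favoured).

`plot(fit)` draws the fitted binding curve over the replicate points;
`summary`, `coef`, `predict`, `residuals`, `simulate` behave as for
any fitted model object.

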