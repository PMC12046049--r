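#' Unit conversion to molar
#'
#' Concentrations are carried internally in molar throughout the package;
#' this helper converts tagged inputs.
#'
#' @param x numeric vector of concentrations.
#' @param unit one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#' @return numeric vector in molar.
#' @export
#' @examples
#' as_molar(75.9, "nM")
as_molar <- function(x, unit = c("M", "mM", "uM", "nM", "pM")) {
  unit <- match.arg(unit)
  x * switch(unit, M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
}

#' Define a competitive dimerisation system
#'
#' Describes the coupled equilibria of a client protein F that can
#' homo-dimerise (F2 <-> 2F, dissociation constant `kd_homo`) while a
#' chaperone H competes for the same interface by forming a 1:1
#' heterodimer (FH <-> F + H, dissociation constant `kd_hetero`).
#' H is treated as monomeric on its own: chaperone self-dimerisation is
#' outside the model.
#'
#' @param kd_homo homodimer dissociation constant (molar). `Inf` disables
#'   homodimerisation.
#' @param kd_hetero heterodimer dissociation constant (molar). `Inf`
#'   disables the heterodimer (default when `h_total = 0`).
#' @param f_total total F-subunit concentration (molar).
#' @param h_total total H-subunit concentration (molar).
#' @return an object of class `"eq_system"`.
#' @export
#' @examples
#' eq_system(kd_homo = 75.9e-9, f_total = 1e-6)
eq_system <- function(kd_homo, kd_hetero = Inf, f_total, h_total = 0) {
  vals <- c(kd_homo = kd_homo, kd_hetero = kd_hetero,
            f_total = f_total, h_total = h_total)
  if (any(is.na(vals)) || any(vals < 0))
    stop("eq_system: all parameters must be finite and non-negative ",
         "(Inf allowed only for kd values)", call. = FALSE)
  if (!is.finite(f_total) || !is.finite(h_total))
    stop("eq_system: total concentrations must be finite", call. = FALSE)
  if (kd_homo <= 0 || kd_hetero <= 0)
    stop("eq_system: dissociation constants must be > 0", call. = FALSE)
  structure(list(kd_homo = kd_homo, kd_hetero = kd_hetero,
                 f_total = f_total, h_total = h_total),
            class = "eq_system")
}

#' @export
print.eq_system <- function(x, ...) {
  cat("Competitive dimerisation system\n")
  cat(sprintf("  kd_homo   = %.4g M\n", x$kd_homo))
  cat(sprintf("  kd_hetero = %.4g M\n", x$kd_hetero))
  cat(sprintf("  f_total   = %.4g M, h_total = %.4g M\n",
              x$f_total, x$h_total))
  invisible(x)
}

# Mass-balance function in the free monomer concentration [F]:
#   g(F) = F + 2 F^2 / kd_homo + F h_total / (kd_hetero + F) - f_total
# strictly increasing on [0, f_total], so the root is unique.
.mass_balance <- function(f, sys) {
  f + 2 * f^2 / sys$kd_homo +
    f * sys$h_total / (sys$kd_hetero + f) - sys$f_total
}

.mass_balance_grad <- function(f, sys) {
  het <- if (sys$h_total == 0 || !is.finite(sys$kd_hetero)) 0
  else sys$h_total * sys$kd_hetero / (sys$kd_hetero + f)^2
  1 + 4 * f / sys$kd_homo + het
}

#' Solve species concentrations of the coupled equilibria
#'
#' Finds the unique non-negative concentrations of free F monomer, F
#' homodimer, free H and FH heterodimer satisfying both equilibrium
#' expressions and both mass balances. The problem reduces to a single
#' monotone mass-balance equation in the free monomer concentration,
#' solved by bracketed root-finding ([stats::uniroot()]) and polished
#' with Newton steps to machine-level mass-balance residuals.
#'
#' @param system an [eq_system()].
#' @return a list of class `"species_state"` with components `f_mono`,
#'   `f_dimer`, `h_mono`, `fh_hetero` (molar).
#' @export
#' @examples
#' solve_species(eq_system(kd_homo = 75.9e-9, f_total = 1e-6))
solve_species <- function(system) {
  stopifnot(inherits(system, "eq_system"))
  sys <- system
  if (sys$f_total == 0) {
    f <- 0
  } else {
    r <- stats::uniroot(.mass_balance, c(0, sys$f_total), sys = sys,
                        tol = 1e-12 * sys$f_total, maxiter = 200L)
    f <- r$root
    # Newton polish: uniroot's tolerance is on F, tighten the residual
    for (i in 1:5) {
      g <- .mass_balance(f, sys)
      if (abs(g) <= 1e-14 * sys$f_total) break
      f <- max(0, min(sys$f_total, f - g / .mass_balance_grad(f, sys)))
    }
    if (abs(.mass_balance(f, sys)) > 1e-9 * sys$f_total)
      stop("solve_species: failed to converge", call. = FALSE)
  }
  f_dimer <- if (is.finite(sys$kd_homo)) f^2 / sys$kd_homo else 0
  fh <- if (is.finite(sys$kd_hetero))
    f * sys$h_total / (sys$kd_hetero + f) else 0
  structure(list(f_mono = f, f_dimer = f_dimer,
                 h_mono = sys$h_total - fh, fh_hetero = fh),
            class = "species_state")
}

#' @export
print.species_state <- function(x, ...) {
  cat("Species concentrations (M):\n")
  print(unlist(x[c("f_mono", "f_dimer", "h_mono", "fh_hetero")]))
  invisible(x)
}

#' Closed-form homodimer-only solution
#'
#' Analytic solution of the monomer-dimer equilibrium when no chaperone
#' is present: the free monomer is the positive root of the quadratic
#' mass balance, `f_mono = kd (-1 + sqrt(1 + 8 f_total / kd)) / 4`.
#' Serves as an analytic oracle for [solve_species()] at `h_total = 0`.
#'
#' @param kd_homo homodimer dissociation constant (molar, > 0).
#' @param f_total total subunit concentration (molar, >= 0).
#' @return a `"species_state"` with `h_mono = fh_hetero = 0`.
#' @export
homodimer_closed_form <- function(kd_homo, f_total) {
  if (!is.finite(kd_homo) || kd_homo <= 0 || !is.finite(f_total) ||
      f_total < 0)
    stop("homodimer_closed_form: kd_homo > 0 and f_total >= 0 required",
         call. = FALSE)
  f <- if (f_total == 0) 0 else
    kd_homo * (-1 + sqrt(1 + 8 * f_total / kd_homo)) / 4
  structure(list(f_mono = f, f_dimer = f^2 / kd_homo,
                 h_mono = 0, fh_hetero = 0),
            class = "species_state")
}

# Signal fractions of the four species under a signal model.
# species-molar: intensity proportional to molar concentration of each
# species; per-subunit: dimeric species weighted x2.
.signal_fractions <- function(state, signal_model) {
  w <- switch(signal_model,
              "species-molar" = c(1, 1, 1, 1),
              "per-subunit"   = c(1, 2, 1, 2),
              stop("unknown signal model: ", signal_model, call. = FALSE))
  s <- c(monomer    = state$f_mono    * w[1],
         homodimer  = state$f_dimer   * w[2],
         h_monomer  = state$h_mono    * w[3],
         heterodimer = state$fh_hetero * w[4])
  s / sum(s)
}

#' Simulate a noise-free titration
#'
#' Evaluates the forward model along an ascending series of total F
#' concentrations at fixed chaperone concentration, returning per-species
#' signal fractions under the chosen intensity response model.
#'
#' @param kd_homo,kd_hetero dissociation constants (molar).
#' @param f_total_series strictly positive, ascending total F series
#'   (molar).
#' @param h_total total H concentration (molar), held fixed along the
#'   series.
#' @param signal_model `"species-molar"` (default; intensity proportional
#'   to species molar concentration) or `"per-subunit"` (dimers weighted
#'   twice).
#' @return data frame with columns `f_total_M`, `frac_monomer`,
#'   `frac_homodimer`, `frac_heterodimer`, `frac_h_monomer`; fractions in
#'   each row sum to 1.
#' @export
simulate_titration <- function(kd_homo, kd_hetero = Inf, f_total_series,
                               h_total = 0,
                               signal_model = c("species-molar",
                                                "per-subunit")) {
  signal_model <- match.arg(signal_model)
  if (length(f_total_series) == 0)
    stop("simulate_titration: empty concentration series", call. = FALSE)
  if (any(f_total_series <= 0) || is.unsorted(f_total_series))
    stop("simulate_titration: series must be strictly positive and ",
         "sorted ascending", call. = FALSE)
  rows <- lapply(f_total_series, function(ft) {
    st <- solve_species(eq_system(kd_homo, kd_hetero, ft, h_total))
    fr <- .signal_fractions(st, signal_model)
    data.frame(f_total_M = ft,
               frac_monomer = fr[["monomer"]],
               frac_homodimer = fr[["homodimer"]],
               frac_heterodimer = fr[["heterodimer"]],
               frac_h_monomer = fr[["h_monomer"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "signal_model") <- signal_model
  out
}

#' Single-site binding isotherm
#'
#' Fraction of receptor bound at a given ligand concentration for 1:1
#' binding. `free_ligand_approx` is the rectangular hyperbola
#' `L / (kd + L)` (a Hill model with slope and maximum fixed at 1);
#' `exact_depletion` solves the single-site quadratic so that ligand
#' consumed by the complex is accounted for.
#'
#' @param kd dissociation constant (molar, > 0).
#' @param ligand_total total ligand concentration (molar, >= 0).
#' @param receptor_total total receptor concentration (molar); only used
#'   in `exact_depletion` mode.
#' @param mode `"free_ligand_approx"` (default) or `"exact_depletion"`.
#' @return fraction bound in \[0, 1\] (vectorised over `ligand_total`).
#' @export
#' @examples
#' peptide_isotherm(100e-6, 300e-6)  # 0.75
peptide_isotherm <- function(kd, ligand_total, receptor_total = 0,
                             mode = c("free_ligand_approx",
                                      "exact_depletion")) {
  mode <- match.arg(mode)
  if (!is.finite(kd) || kd <= 0 || any(ligand_total < 0) ||
      any(receptor_total < 0))
    stop("peptide_isotherm: kd > 0 and concentrations >= 0 required",
         call. = FALSE)
  if (mode == "free_ligand_approx")
    return(ligand_total / (kd + ligand_total))
  # [RL] is the smaller root of RL^2 - (R+L+kd) RL + R L = 0
  b <- receptor_total + ligand_total + kd
  rl <- (b - sqrt(b^2 - 4 * receptor_total * ligand_total)) / 2
  if (receptor_total == 0) return(rep(0, length(ligand_total)))
  pmin(pmax(rl / receptor_total, 0), 1)
}
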