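# Gas constant, J mol^-1 K^-1
R_GAS <- 8.31446

#' Convert a dissociation constant to a binding free energy
#'
#' Standard binding free energy of the complex relative to free
#' monomers at the 1 M standard state: `dG = R T ln(KD / 1 M)`; tighter
#' binding (smaller KD) gives a more negative, more stable dG. The
#' uncertainty is first-order propagated, `dG_err = R T sd / KD`.
#'
#' @param kd dissociation constant (molar, > 0).
#' @param sd standard deviation of `kd` (molar).
#' @param temperature kelvin (default 298.15).
#' @return named numeric `c(dg, dg_err)` in kJ mol^-1.
#' @export
#' @examples
#' kd_to_dg(75.9e-9)
kd_to_dg <- function(kd, sd = 0, temperature = 298.15) {
  if (!is.finite(kd) || kd <= 0)
    stop("kd_to_dg: kd must be > 0", call. = FALSE)
  if (sd < 0 || temperature <= 0)
    stop("kd_to_dg: sd >= 0 and temperature > 0 required", call. = FALSE)
  rt <- R_GAS * temperature / 1000
  c(dg = rt * log(kd), dg_err = rt * sd / kd)
}

#' Free-energy difference between two complexes
#'
#' `ddG = R T ln(kd_a / kd_b)`: positive when complex `a` binds more
#' weakly than complex `b` (i.e. `b` is the more stable complex).
#' Errors combine in quadrature on the relative scale; the result is
#' antisymmetric under swapping the arguments.
#'
#' @param kd_a,kd_b dissociation constants (molar, > 0).
#' @param sd_a,sd_b their standard deviations (molar).
#' @param temperature kelvin.
#' @return named numeric `c(ddg, ddg_err)` in kJ mol^-1.
#' @export
#' @examples
#' ddg_between(75.9e-9, 8.5e-9)  # ~5.4 kJ/mol homodimer stabilisation
ddg_between <- function(kd_a, kd_b, sd_a = 0, sd_b = 0,
                        temperature = 298.15) {
  if (!is.finite(kd_a) || kd_a <= 0 || !is.finite(kd_b) || kd_b <= 0)
    stop("ddg_between: both kds must be > 0", call. = FALSE)
  rt <- R_GAS * temperature / 1000
  c(ddg = rt * log(kd_a / kd_b),
    ddg_err = rt * sqrt((sd_a / kd_a)^2 + (sd_b / kd_b)^2))
}

#' Build a free-energy ledger from KD estimates
#'
#' Converts a table of (variant, species) KD estimates into binding free
#' energies, all pairwise within-species free-energy differences, and
#' the homodimer-vs-heterodimer gap for each variant present in both
#' species. This is the quantitative content of a dimer-stability
#' diagram: which complexes a phosphomimic stabilises, and by how much.
#'
#' @param estimates data frame with columns `variant`, `species`
#'   (`"homodimer"` or `"heterodimer"`), `kd` (molar), `sd` (molar;
#'   optional, defaults 0).
#' @param temperature kelvin.
#' @return an object of class `"energy_ledger"`: a list with
#'   `entries` (per-complex dG), `pairwise` (within-species ddG for all
#'   variant pairs) and `gaps` (homo minus hetero dG per variant), each
#'   a data frame with propagated errors in kJ mol^-1.
#' @export
build_ledger <- function(estimates, temperature = 298.15) {
  need <- c("variant", "species", "kd")
  if (!all(need %in% names(estimates)) || nrow(estimates) < 1)
    stop("build_ledger: need >= 1 row with variant, species, kd",
         call. = FALSE)
  if (is.null(estimates$sd)) estimates$sd <- 0
  key <- paste(estimates$variant, estimates$species)
  if (anyDuplicated(key))
    stop("build_ledger: duplicate (variant, species) keys", call. = FALSE)

  dg <- t(mapply(kd_to_dg, estimates$kd, estimates$sd,
                 MoreArgs = list(temperature = temperature)))
  entries <- data.frame(variant = estimates$variant,
                        species = estimates$species,
                        kd = estimates$kd, sd = estimates$sd,
                        dg = dg[, "dg"], dg_err = dg[, "dg_err"])

  pairwise <- NULL
  for (sp in unique(entries$species)) {
    e <- entries[entries$species == sp, ]
    if (nrow(e) < 2) next
    idx <- utils::combn(nrow(e), 2)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      dd <- ddg_between(e$kd[i], e$kd[j], e$sd[i], e$sd[j], temperature)
      pairwise <- rbind(pairwise, data.frame(
        species = sp, variant_a = e$variant[i], variant_b = e$variant[j],
        ddg = dd[["ddg"]], ddg_err = dd[["ddg_err"]]))
    }
  }

  gaps <- NULL
  for (v in unique(entries$variant)) {
    eh <- entries[entries$variant == v & entries$species == "homodimer", ]
    et <- entries[entries$variant == v &
                    entries$species == "heterodimer", ]
    if (nrow(eh) == 1 && nrow(et) == 1) {
      dd <- ddg_between(eh$kd, et$kd, eh$sd, et$sd, temperature)
      gaps <- rbind(gaps, data.frame(
        variant = v, gap = dd[["ddg"]], gap_err = dd[["ddg_err"]]))
    }
  }

  structure(list(entries = entries, pairwise = pairwise, gaps = gaps,
                 temperature = temperature),
            class = "energy_ledger")
}

#' @export
print.energy_ledger <- function(x, ...) {
  cat(sprintf("Free-energy ledger (T = %.2f K)\n", x$temperature))
  e <- x$entries
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-8s %-11s KD %8.4g M  dG %7.1f +/- %.1f kJ/mol\n",
                e$variant[i], e$species[i], e$kd[i], e$dg[i],
                e$dg_err[i]))
  if (!is.null(x$pairwise)) {
    cat("Within-species differences (ddG = RT ln(kd_a / kd_b)):\n")
    p <- x$pairwise
    for (i in seq_len(nrow(p)))
      cat(sprintf("  %-11s %s vs %s: %5.1f +/- %.1f kJ/mol\n",
                  p$species[i], p$variant_a[i], p$variant_b[i],
                  p$ddg[i], p$ddg_err[i]))
  }
  if (!is.null(x$gaps)) {
    cat("Homodimer - heterodimer gap per variant:\n")
    g <- x$gaps
    for (i in seq_len(nrow(g)))
      cat(sprintf("  %-8s %5.1f +/- %.1f kJ/mol\n",
                  g$variant[i], g$gap[i], g$gap_err[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.energy_ledger <- function(x, ...) x$entries

#' Write a free-energy ledger to CSV
#'
#' Serialises the three ledger tables to `<stem>_entries.csv`,
#' `<stem>_pairwise.csv` and `<stem>_gaps.csv`.
#'
#' @param ledger an `"energy_ledger"`.
#' @param stem output path stem.
#' @return invisibly, the paths written.
#' @export
write_ledger_csv <- function(ledger, stem) {
  paths <- character(0)
  for (part in c("entries", "pairwise", "gaps")) {
    tab <- ledger[[part]]
    if (is.null(tab)) next
    p <- paste0(stem, "_", part, ".csv")
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
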