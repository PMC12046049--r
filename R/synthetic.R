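# Run fn with a locally seeded RNG, leaving the caller's RNG untouched.
.with_seed <- function(seed, fn) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fn()
}

#' Generate a replicate titration dataset with known ground truth
#'
#' Evaluates the coupled-equilibrium forward model along a
#' concentration series and adds replicate noise: Gaussian in fraction
#' space, truncated at zero and renormalised so each replicate's
#' fractions still sum to 1 (`noise_space = "intensity"` instead
#' perturbs species intensities multiplicatively before normalising).
#' The true parameters are attached as the `truth` attribute.
#'
#' @param kd_homo,kd_hetero true dissociation constants (molar).
#' @param f_total_series ascending total F series (molar).
#' @param h_total total H (molar).
#' @param n_replicates replicates per point.
#' @param noise_sd noise SD on fractions (dimensionless).
#' @param seed integer seed; identical seeds give identical datasets.
#' @param signal_model see [simulate_titration()].
#' @param noise_space `"fraction"` (default) or `"intensity"`.
#' @return a [titration_data()] with a `truth` attribute.
#' @export
gen_titration <- function(kd_homo, kd_hetero = Inf, f_total_series,
                          h_total = 0, n_replicates = 3,
                          noise_sd = 0.02, seed = 1L,
                          signal_model = c("species-molar",
                                           "per-subunit"),
                          noise_space = c("fraction", "intensity")) {
  signal_model <- match.arg(signal_model)
  noise_space <- match.arg(noise_space)
  if (noise_sd < 0)
    stop("gen_titration: noise_sd must be >= 0", call. = FALSE)
  clean <- simulate_titration(kd_homo, kd_hetero, f_total_series,
                              h_total, signal_model)
  species <- c("monomer", "homodimer", "heterodimer", "h_monomer")
  cols <- paste0("frac_", species)
  long <- .with_seed(seed, function() {
    rows <- list()
    for (i in seq_len(nrow(clean))) {
      fr0 <- as.numeric(clean[i, cols])
      for (r in seq_len(n_replicates)) {
        fr <- if (noise_sd == 0) fr0
        else if (noise_space == "fraction")
          pmax(fr0 + stats::rnorm(4, 0, noise_sd), 0)
        else fr0 * pmax(1 + stats::rnorm(4, 0, noise_sd), 0)
        fr <- fr / sum(fr)
        rows[[length(rows) + 1]] <- data.frame(
          f_total = clean$f_total_M[i], h_total = h_total,
          replicate = r, species = species, fraction = fr)
      }
    }
    do.call(rbind, rows)
  })
  out <- titration_data(long, signal_model = signal_model,
                        label = sprintf("synthetic seed %d", seed))
  attr(out, "truth") <- list(kd_homo = kd_homo, kd_hetero = kd_hetero,
                             h_total = h_total, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Generate a toy two-chain trajectory with scheduled H-bond occupancies
#'
#' Builds a minimal two-chain system (glycine-like residues carrying an
#' N-H donor on chain A and a carbonyl-O acceptor on chain B, plus CA
#' scaffold atoms) in which each requested residue pair satisfies the
#' hydrogen-bond geometry (H...A 2.0 Angstrom, D-H-A angle 175 degrees)
#' in exactly `floor(occupancy/100 * n_frames)` frames and is broken
#' (H...A 5 Angstrom) in the rest. Pairs are spaced far apart so they
#' cannot interfere. No physical force field is claimed.
#'
#' @param pairs data frame with columns `resno_i` (chain A residue),
#'   `resno_j` (chain B residue), `occupancy_pct` in \[0, 100\].
#' @param n_frames frame count (>= 1).
#' @param spacing centre-to-centre separation between pairs (Angstrom).
#' @return list with `trajectory` (an `"md_trajectory"`) and `truth`
#'   (the pair table with the achieved occupancy, after rounding the
#'   frame quota down).
#' @export
gen_trajectory <- function(pairs, n_frames = 20, spacing = 25) {
  if (n_frames < 1) stop("gen_trajectory: n_frames >= 1", call. = FALSE)
  if (any(pairs$occupancy_pct < 0 | pairs$occupancy_pct > 100))
    stop("gen_trajectory: occupancies must be in [0, 100]",
         call. = FALSE)
  phi <- 5 * pi / 180  # D-H-A angle 175 deg
  u <- c(cos(phi), sin(phi), 0)
  atoms <- list(); base <- list()
  for (k in seq_len(nrow(pairs))) {
    x <- (k - 1) * spacing
    atoms[[k]] <- data.frame(
      elety = c("N", "H1", "CA", "O", "CA"),
      resid = "GLY",
      chain = c("A", "A", "A", "B", "B"),
      resno = c(rep(pairs$resno_i[k], 3), rep(pairs$resno_j[k], 2)),
      elesy = c("N", "H", "C", "O", "C"))
    o_bonded <- c(x + 1, 0, 0) + 2.0 * u
    base[[k]] <- rbind(N = c(x, 0, 0),
                       H = c(x + 1, 0, 0),
                       CA_A = c(x, 2.5, 0),
                       O = o_bonded,
                       CA_B = o_bonded + c(0, 2.5, 0))
  }
  atoms <- do.call(rbind, atoms)
  n_bonded <- floor(pairs$occupancy_pct / 100 * n_frames)
  xyz <- matrix(NA_real_, n_frames, 3 * nrow(atoms))
  for (f in seq_len(n_frames)) {
    co <- NULL
    for (k in seq_len(nrow(pairs))) {
      b <- base[[k]]
      if (f > n_bonded[k])  # broken frame: pull the acceptor away
        b["O", ] <- b["H", ] + 5.0 * u
      co <- rbind(co, b)
    }
    xyz[f, ] <- as.numeric(t(co))
  }
  truth <- pairs
  truth$achieved_pct <- 100 * n_bonded / n_frames
  list(trajectory = md_trajectory(atoms, xyz), truth = truth)
}

#' Apply a rigid-body transform to every frame
#'
#' @param traj an `"md_trajectory"`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector (Angstrom).
#' @return the transformed trajectory.
#' @export
transform_trajectory <- function(traj, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  xyz <- traj$xyz
  for (f in seq_len(nrow(xyz))) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    co <- co %*% t(rotation)
    co <- sweep(co, 2, translation, `+`)
    xyz[f, ] <- as.numeric(t(co))
  }
  md_trajectory(traj$atoms, xyz)
}

#' Random rotation matrix
#'
#' Uniform random 3D rotation built from a normalised quaternion.
#'
#' @param seed integer seed.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function(seed = 1L) {
  .with_seed(seed, function() {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

#' Generate a random tiled peptide map
#'
#' Draws a random protein sequence and tiles it with overlapping
#' peptides, the way a pepsin digest covers a protein in an HDX
#' experiment.
#'
#' @param n_residues protein length.
#' @param pep_len peptide length.
#' @param step start-to-start offset between consecutive peptides.
#' @param seed integer seed.
#' @param boundaries optional residue positions that peptides must not
#'   cross (tiling restarts there), e.g. the edges of a region whose
#'   recovery is being tested.
#' @return data frame with columns `sequence`, `start`, `end`.
#' @export
gen_peptide_map <- function(n_residues = 160, pep_len = 11, step = 6,
                            seed = 1L, boundaries = NULL) {
  aa <- strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]]  # no proline: keeps
  # max_uptake = len - 1 and the synthetic kinetics simple
  seqn <- .with_seed(seed, function()
    paste(sample(aa, n_residues, replace = TRUE), collapse = ""))
  segs <- sort(unique(c(1, boundaries, n_residues + 1)))
  peps <- NULL
  for (s in seq_len(length(segs) - 1)) {
    lo <- segs[s]; hi <- segs[s + 1] - 1
    starts <- seq(lo, max(lo, hi - pep_len + 1), by = step)
    for (st in starts) {
      en <- min(st + pep_len - 1, hi)
      if (en - st + 1 < 4) next
      peps <- rbind(peps, data.frame(
        sequence = substr(seqn, st, en), start = st, end = en))
    }
  }
  unique(peps)
}

#' Generate an HDX uptake table with known protection
#'
#' Exchange kinetics `uptake(t) = max_uptake * (1 - exp(-k0 t / P))`
#' with protection factor `P = 1` in the free state and the supplied
#' per-peptide factor in the bound state, plus Gaussian replicate noise
#' clamped to the physical range.
#'
#' @param peptides data frame with `sequence`, `start`, `end` (see
#'   [gen_peptide_map()]).
#' @param protection numeric vector of protection factors (>= 1), one
#'   per peptide, applied in the bound state.
#' @param timepoints labelling times (seconds).
#' @param n_replicates replicates per state and timepoint.
#' @param k0 intrinsic exchange rate constant (s^-1, > 0).
#' @param noise_sd replicate noise SD (Da).
#' @param seed integer seed.
#' @return list with `table` (long-format uptake table with states
#'   `"free"` and `"bound"`) and `truth` (peptide table with protection
#'   factors).
#' @export
gen_hdx <- function(peptides, protection = rep(1, nrow(peptides)),
                    timepoints = c(30, 60, 500, 1000, 5000),
                    n_replicates = 3, k0 = 5e-3, noise_sd = 0.05,
                    seed = 1L) {
  if (k0 <= 0) stop("gen_hdx: k0 must be > 0", call. = FALSE)
  if (any(protection < 1))
    stop("gen_hdx: protection factors must be >= 1", call. = FALSE)
  mu <- max_uptake(peptides$sequence)
  tab <- .with_seed(seed, function() {
    rows <- list()
    for (i in seq_len(nrow(peptides))) {
      for (state in c("free", "bound")) {
        p <- if (state == "free") 1 else protection[i]
        for (tp in timepoints) {
          m <- mu[i] * (1 - exp(-k0 * tp / p))
          for (r in seq_len(n_replicates)) {
            u <- m + if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
            rows[[length(rows) + 1]] <- data.frame(
              sequence = peptides$sequence[i],
              start = peptides$start[i], end = peptides$end[i],
              state = state, timepoint_s = tp, replicate = r,
              uptake_Da = min(max(u, 0), mu[i]))
          }
        }
      }
    }
    do.call(rbind, rows)
  })
  truth <- peptides
  truth$protection <- protection
  list(table = tab, truth = truth)
}

#' Generate a synthetic native-MS peak list
#'
#' Places charge-state peaks at protonated m/z positions for each
#' species, with intensities proportional to the species fraction times
#' a Gaussian charge-state envelope, optionally perturbing positions by
#' Gaussian ppm jitter.
#'
#' @param species data frame with `species`, `mass` (Da > 0),
#'   `fraction` (summing to 1).
#' @param z_range charge states emitted per species.
#' @param envelope_sd SD of the charge envelope (charges).
#' @param jitter_ppm SD of the m/z jitter (ppm).
#' @param intensity_scale grand-total intensity.
#' @param seed integer seed.
#' @return list with `peaks` (data frame `mz`, `intensity`) and `truth`
#'   (named fraction vector).
#' @export
gen_spectrum <- function(species, z_range = 8:15, envelope_sd = 1.5,
                         jitter_ppm = 0, intensity_scale = 1e4,
                         seed = 1L) {
  if (any(species$mass <= 0))
    stop("gen_spectrum: masses must be > 0", call. = FALSE)
  if (abs(sum(species$fraction) - 1) > 1e-9)
    stop("gen_spectrum: fractions must sum to 1", call. = FALSE)
  .with_seed(seed, function() {
    peaks <- NULL
    for (i in seq_len(nrow(species))) {
      env <- stats::dnorm(z_range, mean(z_range), envelope_sd)
      env <- env / sum(env)
      mz <- compute_mz(species$mass[i], z_range)
      if (jitter_ppm > 0)
        mz <- mz * (1 + stats::rnorm(length(mz), 0, jitter_ppm * 1e-6))
      peaks <- rbind(peaks, data.frame(
        mz = mz,
        intensity = intensity_scale * species$fraction[i] * env))
    }
    truth <- species$fraction
    names(truth) <- species$species
    list(peaks = peaks[order(peaks$mz), ], truth = truth)
  })
}
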