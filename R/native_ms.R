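# Proton mass, Da
M_PROTON <- 1.00728

#' m/z of a protonated species
#'
#' Positive-ion electrospray: `(mass + z * 1.00728) / z`.
#'
#' @param mass neutral mass (Da, > 0).
#' @param z charge state (positive integer); vectorised.
#' @return m/z values (Th).
#' @export
#' @examples
#' compute_mz(10000, 10)  # 1001.007
compute_mz <- function(mass, z) {
  if (any(mass <= 0)) stop("compute_mz: mass must be > 0", call. = FALSE)
  if (any(z < 1) || any(z != round(z)))
    stop("compute_mz: z must be a positive integer", call. = FALSE)
  (mass + z * M_PROTON) / z
}

#' Assign charge-state series to peaks
#'
#' Matches each peak to candidate (species, charge) positions within a
#' ppm tolerance. A peak matching exactly one candidate is assigned; a
#' peak matching two or more is flagged ambiguous and excluded from
#' quantification (rather than split); unmatched peaks are reported as
#' unassigned. Protonated positive ions only, no adducts.
#'
#' @param peaks data frame with columns `mz`, `intensity`.
#' @param candidates data frame with columns `species`, `mass` (Da).
#' @param tolerance_ppm matching tolerance (> 0).
#' @param z_range integer charge states considered for every species.
#' @return a list of class `"peak_assignment"`: `series` (data frame of
#'   assigned peaks: species, z, mz_theoretical, mz, intensity),
#'   `ambiguous` and `unassigned` (data frames of excluded peaks).
#' @export
assign_species_peaks <- function(peaks, candidates, tolerance_ppm = 50,
                                 z_range = 1:50) {
  if (tolerance_ppm <= 0)
    stop("assign_species_peaks: tolerance_ppm must be > 0",
         call. = FALSE)
  grid <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(i)
    data.frame(species = candidates$species[i],
               z = z_range,
               mz_theoretical = compute_mz(candidates$mass[i], z_range))))
  series <- ambiguous <- unassigned <- NULL
  for (i in seq_len(nrow(peaks))) {
    ppm <- abs(peaks$mz[i] - grid$mz_theoretical) /
      grid$mz_theoretical * 1e6
    hits <- which(ppm <= tolerance_ppm)
    # the same species can match at most once; distinct species matching
    # is what makes a peak ambiguous
    hit_species <- unique(grid$species[hits])
    row <- data.frame(mz = peaks$mz[i], intensity = peaks$intensity[i])
    if (length(hits) == 0) {
      unassigned <- rbind(unassigned, row)
    } else if (length(hit_species) > 1) {
      ambiguous <- rbind(ambiguous, cbind(
        row, matches = paste(grid$species[hits], grid$z[hits],
                             sep = "+", collapse = ";")))
    } else {
      h <- hits[which.min(ppm[hits])]
      series <- rbind(series, data.frame(
        species = grid$species[h], z = grid$z[h],
        mz_theoretical = grid$mz_theoretical[h],
        mz = peaks$mz[i], intensity = peaks$intensity[i]))
    }
  }
  structure(list(series = series, ambiguous = ambiguous,
                 unassigned = unassigned),
            class = "peak_assignment")
}

#' @export
print.peak_assignment <- function(x, ...) {
  n_s <- if (is.null(x$series)) 0L else nrow(x$series)
  n_a <- if (is.null(x$ambiguous)) 0L else nrow(x$ambiguous)
  n_u <- if (is.null(x$unassigned)) 0L else nrow(x$unassigned)
  cat(sprintf("Peak assignment: %d assigned, %d ambiguous, %d unassigned\n",
              n_s, n_a, n_u))
  if (n_s) {
    tab <- tapply(x$series$intensity, x$series$species, sum)
    cat("  summed intensity per species:\n")
    print(tab)
  }
  invisible(x)
}

#' Species signal fractions from assigned charge series
#'
#' Sums raw intensities over each species' assigned charge states and
#' normalises by the grand total. Ambiguous and unassigned peaks do not
#' contribute.
#'
#' @param assignment a `"peak_assignment"` (or a data frame with columns
#'   `species` and `intensity`).
#' @return named numeric vector of fractions summing to 1.
#' @export
species_signal_fractions <- function(assignment) {
  series <- if (inherits(assignment, "peak_assignment"))
    assignment$series else assignment
  if (is.null(series) || nrow(series) == 0)
    stop("species_signal_fractions: no assigned peaks", call. = FALSE)
  tot <- tapply(series$intensity, series$species, sum)
  if (sum(tot) <= 0)
    stop("species_signal_fractions: all intensities are zero",
         call. = FALSE)
  frac <- tot / sum(tot)
  out <- as.numeric(frac)
  names(out) <- names(frac)
  out
}
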