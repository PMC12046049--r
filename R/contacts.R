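#' Per-residue interface contact profile
#'
#' For every residue of the query chain, the shortest heavy-atom
#' distance to any heavy atom of the partner chain is computed in each
#' frame; the profile reports the minimum and the mean of these
#' per-frame shortest distances over the trajectory. Heavy atoms are
#' all non-hydrogen atoms.
#'
#' @param traj an `"md_trajectory"` with both chains present.
#' @param query_chain,partner_chain chain ids.
#' @return data frame of class `"contact_profile"` with columns `chain`,
#'   `resno`, `min_shortest`, `avg_shortest` (Angstrom);
#'   `min_shortest <= avg_shortest` for every residue.
#' @export
contact_profile <- function(traj, query_chain, partner_chain) {
  heavy <- traj$atoms$elesy != "H"
  qi <- which(heavy & traj$atoms$chain == query_chain)
  pi_ <- which(heavy & traj$atoms$chain == partner_chain)
  if (length(qi) == 0 || length(pi_) == 0)
    stop("contact_profile: a chain has no heavy atoms", call. = FALSE)
  resnos <- sort(unique(traj$atoms$resno[qi]))
  by_res <- lapply(resnos, function(r) qi[traj$atoms$resno[qi] == r])
  n <- n_frames(traj)
  per_frame <- matrix(NA_real_, n, length(resnos))
  for (f in seq_len(n)) {
    co <- .frame_coords(traj, f)
    pc <- co[pi_, , drop = FALSE]
    for (k in seq_along(resnos)) {
      qc <- co[by_res[[k]], , drop = FALSE]
      # all-pairs squared distances residue x partner
      d2 <- outer(rowSums(qc^2), rowSums(pc^2), `+`) -
        2 * qc %*% t(pc)
      per_frame[f, k] <- sqrt(max(min(d2), 0))
    }
  }
  structure(data.frame(chain = query_chain, resno = resnos,
                       min_shortest = apply(per_frame, 2, min),
                       avg_shortest = colMeans(per_frame)),
            class = c("contact_profile", "data.frame"))
}

#' Map contact distances to display saturation
#'
#' Linear rescaling of average shortest distances into \[0, 1\] for
#' surface colouring, saturating at the range ends: residues at or
#' closer than `d_min` get 1 (fully saturated, in contact), residues at
#' or beyond `d_max` get 0.
#'
#' @param profile a [contact_profile()].
#' @param d_min,d_max distance range (Angstrom, `d_max > d_min`).
#' @return named numeric vector of values in \[0, 1\], one per residue.
#' @export
surface_saturation_values <- function(profile, d_min = 3, d_max = 15) {
  if (nrow(profile) == 0)
    stop("surface_saturation_values: empty profile", call. = FALSE)
  if (d_max <= d_min)
    stop("surface_saturation_values: d_max must exceed d_min",
         call. = FALSE)
  v <- pmin(pmax((d_max - profile$avg_shortest) / (d_max - d_min), 0), 1)
  names(v) <- profile$resno
  v
}
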