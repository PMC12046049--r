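#' Geometric hydrogen-bond criteria
#'
#' The detection thresholds, all inclusive at the boundary: a hydrogen
#' belongs to a donor heavy atom when within `max_dh` of it; a bond is
#' counted when the hydrogen-acceptor distance is at most `max_ha` and
#' the donor-hydrogen-acceptor angle is at least `min_angle_dha`.
#'
#' @param max_dh donor-hydrogen distance cutoff (Angstrom).
#' @param max_ha hydrogen-acceptor distance cutoff (Angstrom).
#' @param min_angle_dha minimum D-H-A angle (degrees, in (0, 180\]).
#' @return a list of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(max_dh = 1.2, max_ha = 3.0,
                           min_angle_dha = 150) {
  if (max_dh <= 0 || max_ha <= 0 || min_angle_dha <= 0 ||
      min_angle_dha > 180)
    stop("hbond_criteria: cutoffs must be positive, angle in (0, 180]",
         call. = FALSE)
  structure(list(max_dh = max_dh, max_ha = max_ha,
                 min_angle_dha = min_angle_dha),
            class = "hbond_criteria")
}

# donor-hydrogen pairs: each H attached to its nearest N/O/S heavy atom
# within max_dh (chemistry inferred from geometry, not from residue
# templates, so toy systems work)
.donor_pairs <- function(coords, ele, max_dh) {
  h_idx <- which(ele == "H")
  d_idx <- which(ele %in% c("N", "O", "S"))
  if (length(h_idx) == 0 || length(d_idx) == 0)
    return(NULL)
  out <- NULL
  for (h in h_idx) {
    dv <- sqrt(colSums((t(coords[d_idx, , drop = FALSE]) -
                          coords[h, ])^2))
    ok <- which(dv <= max_dh)
    if (length(ok)) {
      j <- ok[which.min(dv[ok])]
      out <- rbind(out, c(donor = d_idx[j], hydrogen = h))
    }
  }
  out
}

#' Detect inter-chain hydrogen bonds in one frame
#'
#' Scans donor-hydrogen pairs on one chain against acceptors (N/O, plus
#' S when `include_s_acceptors`) on the other, in both directions, and
#' returns the triplets satisfying [hbond_criteria()]. Requires explicit
#' hydrogens: the criteria are defined on the hydrogen position.
#'
#' @param traj an `"md_trajectory"`.
#' @param frame 1-based frame index.
#' @param criteria an [hbond_criteria()].
#' @param chains length-2 character vector of chain ids to scan between.
#' @param include_s_acceptors allow sulfur acceptors.
#' @return data frame with one row per bond: donor/hydrogen/acceptor
#'   atom indices, donor and acceptor chain and residue number, the
#'   H...A distance and the D-H-A angle; zero rows when none found.
#' @export
detect_hbonds_frame <- function(traj, frame = 1,
                                criteria = hbond_criteria(),
                                chains = c("A", "B"),
                                include_s_acceptors = FALSE) {
  ele <- traj$atoms$elesy
  if (!any(ele == "H"))
    stop("detect_hbonds_frame: no hydrogens in the atom roster; the ",
         "hydrogen-bond criteria require explicit hydrogens",
         call. = FALSE)
  coords <- .frame_coords(traj, frame)
  pairs <- .donor_pairs(coords, ele, criteria$max_dh)
  acc_ele <- if (include_s_acceptors) c("N", "O", "S") else c("N", "O")
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0),
                      donor_chain = character(0),
                      donor_resno = integer(0),
                      acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      dist_ha = numeric(0), angle_dha = numeric(0))
  if (is.null(pairs)) return(empty)
  out <- empty
  for (dir in list(c(1, 2), c(2, 1))) {
    dc <- chains[dir[1]]; ac <- chains[dir[2]]
    p <- pairs[traj$atoms$chain[pairs[, "donor"]] == dc, , drop = FALSE]
    a_idx <- which(ele %in% acc_ele & traj$atoms$chain == ac)
    if (nrow(p) == 0 || length(a_idx) == 0) next
    for (k in seq_len(nrow(p))) {
      d <- p[k, "donor"]; h <- p[k, "hydrogen"]
      va <- t(coords[a_idx, , drop = FALSE]) - coords[h, ]
      dist_ha <- sqrt(colSums(va^2))
      cand <- which(dist_ha <= criteria$max_ha & a_idx != d)
      for (ci in cand) {
        a <- a_idx[ci]
        v1 <- coords[d, ] - coords[h, ]
        v2 <- coords[a, ] - coords[h, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang >= criteria$min_angle_dha)
          out <- rbind(out, data.frame(
            donor = d, hydrogen = h, acceptor = a,
            donor_chain = dc,
            donor_resno = traj$atoms$resno[d],
            acceptor_chain = ac,
            acceptor_resno = traj$atoms$resno[a],
            dist_ha = dist_ha[ci], angle_dha = ang))
      }
    }
  }
  out
}

#' Hydrogen-bond occupancy map over a trajectory
#'
#' For each inter-chain residue pair, the percentage of frames in which
#' the pair forms at least one hydrogen bond under the criteria. Pairs
#' are keyed by (residue on the first chain, residue on the second
#' chain) regardless of which side donates; a pair forming several
#' simultaneous bonds in a frame still counts that frame once (capped at
#' 100%). `count = "bonds"` instead sums bonds per frame, so values can
#' exceed 100%.
#'
#' @param traj an `"md_trajectory"`.
#' @param criteria an [hbond_criteria()].
#' @param chains length-2 chain ids.
#' @param count `"frames"` (default) or `"bonds"`.
#' @param include_s_acceptors passed to [detect_hbonds_frame()].
#' @return an object of class `"occupancy_map"`: data frame with columns
#'   `chain_i`, `resno_i`, `chain_j`, `resno_j`, `occupancy` (percent);
#'   pairs never bonded are absent (sparse map). Attribute `n_frames`.
#' @export
hbond_occupancy <- function(traj, criteria = hbond_criteria(),
                            chains = c("A", "B"),
                            count = c("frames", "bonds"),
                            include_s_acceptors = FALSE) {
  count <- match.arg(count)
  n <- n_frames(traj)
  tally <- new.env(parent = emptyenv())
  for (f in seq_len(n)) {
    hb <- detect_hbonds_frame(traj, f, criteria, chains,
                              include_s_acceptors)
    if (nrow(hb) == 0) next
    # normalise pair orientation to (chains[1], chains[2])
    ri <- ifelse(hb$donor_chain == chains[1], hb$donor_resno,
                 hb$acceptor_resno)
    rj <- ifelse(hb$donor_chain == chains[1], hb$acceptor_resno,
                 hb$donor_resno)
    keys <- paste(ri, rj, sep = "_")
    inc <- if (count == "frames") table(unique(keys)) else table(keys)
    if (count == "frames") inc[] <- 1
    for (k in names(inc)) {
      prev <- if (!is.null(tally[[k]])) tally[[k]] else 0
      tally[[k]] <- prev + as.numeric(inc[[k]])
    }
  }
  keys <- ls(tally)
  if (length(keys) == 0) {
    map <- data.frame(chain_i = character(0), resno_i = integer(0),
                      chain_j = character(0), resno_j = integer(0),
                      occupancy = numeric(0))
  } else {
    parts <- do.call(rbind, strsplit(keys, "_"))
    map <- data.frame(chain_i = chains[1],
                      resno_i = as.integer(parts[, 1]),
                      chain_j = chains[2],
                      resno_j = as.integer(parts[, 2]),
                      occupancy = 100 *
                        vapply(keys, function(k) tally[[k]],
                               numeric(1)) / n)
    map <- map[order(map$resno_i, map$resno_j), ]
    rownames(map) <- NULL
  }
  structure(map, class = c("occupancy_map", "data.frame"),
            n_frames = n, count = count)
}

#' Signed difference between two occupancy maps
#'
#' Per residue pair, `occupancy_b - occupancy_a` over the union of
#' pairs, treating pairs absent from a map as 0%. The result is
#' antisymmetric under swapping the arguments: a bond present in `a`
#' and lost in `b` appears with negative sign.
#'
#' @param map_a,map_b `"occupancy_map"`s on comparable residue
#'   numbering (e.g. reference vs modified state).
#' @return data frame of class `"occupancy_diff"` with columns
#'   `chain_i`, `resno_i`, `chain_j`, `resno_j`, `occupancy_a`,
#'   `occupancy_b`, `delta`.
#' @export
occupancy_difference <- function(map_a, map_b) {
  key <- function(m) paste(m$chain_i, m$resno_i, m$chain_j, m$resno_j)
  m <- merge(as.data.frame(map_a), as.data.frame(map_b),
             by = c("chain_i", "resno_i", "chain_j", "resno_j"),
             all = TRUE, suffixes = c("_a", "_b"))
  m$occupancy_a[is.na(m$occupancy_a)] <- 0
  m$occupancy_b[is.na(m$occupancy_b)] <- 0
  m$delta <- m$occupancy_b - m$occupancy_a
  names(m)[names(m) == "occupancy_a"] <- "occupancy_a"
  m <- m[order(m$resno_i, m$resno_j), ]
  rownames(m) <- NULL
  structure(m, class = c("occupancy_diff", "data.frame"))
}
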