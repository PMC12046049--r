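# Independent oracles used to cross-check the package's implementations.

# Horn's quaternion method for optimal rigid superposition: returns the
# RMSD of `mobile` (n x 3) onto `fixed` (n x 3). Independent of the
# Kabsch-style SVD route used by the package's RMSD backend.
quaternion_rmsd <- function(fixed, mobile) {
  n <- nrow(fixed)
  fc <- sweep(fixed, 2, colMeans(fixed))
  mc <- sweep(mobile, 2, colMeans(mobile))
  M <- t(mc) %*% fc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda_max <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(fc^2) + sum(mc^2) - 2 * lambda_max) / n
  sqrt(max(e2, 0))
}

# O(n^2) brute-force contact scan: per-residue min/avg shortest
# heavy-atom distance to the partner chain, computed with plain loops.
brute_contact_profile <- function(traj, query_chain, partner_chain) {
  heavy <- traj$atoms$elesy != "H"
  qi <- which(heavy & traj$atoms$chain == query_chain)
  pj <- which(heavy & traj$atoms$chain == partner_chain)
  resnos <- sort(unique(traj$atoms$resno[qi]))
  nfr <- nrow(traj$xyz)
  res <- data.frame(resno = resnos, min_shortest = NA_real_,
                    avg_shortest = NA_real_)
  for (k in seq_along(resnos)) {
    ri <- qi[traj$atoms$resno[qi] == resnos[k]]
    per_frame <- numeric(nfr)
    for (f in seq_len(nfr)) {
      co <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
      best <- Inf
      for (a in ri) for (b in pj) {
        d <- sqrt(sum((co[a, ] - co[b, ])^2))
        if (d < best) best <- d
      }
      per_frame[f] <- best
    }
    res$min_shortest[k] <- min(per_frame)
    res$avg_shortest[k] <- mean(per_frame)
  }
  res
}

# Small hand-built trajectory: one donor N-H on chain A, one acceptor O
# on chain B, geometry given per frame as (dist_HA, angle_DHA_deg).
make_dha_trajectory <- function(geometries) {
  atoms <- data.frame(elety = c("N", "H1", "O"),
                      resid = "GLY",
                      chain = c("A", "A", "B"),
                      resno = c(1L, 1L, 2L),
                      elesy = c("N", "H", "O"))
  xyz <- t(vapply(geometries, function(g) {
    d <- g[1]; ang <- g[2]
    phi <- (180 - ang) * pi / 180  # angle of H->A relative to +x
    a <- c(1 + d * cos(phi), d * sin(phi), 0)
    as.numeric(t(rbind(c(0, 0, 0), c(1, 0, 0), a)))
  }, numeric(9)))
  if (length(geometries) == 1) xyz <- matrix(xyz, nrow = 1)
  md_trajectory(atoms, xyz)
}

# random non-planar trajectory of n_atoms across n_frames, single chain
random_cloud_trajectory <- function(n_atoms, n_frames, seed,
                                    chain = "A") {
  set.seed(seed)
  atoms <- data.frame(elety = "CA", resid = "GLY", chain = chain,
                      resno = seq_len(n_atoms), elesy = "C")
  xyz <- matrix(rnorm(n_frames * 3 * n_atoms, sd = 5), n_frames)
  md_trajectory(atoms, xyz)
}
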