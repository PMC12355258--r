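# Independent brute-force oracles and tiny system builders shared by the
# tests. Oracles deliberately use naive loops over explicit periodic images
# or atom pairs, never the package's vectorized internals.

# Minimum-image distance by wrapping both points into the primary cell and
# enumerating all 27 periodic images.
oracle_min_image <- function(a, b, box) {
  a <- a %% box
  b <- b %% box
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    bb <- b + c(ix, iy, iz) * box
    best <- min(best, sqrt(sum((a - bb)^2)))
  }
  best
}

# Exhaustive residue-chain minimum distances: loops over every atom pair.
oracle_residue_chain_distances <- function(traj, frames) {
  top <- traj$topology
  copies <- sort(unique(top$molecule_id[top$species == "PROTEIN"]))
  chains <- sort(unique(top$molecule_id[top$species == "POLYMER"]))
  residues <- sort(unique(top$residue_id[top$species == "PROTEIN"]))
  d <- array(Inf, dim = c(length(copies), length(residues), length(frames),
                          length(chains)))
  for (jj in seq_along(frames)) {
    f <- traj$frames[[frames[jj]]]
    for (ci in seq_along(copies)) for (ri in seq_along(residues)) {
      pa <- which(top$molecule_id == copies[ci] &
                    top$residue_id == residues[ri] & top$species == "PROTEIN")
      for (ki in seq_along(chains)) {
        ca <- which(top$molecule_id == chains[ki])
        best <- Inf
        for (i in pa) for (j in ca) {
          best <- min(best, oracle_min_image(f$coords[i, ], f$coords[j, ], f$box))
        }
        d[ci, ri, jj, ki] <- best
      }
    }
  }
  list(d = d, d_min = apply(d, c(1, 2, 3), min))
}

# Brute-force hydrogen-bond detection: triple loop over (donor-H, acceptor).
oracle_detect_hbonds <- function(frame, topology, da, criteria) {
  hits <- list()
  for (p in seq_len(nrow(da$donors))) {
    D <- da$donors$donor[p]; H <- da$donors$hydrogen[p]
    for (A in da$acceptors) {
      if (A == D) next
      if (topology$molecule_id[A] == topology$molecule_id[D] &&
          topology$residue_id[A] == topology$residue_id[D]) next
      dist <- oracle_min_image(frame$coords[D, ], frame$coords[A, ], frame$box)
      if (dist > criteria$d_cut) next
      vH <- frame$coords[H, ] - frame$coords[D, ]
      vA <- frame$coords[A, ] - frame$coords[D, ]
      # min-image the vectors too
      vH <- vH - frame$box * round(vH / frame$box)
      vA <- vA - frame$box * round(vA / frame$box)
      ang <- acos(max(-1, min(1, sum(vH * vA) /
                                sqrt(sum(vH^2) * sum(vA^2))))) * 180 / pi
      if (ang <= criteria$angle_cut) {
        hits[[length(hits) + 1L]] <- data.frame(donor = D, hydrogen = H,
                                                acceptor = A, angle = ang)
      }
    }
  }
  if (!length(hits)) return(data.frame(donor = integer(0),
                                       hydrogen = integer(0),
                                       acceptor = integer(0),
                                       angle = numeric(0)))
  ev <- do.call(rbind, hits)
  ev <- ev[order(ev$donor, ev$acceptor, ev$angle), , drop = FALSE]
  ev[!duplicated(ev[, c("donor", "acceptor")]), , drop = FALSE]
}

# Brute-force per-Calpha contact count.
oracle_count_contacts <- function(frame, ca_sel, polymer_sel, cutoff) {
  n <- 0L
  for (i in ca_sel) {
    touched <- FALSE
    for (j in polymer_sel) {
      if (oracle_min_image(frame$coords[i, ], frame$coords[j, ], frame$box) <=
          cutoff) { touched <- TRUE; break }
    }
    if (touched) n <- n + 1L
  }
  n
}

# A hand-sized mixed system: n_prot single-atom-per-residue proteins and
# n_chain short chains at explicit coordinates, for direct-construction
# tests.
tiny_system <- function(n_prot = 2, n_res = 3, n_chain = 2, chain_len = 4,
                        box = c(20, 20, 20), seed = 1) {
  set.seed(seed)
  atoms <- list(); xyz <- list()
  for (c in seq_len(n_prot)) {
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = "CA", element = "C", mass = 100, charge = 0,
      residue_id = seq_len(n_res), residue_name = "LYZ", molecule_id = c,
      species = "PROTEIN")
    xyz[[length(xyz) + 1L]] <- matrix(runif(n_res * 3, 0, box[1]), ncol = 3)
  }
  for (k in seq_len(n_chain)) {
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = "C", element = "C", mass = 70, charge = 0,
      residue_id = seq_len(chain_len), residue_name = "ACR",
      molecule_id = n_prot + k, species = "POLYMER")
    xyz[[length(xyz) + 1L]] <- matrix(runif(chain_len * 3, 0, box[1]), ncol = 3)
  }
  top <- new_topology(do.call(rbind, atoms))
  new_trajectory(top, list(new_frame(do.call(rbind, xyz), box, time = 0)))
}

# Random multi-frame variant of tiny_system.
tiny_trajectory <- function(n_frames = 3, ..., seed = 1) {
  t1 <- tiny_system(..., seed = seed)
  set.seed(seed + 1000)
  box <- t1$frames[[1]]$box
  n <- nrow(t1$frames[[1]]$coords)
  frames <- lapply(seq_len(n_frames), function(j) {
    new_frame(matrix(runif(n * 3, 0, box[1]), ncol = 3), box, time = j - 1)
  })
  new_trajectory(t1$topology, frames)
}
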