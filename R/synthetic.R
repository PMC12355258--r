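# Synthetic trajectory generators with known ground truth.
#
# Two regimes: planted-geometry mode places bead-per-residue proteins and
# bead-per-monomer chains so that every association distance, hydrogen-bond
# geometry, contact and bridge is known exactly (for exact analyzer tests),
# and a toy overdamped-Langevin mode emulates the study system -- charged
# protein spheres and flexible polyelectrolyte chains interacting through
# screened (Debye-Hueckel) electrostatics -- for qualitative trend checks.

#' Synthetic system specification
#'
#' Defaults emulate the reference composition: 16 proteins of 129 residues,
#' 8 polyelectrolyte chains of 40 monomers with half the monomers carrying
#' a -1 charge, monomer spacing 0.27 nm, Bjerrum length 0.7 nm, ionic
#' strength 0.15 M, and a protein net charge acting as a pH proxy (+8 for
#' neutral pH, through 0, to -4 for strongly alkaline conditions).
#'
#' @param n_proteins,n_residues,n_chains,chain_length system composition.
#' @param charged_fraction fraction of charged monomers in [0, 1].
#' @param monomer_spacing nm.
#' @param bjerrum_length nm.
#' @param ionic_strength mol/L.
#' @param protein_net_charge elementary charges (pH proxy).
#' @param protein_radius nm; radius of the rigid protein bead sphere.
#' @param temperature_factor dimensionless thermal-noise scale (1 = ambient).
#' @param box edge lengths nm, or NULL to size automatically.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 16L, n_residues = 129L, n_chains = 8L,
                           chain_length = 40L, charged_fraction = 0.5,
                           monomer_spacing = 0.27, bjerrum_length = 0.7,
                           ionic_strength = 0.15, protein_net_charge = 8L,
                           protein_radius = 1.5, temperature_factor = 1,
                           box = NULL) {
  stopifnot(n_proteins >= 1, n_residues >= 1, n_chains >= 1, chain_length >= 1,
            charged_fraction >= 0, charged_fraction <= 1,
            monomer_spacing > 0, bjerrum_length > 0, ionic_strength >= 0,
            protein_radius > 0, temperature_factor >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_residues = as.integer(n_residues),
                 n_chains = as.integer(n_chains),
                 chain_length = as.integer(chain_length),
                 charged_fraction = charged_fraction,
                 monomer_spacing = monomer_spacing,
                 bjerrum_length = bjerrum_length,
                 ionic_strength = ionic_strength,
                 protein_net_charge = as.integer(protein_net_charge),
                 protein_radius = protein_radius,
                 temperature_factor = temperature_factor,
                 box = box),
            class = "synthetic_spec")
}

#' Debye screening length from ionic strength
#'
#' kappa^2 = 8 pi lambda_B n_I with n_I the ionic strength converted to a
#' number density (mol/L -> nm^-3); returns kappa^-1 in nm (about 0.79 nm
#' at 0.15 M with lambda_B = 0.7 nm).
#'
#' @param ionic_strength mol/L.
#' @param bjerrum_length nm.
#' @return Debye length, nm (Inf at zero ionic strength).
#' @export
debye_length <- function(ionic_strength, bjerrum_length = 0.7) {
  if (ionic_strength <= 0) return(Inf)
  n_per_nm3 <- ionic_strength * 6.02214076e23 / 1e24  # mol/L -> nm^-3
  1 / sqrt(8 * pi * bjerrum_length * n_per_nm3)
}

# Evenly distributed points on a unit sphere (Fibonacci lattice);
# deterministic.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Protein bead charges: |q| beads carry sign(q) each, the rest 0.
protein_bead_charges <- function(n_beads, net_charge) {
  q <- numeric(n_beads)
  k <- min(abs(net_charge), n_beads)
  if (k > 0) q[seq_len(k)] <- sign(net_charge)
  if (abs(net_charge) > n_beads) q <- q * abs(net_charge) / n_beads
  q
}

# Monomer charges: round(f * L) charged monomers, spread evenly
# (every-other for f = 0.5), each -1.
chain_bead_charges <- function(chain_length, charged_fraction) {
  q <- numeric(chain_length)
  k <- round(charged_fraction * chain_length)
  if (k > 0) q[round(seq(1, chain_length, length.out = k))] <- -1
  q
}

# Run a generator body with a private, restored RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## ---- planted-geometry mode ------------------------------------------------

#' Plant manifest for the planted-geometry generator
#'
#' Declares the ground truth a planted trajectory must realize:
#'
#' * `association`: data.frame with columns `copy`, `residue`, `chain`,
#'   `distance` (nm) and optional `active_from` (first frame index at which
#'   the plant holds; earlier frames leave the residue on its protein
#'   sphere, far from every chain). Each row pins that residue of that
#'   protein copy at exactly `distance` from its nearest atom of chain
#'   `chain` (and farther from every other chain).
#' * `hbonds`: data.frame with columns `distance` (nm), `angle` (degrees)
#'   and optional `donor_species`, `acceptor_species` (default WATER) and
#'   `active_from`. Each row plants an isolated donor-hydrogen-acceptor
#'   triple with exactly that geometry.
#'
#' @param association,hbonds data.frames as above (either may be NULL).
#' @return list of class `plant_manifest`.
#' @export
plant_manifest <- function(association = NULL, hbonds = NULL) {
  assoc <- if (is.null(association)) {
    data.frame(copy = integer(0), residue = integer(0), chain = integer(0),
               distance = numeric(0), active_from = integer(0))
  } else {
    association <- as.data.frame(association)
    if (is.null(association$chain)) association$chain <- 1L
    if (is.null(association$active_from)) association$active_from <- 1L
    association
  }
  hb <- if (is.null(hbonds)) {
    data.frame(distance = numeric(0), angle = numeric(0),
               donor_species = character(0), acceptor_species = character(0),
               active_from = integer(0))
  } else {
    hbonds <- as.data.frame(hbonds)
    if (is.null(hbonds$donor_species)) hbonds$donor_species <- "WATER"
    if (is.null(hbonds$acceptor_species)) hbonds$acceptor_species <- "WATER"
    if (is.null(hbonds$active_from)) hbonds$active_from <- 1L
    hbonds
  }
  if (nrow(assoc) && anyDuplicated(assoc[, c("copy", "residue")])) {
    stop("conflicting plants: duplicate (copy, residue) rows in association manifest")
  }
  structure(list(association = assoc, hbonds = hb), class = "plant_manifest")
}

#' Generate a planted-geometry trajectory
#'
#' Builds a bead-per-residue / bead-per-monomer system in which every
#' quantity declared by the manifest holds exactly: proteins sit on a grid
#' with their residues on spheres, chains are straight rods in a separate
#' region (>= 3 nm from every protein), and each planted residue or
#' hydrogen-bond triple is placed analytically. Optional uniform jitter
#' (strictly below the criterion margins) perturbs every atom per frame.
#'
#' The returned manifest gains an `expected` element with the analyzer
#' ground truth: `ar` (named AR% per residue, for plants active in every
#' frame), `hbond_detected` (valid triple count under the default
#' criteria), `contacts_per_frame` (per-Calpha counts at 0.6 nm), and
#' `bridges` (chain -> protein sets at the 0.35 nm link cutoff).
#'
#' @param spec a [synthetic_spec()].
#' @param manifest a [plant_manifest()].
#' @param n_frames number of frames (default 10).
#' @param seed RNG seed (jitter only; the geometry is deterministic).
#' @param jitter uniform per-coordinate jitter amplitude, nm (default 0 =
#'   noise-free). Keep below ~0.01 to stay inside the planted margins.
#' @param dt_ps frame spacing, ps (default 100).
#' @return list with `trajectory` (`md_trajectory`) and `manifest` (the
#'   input manifest plus `$expected`).
#' @export
generate_planted <- function(spec, manifest = plant_manifest(), n_frames = 10L,
                             seed = 1L, jitter = 0, dt_ps = 100) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(manifest, "plant_manifest"))
  assoc <- manifest$association
  hb <- manifest$hbonds
  if (nrow(assoc)) {
    if (any(assoc$copy < 1L | assoc$copy > spec$n_proteins)) {
      stop("association plant references a protein copy outside 1..", spec$n_proteins)
    }
    if (any(assoc$residue < 1L | assoc$residue > spec$n_residues)) {
      stop("association plant references a residue outside 1..", spec$n_residues)
    }
    if (any(assoc$chain < 1L | assoc$chain > spec$n_chains)) {
      stop("association plant references a chain outside 1..", spec$n_chains)
    }
    # at most chain_length %/% 2 plants per chain (anchors 2 monomers apart)
    per_chain <- table(assoc$chain)
    if (any(per_chain > spec$chain_length %/% 2)) {
      stop("infeasible manifest: more than chain_length/2 plants on chain(s) ",
           paste(names(per_chain)[per_chain > spec$chain_length %/% 2],
                 collapse = ", "))
    }
  }

  rp <- spec$protein_radius
  sp_grid <- 2 * rp + 3            # protein grid spacing
  ncol_p <- ceiling(sqrt(spec$n_proteins))
  chain_len_nm <- (spec$chain_length - 1) * spec$monomer_spacing
  margin <- 2.5

  # region z-planes: proteins, chains, hbond triples
  z_prot <- margin + rp
  z_chain <- z_prot + rp + 3.5
  z_hb <- z_chain + 3.5
  box_z <- z_hb + margin + 1
  hb_rows_grid <- ceiling(max(1, nrow(hb)) / 8)
  box_x <- max(ncol_p * sp_grid, chain_len_nm + 2 * margin, 16) + margin
  box_y <- max(ncol_p * sp_grid, spec$n_chains * 3,
               2 * hb_rows_grid + 2 * margin) + margin
  # doubled so even a planted residue far from its protein sphere leaves the
  # molecule within half a box edge (keeps unwrap-based metrics well-defined);
  # planted distances are unaffected, cross-region image distances only grow
  box <- spec$box %||% (2 * c(box_x, box_y, box_z))

  atoms <- list()
  coords <- list()
  # proteins
  sphere <- fibonacci_sphere(spec$n_residues) * rp
  qp <- protein_bead_charges(spec$n_residues, spec$protein_net_charge)
  for (c in seq_len(spec$n_proteins)) {
    gx <- ((c - 1L) %% ncol_p)
    gy <- ((c - 1L) %/% ncol_p)
    center <- c(margin + rp + gx * sp_grid, margin + rp + gy * sp_grid, z_prot)
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = "CA", element = "C", mass = 110, charge = qp,
      residue_id = seq_len(spec$n_residues), residue_name = "LYZ",
      molecule_id = c, species = "PROTEIN", stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <- sweep(sphere, 2, center, "+")
  }
  # chains
  qc <- chain_bead_charges(spec$chain_length, spec$charged_fraction)
  for (k in seq_len(spec$n_chains)) {
    start <- c(margin, margin + (k - 1) * 3, z_chain)
    co <- cbind(start[1] + (seq_len(spec$chain_length) - 1) * spec$monomer_spacing,
                start[2], start[3])
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = "C", element = "C", mass = 72, charge = qc,
      residue_id = seq_len(spec$chain_length), residue_name = "ACR",
      molecule_id = spec$n_proteins + k, species = "POLYMER",
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <- co
  }
  top_df <- do.call(rbind, atoms)
  base_xyz <- do.call(rbind, coords)
  next_mol <- spec$n_proteins + spec$n_chains

  # hydrogen-bond triples: donor molecule (D + H) and acceptor molecule (A)
  if (nrow(hb)) {
    hb_rows <- vector("list", nrow(hb))
    hb_xyz <- vector("list", nrow(hb))
    for (t in seq_len(nrow(hb))) {
      g <- c(margin + 2 * ((t - 1L) %% 8L), margin + 2 * ((t - 1L) %/% 8L), z_hb)
      ang <- hb$angle[t] * pi / 180
      D <- g
      H <- g + c(0.1, 0, 0)
      A <- g + hb$distance[t] * c(cos(ang), sin(ang), 0)
      hb_rows[[t]] <- data.frame(
        name = c("OD", "HD", "OA"), element = c("O", "H", "O"),
        mass = c(16, 1, 16), charge = 0,
        residue_id = 1L,
        residue_name = "HBD",
        molecule_id = c(next_mol + 1L, next_mol + 1L, next_mol + 2L),
        species = c(hb$donor_species[t], hb$donor_species[t],
                    hb$acceptor_species[t]),
        stringsAsFactors = FALSE)
      next_mol <- next_mol + 2L
      hb_xyz[[t]] <- rbind(D, H, A)
    }
    top_df <- rbind(top_df, do.call(rbind, hb_rows))
    base_xyz <- rbind(base_xyz, do.call(rbind, hb_xyz))
  }

  topology <- new_topology(top_df)

  # index helpers for plants
  prot_rows <- function(copy, residue) {
    which(topology$molecule_id == copy & topology$residue_id == residue &
            topology$species == "PROTEIN")
  }
  chain_atom_row <- function(chain, monomer) {
    which(topology$molecule_id == spec$n_proteins + chain &
            topology$residue_id == monomer)
  }

  # assign anchor monomers per chain: 2 apart, starting at monomer 1
  anchor <- integer(nrow(assoc))
  if (nrow(assoc)) {
    for (k in unique(assoc$chain)) {
      idx <- which(assoc$chain == k)
      anchor[idx] <- 1L + 2L * (seq_along(idx) - 1L)
    }
  }

  # hbond triples appended last, 3 atoms each (D, H, A)
  hb_row0 <- nrow(top_df) - 3L * nrow(hb)

  frames <- vector("list", n_frames)
  plant_rows <- if (nrow(assoc)) vapply(seq_len(nrow(assoc)), function(p) {
    r <- prot_rows(assoc$copy[p], assoc$residue[p])
    if (length(r) != 1L) stop("plant maps to ", length(r), " atoms")
    r
  }, integer(1)) else integer(0)

  with_seed(seed, {
    for (j in seq_len(n_frames)) {
      xyz <- base_xyz
      if (nrow(assoc)) {
        for (p in seq_len(nrow(assoc))) {
          if (j >= assoc$active_from[p]) {
            a_row <- chain_atom_row(assoc$chain[p], anchor[p])
            # offset toward the protein region (-z): nearest chain atom is the
            # anchor, neighbours are sqrt(d^2 + spacing^2) away
            xyz[plant_rows[p], ] <- xyz[a_row, ] + c(0, 0, -assoc$distance[p])
          }
        }
      }
      if (nrow(hb)) {
        for (t in seq_len(nrow(hb))) {
          if (j < hb$active_from[t]) {
            a_row <- hb_row0 + 3L * (t - 1L) + 3L
            xyz[a_row, 3] <- xyz[a_row, 3] + 2.5  # park acceptor out of range
          }
        }
      }
      if (jitter > 0) {
        xyz <- xyz + matrix(stats::runif(length(xyz), -jitter, jitter),
                            ncol = 3)
      }
      frames[[j]] <- new_frame(xyz, box, time = (j - 1) * dt_ps)
    }
  })

  traj <- new_trajectory(topology, frames)
  manifest$expected <- planted_expectations(spec, assoc, hb, n_frames,
                                            jitter = jitter)
  list(trajectory = traj, manifest = manifest)
}

# Ground-truth predictions implied by a manifest (independent of the
# generated coordinates; plants active in every frame drive AR).
planted_expectations <- function(spec, assoc, hb, n_frames, jitter = 0,
                                 ar_threshold = 0.35, contact_cutoff = 0.6,
                                 bridge_cutoff = 0.35,
                                 criteria = hbond_criteria()) {
  ar <- stats::setNames(numeric(spec$n_residues),
                        as.character(seq_len(spec$n_residues)))
  contacts <- integer(n_frames)
  bridges <- data.frame(chain = integer(0), n_proteins = integer(0),
                        proteins = character(0))
  if (nrow(assoc)) {
    always <- assoc[assoc$active_from <= 1L, , drop = FALSE]
    if (nrow(always)) {
      within <- always[always$distance <= ar_threshold, , drop = FALSE]
      if (nrow(within)) {
        tab <- table(within$residue)
        ar[names(tab)] <- 100 * as.integer(tab) / spec$n_proteins
      }
    }
    for (j in seq_len(n_frames)) {
      act <- assoc$active_from <= j & assoc$distance <= contact_cutoff
      contacts[j] <- sum(act)
    }
    links <- assoc[assoc$active_from <= 1L & assoc$distance <= bridge_cutoff, ,
                   drop = FALSE]
    if (nrow(links)) {
      by_chain <- split(links$copy, links$chain)
      keep <- vapply(by_chain, function(p) length(unique(p)) >= 2L, logical(1))
      if (any(keep)) {
        bridges <- do.call(rbind, lapply(names(by_chain)[keep], function(k) {
          p <- sort(unique(by_chain[[k]]))
          data.frame(chain = spec$n_proteins + as.integer(k),
                     n_proteins = length(p),
                     proteins = paste(p, collapse = ","))
        }))
      }
    }
  }
  hb_detected <- if (nrow(hb)) {
    sum(hb$active_from <= 1L & hb$distance <= criteria$d_cut &
          hb$angle <= criteria$angle_cut)
  } else 0L
  list(ar = ar, hbond_detected = as.integer(hb_detected),
       contacts_per_frame = contacts, bridges = bridges,
       jitter = jitter)
}

## ---- ideal-gas mode -------------------------------------------------------

#' Generate an ideal-gas trajectory (RDF null model)
#'
#' Two non-interacting species with uniform independent positions redrawn
#' each frame; g(r) of such a system is 1 at every r.
#'
#' @param n_A,n_B particle counts (species PROTEIN and POLYMER, one atom
#'   per molecule).
#' @param box edge lengths nm.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return an `md_trajectory`.
#' @export
generate_ideal_gas <- function(n_A, n_B, box = c(5, 5, 5), n_frames = 10L,
                               seed = 1L) {
  stopifnot(n_A >= 1, n_B >= 1)
  box <- if (length(box) == 1L) rep(box, 3L) else box
  top <- new_topology(data.frame(
    name = c(rep("A", n_A), rep("B", n_B)),
    element = "C", mass = 1, charge = 0, residue_id = 1L,
    residue_name = c(rep("GAS", n_A), rep("GAS", n_B)),
    molecule_id = seq_len(n_A + n_B),
    species = c(rep("PROTEIN", n_A), rep("POLYMER", n_B)),
    stringsAsFactors = FALSE))
  n <- n_A + n_B
  with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(j) {
      xyz <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                   stats::runif(n, 0, box[3]))
      new_frame(xyz, box, time = j - 1)
    })
    new_trajectory(top, frames)
  })
}

## ---- toy Langevin mode ----------------------------------------------------

#' Generate a toy Langevin trajectory
#'
#' Overdamped (Brownian) dynamics of rigid charged protein spheres,
#' flexible bead-spring polyelectrolyte chains and monovalent counterions
#' in a periodic box. Interactions: harmonic bonds at the monomer spacing,
#' screened Debye-Hueckel electrostatics (Bjerrum length and Debye length
#' from the spec's ionic strength, energies in kT), and a soft quadratic
#' excluded-volume repulsion. Proteins move as rigid bodies (translation
#' only). Thermal noise scales with `temperature_factor`. This is an
#' emulation of the study system's composition and electrostatics, not an
#' atomistic model.
#'
#' @param spec a [synthetic_spec()]. `box = NULL` sizes the box for a
#'   semi-dilute system.
#' @param n_steps integration steps (default 6000).
#' @param dt reduced time step (default 0.001; the deterministic drift per
#'   step is checked against half the monomer spacing and violation is an
#'   error).
#' @param seed RNG seed; trajectories are bit-reproducible from
#'   (spec, seed).
#' @param save_every record a frame every this many steps (default 50).
#' @param n_ions number of +1 counterions; default neutralizes the system.
#' @return an `md_trajectory` (times in ps, 1 ps per saved interval).
#' @export
generate_langevin <- function(spec, n_steps = 6000L, dt = 0.001, seed = 1L,
                              save_every = 50L, n_ions = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rp <- spec$protein_radius
  qp <- protein_bead_charges(spec$n_residues, spec$protein_net_charge)
  qc <- chain_bead_charges(spec$chain_length, spec$charged_fraction)
  total_q <- spec$n_proteins * sum(qp) + spec$n_chains * sum(qc)
  n_ions <- n_ions %||% max(0L, as.integer(round(-total_q)))
  n_beads <- spec$n_proteins * spec$n_residues +
    spec$n_chains * spec$chain_length + n_ions

  box <- spec$box %||% rep(max(
    2.5 * rp * ceiling(spec$n_proteins^(1 / 3)) + 2,
    ((n_beads * 0.6) / 1)^(1 / 3), 6), 3)
  if (length(box) == 1L) box <- rep(box, 3L)

  atoms <- list()
  for (c in seq_len(spec$n_proteins)) {
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = "CA", element = "C", mass = 110, charge = qp,
      residue_id = seq_len(spec$n_residues), residue_name = "LYZ",
      molecule_id = c, species = "PROTEIN", stringsAsFactors = FALSE)
  }
  for (k in seq_len(spec$n_chains)) {
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = "C", element = "C", mass = 72, charge = qc,
      residue_id = seq_len(spec$chain_length), residue_name = "ACR",
      molecule_id = spec$n_proteins + k, species = "POLYMER",
      stringsAsFactors = FALSE)
  }
  if (n_ions > 0L) {
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = "NA", element = "N", mass = 23, charge = 1,
      residue_id = 1L, residue_name = "NA",
      molecule_id = spec$n_proteins + spec$n_chains + seq_len(n_ions),
      species = "ION", stringsAsFactors = FALSE)
  }
  topology <- new_topology(do.call(rbind, atoms))
  q <- topology$charge

  lam <- spec$bjerrum_length
  kappa <- 1 / debye_length(spec$ionic_strength, lam)
  r_cut <- if (is.finite(kappa) && kappa > 0) min(3 / kappa, min(box) / 2 - 1e-6)
           else min(box) / 2 - 1e-6
  sigma <- 0.35          # soft-core diameter, nm
  k_ev <- 50             # excluded-volume stiffness, kT/nm^2
  k_bond <- 80           # bond stiffness, kT/nm^2 (thermal bond sd ~0.11 nm)
  r_el_min <- 0.3        # electrostatic force capped below this separation
  Tfac <- spec$temperature_factor

  sphere <- fibonacci_sphere(spec$n_residues) * rp
  prot_idx <- lapply(seq_len(spec$n_proteins), function(c)
    select_atoms(topology, molecule_id = c))
  chain_idx <- lapply(seq_len(spec$n_chains), function(k)
    select_atoms(topology, molecule_id = spec$n_proteins + k))
  ion_idx <- select_atoms(topology, species = "ION")

  max_disp_ok <- 0.5 * spec$monomer_spacing

  with_seed(seed, {
    # initial placement: proteins on a grid, chains as random-direction rods,
    # ions uniform
    xyz <- matrix(0, n_beads, 3)
    ng <- ceiling(spec$n_proteins^(1 / 3))
    centers <- matrix(0, spec$n_proteins, 3)
    for (c in seq_len(spec$n_proteins)) {
      g <- c((c - 1L) %% ng, ((c - 1L) %/% ng) %% ng, (c - 1L) %/% (ng * ng))
      centers[c, ] <- (g + 0.5) * box / ng
      xyz[prot_idx[[c]], ] <- sweep(sphere, 2, centers[c, ], "+")
    }
    for (k in seq_len(spec$n_chains)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      start <- stats::runif(3) * box
      xyz[chain_idx[[k]], ] <- start[col(matrix(0, spec$chain_length, 3))] +
        outer((seq_len(spec$chain_length) - 1) * spec$monomer_spacing, u)
    }
    if (n_ions > 0L) {
      xyz[ion_idx, ] <- cbind(stats::runif(n_ions, 0, box[1]),
                              stats::runif(n_ions, 0, box[2]),
                              stats::runif(n_ions, 0, box[3]))
    }
    # tiny jitter on flexible beads so no non-bonded pair starts coincident
    # (a coincident pair has zero net repulsion and would evade relaxation)
    nonrigid <- c(unlist(chain_idx), ion_idx)
    if (length(nonrigid)) {
      xyz[nonrigid, ] <- xyz[nonrigid, ] +
        matrix(stats::runif(3 * length(nonrigid), -0.02, 0.02),
               length(nonrigid), 3)
    }

    bond_i <- unlist(lapply(chain_idx, function(ix) ix[-length(ix)]))
    bond_j <- unlist(lapply(chain_idx, function(ix) ix[-1]))

    # loop invariants: charge products and the pair mask excluding
    # intra-protein (rigid) and directly bonded pairs
    qq <- outer(q, q)
    pair_on <- matrix(TRUE, n_beads, n_beads)
    diag(pair_on) <- FALSE
    for (c in seq_len(spec$n_proteins)) pair_on[prot_idx[[c]], prot_idx[[c]]] <- FALSE
    if (length(bond_i)) {
      pair_on[cbind(bond_i, bond_j)] <- FALSE
      pair_on[cbind(bond_j, bond_i)] <- FALSE
    }
    free <- setdiff(seq_len(n_beads), unlist(prot_idx))

    forces <- function(xyz) {
      F <- matrix(0, n_beads, 3)
      dx <- vector("list", 3)
      d2 <- matrix(0, n_beads, n_beads)
      for (kk in 1:3) {
        dd <- outer(xyz[, kk], xyz[, kk], "-")
        dd <- dd - box[kk] * round(dd / box[kk])
        dx[[kk]] <- dd
        d2 <- d2 + dd * dd
      }
      r <- sqrt(d2)
      r[!pair_on] <- Inf
      fmag <- matrix(0, n_beads, n_beads)
      el <- qq != 0 & r < r_cut
      if (any(el)) {
        # -dU/dr of lam*qq*exp(-kr)/r; positive = repulsive (along +dx);
        # capped below r_el_min so the soft core always wins at contact
        rr <- pmax(r[el], r_el_min)
        fmag[el] <- lam * qq[el] * exp(-kappa * rr) * (kappa * rr + 1) / rr^2
      }
      ev <- r < sigma
      if (any(ev)) fmag[ev] <- fmag[ev] + 2 * k_ev * (sigma - r[ev])
      fr <- fmag / pmax(r, 0.05)  # floored to keep deep overlaps finite
      fr[!is.finite(fr) | !pair_on] <- 0
      for (kk in 1:3) F[, kk] <- rowSums(fr * dx[[kk]])
      if (length(bond_i)) {
        bb <- xyz[bond_i, , drop = FALSE] - xyz[bond_j, , drop = FALSE]
        for (kk in 1:3) bb[, kk] <- bb[, kk] - box[kk] * round(bb[, kk] / box[kk])
        bl <- sqrt(rowSums(bb^2))
        fvec <- bb * (-k_bond * (bl - spec$monomer_spacing) / pmax(bl, 1e-9))
        for (kk in 1:3) {
          acc <- numeric(n_beads)
          inc <- tapply(c(fvec[, kk], -fvec[, kk]), c(bond_i, bond_j), sum)
          acc[as.integer(names(inc))] <- inc
          F[, kk] <- F[, kk] + acc
        }
      }
      F
    }

    # drift displacement for one step (no noise); proteins move rigidly by
    # their center-of-mass force with friction ~ bead count
    drift <- function(F, dt) {
      disp <- matrix(0, n_beads, 3)
      for (c in seq_len(spec$n_proteins)) {
        ix <- prot_idx[[c]]
        disp[ix, ] <- matrix(dt * colSums(F[ix, , drop = FALSE]) / length(ix),
                             length(ix), 3, byrow = TRUE)
      }
      if (length(free)) disp[free, ] <- dt * F[free, , drop = FALSE]
      disp
    }

    # clamped steepest-descent warmup: relax initial overlaps until the
    # drift satisfies the dynamics stability bound (relaxation, not dynamics)
    for (w in seq_len(3000L)) {
      disp <- drift(forces(xyz), dt / 10)
      if (w > 150L && max(abs(disp)) * 10 <= 0.5 * max_disp_ok) break
      disp[disp > 0.02] <- 0.02
      disp[disp < -0.02] <- -0.02
      xyz <- xyz + disp
    }

    frames <- vector("list", n_steps %/% save_every)
    fidx <- 0L
    for (step in seq_len(n_steps)) {
      disp <- drift(forces(xyz), dt)
      # stability criterion on the deterministic drift: a drift step larger
      # than half a bond length means the integration is too stiff for dt
      mx <- max(abs(disp))
      if (!is.finite(mx) || mx > max_disp_ok) {
        stop(sprintf("integration unstable at step %d: drift displacement %.3g nm exceeds %.3g nm; reduce dt",
                     step, mx, max_disp_ok))
      }
      if (Tfac > 0) {
        amp_free <- sqrt(2 * dt * Tfac)
        noise <- matrix(stats::rnorm(n_beads * 3), n_beads, 3) * amp_free
        for (c in seq_len(spec$n_proteins)) {
          ix <- prot_idx[[c]]
          dcom <- sqrt(2 * dt * Tfac / length(ix)) * stats::rnorm(3)
          noise[ix, ] <- matrix(dcom, length(ix), 3, byrow = TRUE)
        }
        disp <- disp + noise
      }
      xyz <- xyz + disp
      if (step %% save_every == 0L) {
        fidx <- fidx + 1L
        frames[[fidx]] <- new_frame(xyz %% rep(box, each = n_beads), box,
                                    time = fidx - 1)
      }
    }
    if (fidx == 0L) stop("n_steps < save_every: no frames recorded")
    new_trajectory(topology, frames[seq_len(fidx)])
  })
}
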