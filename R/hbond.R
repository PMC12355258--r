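# Geometric hydrogen-bond detection and species-pair accounting.
#
# A hydrogen bond is scored when the donor-acceptor minimum-image distance
# is <= d_cut (default 0.35 nm) and the hydrogen-donor-acceptor angle --
# vertex at the donor, between the D->H and D->A directions -- is
# <= angle_cut (default 30 degrees). Both comparisons are boundary
# inclusive. Donors are N/O atoms with at least one attached hydrogen;
# acceptors are all N/O atoms.

#' Hydrogen-bond criteria
#'
#' @param d_cut donor-acceptor distance cutoff, nm (default 0.35).
#' @param angle_cut hydrogen-donor-acceptor angle cutoff, degrees
#'   (default 30).
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_cut = 0.35, angle_cut = 30) {
  if (d_cut <= 0) stop("d_cut must be positive")
  if (angle_cut <= 0 || angle_cut >= 180) stop("angle_cut must lie in (0, 180)")
  structure(list(d_cut = d_cut, angle_cut = angle_cut), class = "hbond_criteria")
}

#' Identify hydrogen-bond donors and acceptors
#'
#' Donors are N or O atoms with at least one attached hydrogen; acceptors
#' are all N and O atoms. Hydrogen attachment uses the covalent `bonds`
#' attribute of the topology when present (two-column matrix of 1-based atom
#' indices), otherwise a distance criterion: an H belongs to the nearest
#' N/O/C heavy atom within `attach_cut` in the supplied frame, and counts
#' toward a donor only when that heavy atom is N or O.
#'
#' @param topology a `topology`.
#' @param frame frame used for distance-based attachment (required when the
#'   topology has no bond table).
#' @param attach_cut covalent attachment distance, nm (default 0.12).
#' @return list with `donors` (data.frame donor, hydrogen: 1-based atom
#'   indices, one row per D-H pair, ordered by donor then hydrogen) and
#'   `acceptors` (integer vector, ascending).
#' @export
find_donors_acceptors <- function(topology, frame = NULL, attach_cut = 0.12) {
  is_no <- topology$element %in% c("N", "O")
  is_h <- topology$element == "H"
  acceptors <- which(is_no)
  hyd <- which(is_h)
  donors <- data.frame(donor = integer(0), hydrogen = integer(0))
  if (length(hyd)) {
    bonds <- attr(topology, "bonds")
    if (!is.null(bonds)) {
      b <- rbind(bonds, bonds[, 2:1, drop = FALSE])
      b <- b[b[, 2] %in% hyd, , drop = FALSE]
      heavy_of <- stats::setNames(b[, 1], b[, 2])
      miss <- setdiff(hyd, as.integer(names(heavy_of)))
      if (length(miss)) {
        stop("hydrogen atom(s) with no covalent partner in bond table: ",
             paste(utils::head(miss, 5), collapse = ", "))
      }
      hv <- heavy_of[as.character(hyd)]
    } else {
      if (is.null(frame)) {
        stop("topology has no bond table; supply a frame for distance-based attachment")
      }
      heavy <- which(topology$element %in% c("N", "O", "C", "S"))
      if (!length(heavy)) stop("no heavy atoms to attach hydrogens to")
      dm <- pair_distance_matrix(frame$coords[hyd, , drop = FALSE],
                                 frame$coords[heavy, , drop = FALSE], frame$box)
      nearest <- apply(dm, 1, which.min)
      dmin <- dm[cbind(seq_along(hyd), nearest)]
      orphan <- dmin > attach_cut
      if (any(orphan)) {
        stop("hydrogen atom(s) attributable to no heavy atom within ",
             attach_cut, " nm: atom index ",
             paste(utils::head(hyd[orphan], 5), collapse = ", "))
      }
      hv <- heavy[nearest]
    }
    keep <- is_no[hv]
    donors <- data.frame(donor = hv[keep], hydrogen = hyd[keep])
    donors <- donors[order(donors$donor, donors$hydrogen), , drop = FALSE]
    rownames(donors) <- NULL
  }
  list(donors = donors, acceptors = acceptors)
}

#' Detect hydrogen bonds in one frame
#'
#' Applies the geometric criteria to every (donor, hydrogen, acceptor)
#' combination, excluding intra-residue donor-acceptor pairs. When several
#' hydrogens of one donor satisfy the criteria toward the same acceptor,
#' only the best-angle hydrogen is reported (at most one event per (D, A)
#' pair).
#'
#' @param frame an `md_frame`.
#' @param topology matching `topology`.
#' @param da donor/acceptor sets from [find_donors_acceptors()].
#' @param criteria an [hbond_criteria()].
#' @return data.frame with one row per bond: `donor`, `hydrogen`,
#'   `acceptor` (atom indices), `donor_species`, `acceptor_species`,
#'   `donor_molecule`, `acceptor_molecule`, `distance_nm`, `angle_deg`,
#'   ordered by (donor, acceptor).
#' @export
detect_hbonds <- function(frame, topology, da, criteria = hbond_criteria()) {
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donor_species = character(0),
                      acceptor_species = character(0),
                      donor_molecule = integer(0), acceptor_molecule = integer(0),
                      distance_nm = numeric(0), angle_deg = numeric(0))
  if (nrow(da$donors) == 0L || length(da$acceptors) == 0L) return(empty)
  box <- frame$box
  D <- da$donors$donor; H <- da$donors$hydrogen; A <- da$acceptors
  dmat <- pair_distance_matrix(frame$coords[D, , drop = FALSE],
                               frame$coords[A, , drop = FALSE], box)
  # residue identity key to exclude intra-residue pairs
  reskey <- paste(topology$molecule_id, topology$residue_id)
  same_res <- outer(reskey[D], reskey[A], "==")
  cand <- which(dmat <= criteria$d_cut & !same_res & outer(D, A, "!="), arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  di <- cand[, 1]; ai <- cand[, 2]
  vH <- min_image_disp(frame$coords[H[di], , drop = FALSE],
                       frame$coords[D[di], , drop = FALSE], box)
  vA <- min_image_disp(frame$coords[A[ai], , drop = FALSE],
                       frame$coords[D[di], , drop = FALSE], box)
  cosang <- rowSums(vH * vA) / (sqrt(rowSums(vH * vH)) * sqrt(rowSums(vA * vA)))
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  ok <- ang <= criteria$angle_cut
  if (!any(ok)) return(empty)
  ev <- data.frame(donor = D[di][ok], hydrogen = H[di][ok], acceptor = A[ai][ok],
                   distance_nm = dmat[cand][ok], angle_deg = ang[ok])
  # best-angle hydrogen per (donor, acceptor)
  ev <- ev[order(ev$donor, ev$acceptor, ev$angle_deg), , drop = FALSE]
  ev <- ev[!duplicated(ev[, c("donor", "acceptor")]), , drop = FALSE]
  ev$donor_species <- topology$species[ev$donor]
  ev$acceptor_species <- topology$species[ev$acceptor]
  ev$donor_molecule <- topology$molecule_id[ev$donor]
  ev$acceptor_molecule <- topology$molecule_id[ev$acceptor]
  rownames(ev) <- NULL
  ev[, names(empty)]
}

# Map a species pair to its account label; protein = LYZ, polymer = PAA,
# water = W following the field's naming for this system.
species_pair_label <- function(s1, s2) {
  short <- c(PROTEIN = "LYZ", POLYMER = "PAA", WATER = "W", ION = "ION")
  a <- short[s1]; b <- short[s2]
  known <- c("LYZ-LYZ", "LYZ-W", "LYZ-PAA", "PAA-PAA", "PAA-W")
  lab <- ifelse(a <= b, paste(a, b, sep = "-"), paste(b, a, sep = "-"))
  ifelse(lab %in% known, lab, "other")
}

#' Count hydrogen bonds by species pair
#'
#' Buckets events into the unordered species pairs LYZ-LYZ, LYZ-W, LYZ-PAA,
#' PAA-PAA and PAA-W (anything else, e.g. water-water or ion-involving,
#' goes to `other`) and normalizes: pairs involving the protein by the
#' number of protein molecules, PAA-PAA and PAA-W by the number of polymer
#' chains, `other` by 1. By default protein-protein counts include bonds
#' within a single protein copy; `intermolecular_only = TRUE` restricts
#' every pair to bonds between distinct molecules.
#'
#' @param events event table from [detect_hbonds()] (possibly several frames
#'   concatenated).
#' @param topology the system topology (supplies molecule counts).
#' @param n_lyz,n_paa normalizers; default: number of distinct PROTEIN /
#'   POLYMER molecule ids in the topology.
#' @param intermolecular_only drop events whose donor and acceptor share a
#'   molecule id.
#' @return data.frame (pair, raw, normalizer, normalized) with one row per
#'   pair present.
#' @export
count_by_pair <- function(events, topology, n_lyz = NULL, n_paa = NULL,
                          intermolecular_only = FALSE) {
  n_lyz <- n_lyz %||% length(unique(topology$molecule_id[topology$species == "PROTEIN"]))
  n_paa <- n_paa %||% length(unique(topology$molecule_id[topology$species == "POLYMER"]))
  if (intermolecular_only && nrow(events)) {
    events <- events[events$donor_molecule != events$acceptor_molecule, , drop = FALSE]
  }
  if (nrow(events) == 0L) {
    return(data.frame(pair = character(0), raw = integer(0),
                      normalizer = numeric(0), normalized = numeric(0)))
  }
  lab <- species_pair_label(events$donor_species, events$acceptor_species)
  raw <- table(lab)
  pair <- names(raw)
  normalizer <- ifelse(grepl("LYZ", pair), n_lyz,
                       ifelse(grepl("PAA", pair), n_paa, 1))
  data.frame(pair = pair, raw = as.integer(raw), normalizer = normalizer,
             normalized = as.integer(raw) / normalizer, row.names = NULL)
}

#' Hydrogen-bond time series for one species pair
#'
#' Per-frame normalized counts for a species pair plus a block-averaged
#' standard error of the mean over the analysis window.
#'
#' @param traj `md_trajectory` with species assigned.
#' @param criteria [hbond_criteria()].
#' @param pair pair label, e.g. `"LYZ-PAA"`.
#' @param da optional precomputed [find_donors_acceptors()] result.
#' @param n_blocks number of blocks for the error estimate (default 5).
#' @param n_lyz,n_paa normalizers (defaults as in [count_by_pair()]).
#' @param intermolecular_only as in [count_by_pair()].
#' @return list of class `pair_count_series`: `pair`, `time_ps`, `raw`,
#'   `normalized`, `normalizer`, `mean`, `se` (block-averaged standard
#'   error), `n_blocks`.
#' @export
hbond_timeseries <- function(traj, criteria = hbond_criteria(), pair = "LYZ-PAA",
                             da = NULL, n_blocks = 5L, n_lyz = NULL, n_paa = NULL,
                             intermolecular_only = FALSE) {
  nf <- n_frames(traj)
  if (nf < n_blocks) {
    stop("trajectory has ", nf, " frames; block averaging needs at least ",
         n_blocks)
  }
  top <- traj$topology
  da <- da %||% find_donors_acceptors(top, traj$frames[[1]])
  n_lyz <- n_lyz %||% length(unique(top$molecule_id[top$species == "PROTEIN"]))
  n_paa <- n_paa %||% length(unique(top$molecule_id[top$species == "POLYMER"]))
  raw <- integer(nf)
  for (j in seq_len(nf)) {
    ev <- detect_hbonds(traj$frames[[j]], top, da, criteria)
    if (intermolecular_only && nrow(ev)) {
      ev <- ev[ev$donor_molecule != ev$acceptor_molecule, , drop = FALSE]
    }
    if (nrow(ev)) {
      lab <- species_pair_label(ev$donor_species, ev$acceptor_species)
      raw[j] <- sum(lab == pair)
    }
  }
  normalizer <- if (grepl("LYZ", pair)) n_lyz else if (grepl("PAA", pair)) n_paa else 1
  normalized <- raw / normalizer
  be <- block_error(normalized, n_blocks)
  structure(list(pair = pair,
                 time_ps = vapply(traj$frames, function(f) f$time, numeric(1)),
                 raw = raw, normalized = normalized, normalizer = normalizer,
                 mean = mean(normalized), se = be, n_blocks = n_blocks),
            class = "pair_count_series")
}

# Standard error of the mean from n_blocks equal (up to rounding) blocks.
block_error <- function(x, n_blocks = 5L) {
  n <- length(x)
  if (n < n_blocks) stop("series shorter than the number of blocks")
  grp <- cut(seq_len(n), n_blocks, labels = FALSE)
  bm <- vapply(split(x, grp), mean, numeric(1))
  if (length(bm) < 2L) return(0)
  s <- stats::sd(bm)
  if (is.na(s)) 0 else s / sqrt(length(bm))
}
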