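# Alpha-carbon contact kinetics and protein-polymer bridge detection.

#' Count protein-polymer contacts in one frame
#'
#' A contact is an alpha-carbon (or any atom of `ca_sel`) whose
#' minimum-image distance to the nearest polymer atom is within the cutoff
#' (default 0.6 nm). By default each Calpha counts once however many polymer
#' atoms are near; `multiplicity = "pair"` counts every (Calpha, polymer
#' atom) pair within the cutoff instead.
#'
#' @param frame an `md_frame`.
#' @param ca_sel atom indices of the protein alpha carbons.
#' @param polymer_sel atom indices of the polymer.
#' @param cutoff contact distance, nm (default 0.6).
#' @param multiplicity `"atom"` (default, per-Calpha) or `"pair"`.
#' @return integer contact count.
#' @export
count_contacts <- function(frame, ca_sel, polymer_sel, cutoff = 0.6,
                           multiplicity = c("atom", "pair")) {
  multiplicity <- match.arg(multiplicity)
  if (length(ca_sel) == 0L) stop("alpha-carbon selection is empty")
  if (length(polymer_sel) == 0L) stop("polymer selection is empty")
  if (cutoff <= 0) stop("cutoff must be positive")
  dm <- pair_distance_matrix(frame$coords[ca_sel, , drop = FALSE],
                             frame$coords[polymer_sel, , drop = FALSE],
                             frame$box)
  within <- dm <= cutoff
  if (multiplicity == "atom") sum(apply(within, 1, any)) else sum(within)
}

#' Contact time series with plateau estimate
#'
#' Per-frame contact counts normalized by the total number of protein and
#' polymer molecules (the sum, 24 for a 16-protein/8-chain system), plus a
#' plateau-time estimate from [plateau_time()].
#'
#' @param traj `md_trajectory` with species assigned.
#' @param ca_sel alpha-carbon selection; default atoms named `"CA"` of
#'   PROTEIN species.
#' @param polymer_sel polymer selection; default all POLYMER atoms.
#' @param cutoff contact cutoff, nm (default 0.6).
#' @param normalizer molecule-count normalizer; default n_protein +
#'   n_polymer molecules.
#' @param multiplicity as in [count_contacts()].
#' @param plateau_window fraction of the series used as the plateau
#'   reference window (default 1/3); NULL skips plateau estimation.
#' @return list of class `contact_series`: `time_ps`, `raw`, `normalized`,
#'   `normalizer`, `cutoff`, `plateau_time_ps` (numeric or NA when no
#'   plateau is reached).
#' @export
contact_timeseries <- function(traj, ca_sel = NULL, polymer_sel = NULL,
                               cutoff = 0.6, normalizer = NULL,
                               multiplicity = "atom", plateau_window = 1/3) {
  if (n_frames(traj) < 2L) stop("contact kinetics needs at least 2 frames")
  top <- traj$topology
  ca_sel <- ca_sel %||% select_atoms(top, species = "PROTEIN", name = "CA")
  polymer_sel <- polymer_sel %||% select_atoms(top, species = "POLYMER")
  if (is.null(normalizer)) {
    normalizer <- length(unique(top$molecule_id[top$species == "PROTEIN"])) +
      length(unique(top$molecule_id[top$species == "POLYMER"]))
  }
  raw <- vapply(traj$frames, count_contacts, integer(1), ca_sel = ca_sel,
                polymer_sel = polymer_sel, cutoff = cutoff,
                multiplicity = multiplicity)
  times <- vapply(traj$frames, function(f) f$time, numeric(1))
  pt <- NA_real_
  if (!is.null(plateau_window) && length(raw) >= 6L) {
    pt <- plateau_time(raw / normalizer, times, window = plateau_window)
  }
  structure(list(time_ps = times, raw = raw, normalized = raw / normalizer,
                 normalizer = normalizer, cutoff = cutoff,
                 plateau_time_ps = pt),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("contact_series: %d frames, mean %.3f contacts/molecule, plateau at %s\n",
              length(x$raw), mean(x$normalized),
              if (is.na(x$plateau_time_ps)) "none" else
                sprintf("%g ps", x$plateau_time_ps)))
  invisible(x)
}

#' Plateau time of a series
#'
#' The reference level is the mean of the final `window` fraction of the
#' series, with a tolerance band of one standard deviation of that window.
#' The plateau time is the earliest time t such that every running mean of
#' the series started at t stays within the band; a plateau must begin no
#' later than the reference window itself, otherwise `NA` ("none") is
#' returned -- a series still rising into the reference window has not
#' plateaued.
#'
#' @param x numeric series (normalized contact counts or similar).
#' @param times frame times, ps (default frame index).
#' @param window fraction of the series forming the reference window,
#'   in (0, 1); default 1/3.
#' @return plateau time in ps, or `NA_real_` when no plateau is reached.
#' @export
plateau_time <- function(x, times = seq_along(x) - 1, window = 1/3) {
  n <- length(x)
  if (n < 6L) stop("plateau estimation needs at least 6 frames")
  if (window <= 0 || window >= 1) stop("window must lie in (0, 1)")
  w0 <- n - max(2L, ceiling(window * n)) + 1L
  ref <- mean(x[w0:n])
  band <- stats::sd(x[w0:n])
  for (t0 in seq_len(w0)) {
    rm_ok <- TRUE
    s <- 0
    for (t1 in t0:n) {
      s <- s + x[t1]
      if (abs(s / (t1 - t0 + 1) - ref) > band + 1e-12) { rm_ok <- FALSE; break }
    }
    if (rm_ok) return(times[t0])
  }
  NA_real_
}

#' Detect protein-polymer bridges in one frame
#'
#' A polymer chain bridges the proteins it is simultaneously linked to; a
#' bridge is recorded for every chain linked to two or more distinct
#' protein molecules. Links are either any-atom proximity within `cutoff`
#' (default 0.35 nm, `mode = "distance"`) or protein-polymer hydrogen bonds
#' (`mode = "hbond"`, using [detect_hbonds()]).
#'
#' @param frame an `md_frame`.
#' @param topology matching `topology` with species assigned.
#' @param mode `"distance"` or `"hbond"`.
#' @param cutoff link distance for distance mode, nm.
#' @param criteria [hbond_criteria()] for hbond mode.
#' @param da optional donor/acceptor sets for hbond mode.
#' @return data.frame with one row per bridging chain: `chain`
#'   (molecule_id), `n_proteins`, `proteins` (comma-separated molecule ids,
#'   ascending), `link_type`.
#' @export
detect_bridges <- function(frame, topology, mode = c("distance", "hbond"),
                           cutoff = 0.35, criteria = hbond_criteria(),
                           da = NULL) {
  mode <- match.arg(mode)
  empty <- data.frame(chain = integer(0), n_proteins = integer(0),
                      proteins = character(0), link_type = character(0))
  chains <- sort(unique(topology$molecule_id[topology$species == "POLYMER"]))
  if (length(chains) == 0L) return(empty)
  links <- NULL  # data.frame(chain, protein)
  if (mode == "distance") {
    prot_sel <- select_atoms(topology, species = "PROTEIN")
    poly_sel <- select_atoms(topology, species = "POLYMER")
    if (!length(prot_sel)) return(empty)
    dm <- pair_distance_matrix(frame$coords[poly_sel, , drop = FALSE],
                               frame$coords[prot_sel, , drop = FALSE],
                               frame$box)
    hit <- which(dm <= cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      links <- unique(data.frame(
        chain = topology$molecule_id[poly_sel][hit[, 1]],
        protein = topology$molecule_id[prot_sel][hit[, 2]]))
    }
  } else {
    da <- da %||% find_donors_acceptors(topology, frame)
    ev <- detect_hbonds(frame, topology, da, criteria)
    pp <- ev[(ev$donor_species == "PROTEIN" & ev$acceptor_species == "POLYMER") |
               (ev$donor_species == "POLYMER" & ev$acceptor_species == "PROTEIN"), ,
             drop = FALSE]
    if (nrow(pp)) {
      chain <- ifelse(pp$donor_species == "POLYMER", pp$donor_molecule,
                      pp$acceptor_molecule)
      protein <- ifelse(pp$donor_species == "PROTEIN", pp$donor_molecule,
                        pp$acceptor_molecule)
      links <- unique(data.frame(chain = chain, protein = protein))
    }
  }
  if (is.null(links) || nrow(links) == 0L) return(empty)
  out <- do.call(rbind, lapply(split(links$protein, links$chain), function(p) {
    p <- sort(unique(p))
    data.frame(n_proteins = length(p), proteins = paste(p, collapse = ","))
  }))
  out$chain <- as.integer(rownames(out))
  out <- out[out$n_proteins >= 2L, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out$link_type <- mode
  out <- out[order(out$chain), c("chain", "n_proteins", "proteins", "link_type")]
  rownames(out) <- NULL
  out
}
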