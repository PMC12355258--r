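# Residue-level association-rate statistic.
#
# For every protein copy c, residue i, analysis frame j and polymer chain k,
# d[c,i,j,k] is the minimum-image distance between the closest (residue
# atom, chain atom) pair. The per-frame chain minimum
#     d_min[c,i,j] = min_k d[c,i,j,k]
# is averaged over the m analysis frames to a copy-specific mean d_bar[c,i];
# a copy counts as associated at residue i when d_bar[c,i] <= threshold
# (default 0.35 nm, the hydrogen-bond distance criterion), and the
# association rate AR(i) is the percentage of copies associated there.

#' Per-residue, per-chain minimum distances
#'
#' Builds the residue distance table underlying the association-rate
#' statistic: for every (protein copy, residue, frame, chain) the minimum
#' minimum-image distance between any atom of that residue and any atom of
#' that chain, plus its minimum over chains.
#'
#' @param traj an `md_trajectory` with species assigned.
#' @param frames integer indices of the analysis frames (default: all).
#'   See [analysis_frames()] for the last-window helper.
#' @param protein_sel,polymer_sel atom index vectors; default all PROTEIN /
#'   all POLYMER atoms. A restricted selection (e.g. heavy atoms only) is
#'   honoured as-is.
#' @return object of class `residue_distance_table`: list with
#'   `d` (4-d array copy x residue x frame x chain),
#'   `d_min` (3-d array copy x residue x frame), `copies`, `residues`,
#'   `chains` (id vectors), `frame_index`, `times`, and counts
#'   `n_copies`, `n_residues`, `n_chains`, `m`.
#' @export
residue_chain_distances <- function(traj, frames = NULL, protein_sel = NULL,
                                    polymer_sel = NULL) {
  top <- traj$topology
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  frames <- as.integer(frames)
  if (length(frames) == 0L) stop("no analysis frames selected")
  if (any(frames < 1L | frames > n_frames(traj))) {
    stop("frame index out of range (1..", n_frames(traj), ")")
  }
  protein_sel <- protein_sel %||% select_atoms(top, species = "PROTEIN")
  polymer_sel <- polymer_sel %||% select_atoms(top, species = "POLYMER")
  if (length(protein_sel) == 0L) stop("protein selection is empty")
  if (length(polymer_sel) == 0L) stop("polymer selection is empty")

  copies <- sort(unique(top$molecule_id[protein_sel]))
  chains <- sort(unique(top$molecule_id[polymer_sel]))
  residues <- sort(unique(top$residue_id[protein_sel]))
  nc <- length(copies); nr <- length(residues); nk <- length(chains)
  m <- length(frames)

  # group index per protein atom: (copy, residue) cell in column-major order
  grp <- match(top$molecule_id[protein_sel], copies) +
    nc * (match(top$residue_id[protein_sel], residues) - 1L)
  chain_of <- match(top$molecule_id[polymer_sel], chains)

  d <- array(NA_real_, dim = c(nc, nr, m, nk))
  for (jj in seq_len(m)) {
    f <- traj$frames[[frames[jj]]]
    dm <- pair_distance_matrix(f$coords[protein_sel, , drop = FALSE],
                               f$coords[polymer_sel, , drop = FALSE], f$box)
    for (k in seq_len(nk)) {
      # per protein atom: nearest atom of chain k, then min within each
      # (copy, residue) atom group
      per_atom <- do.call(pmin, as.data.frame(dm[, chain_of == k, drop = FALSE]))
      cell_min <- vapply(split(per_atom, grp), min, numeric(1))
      slab <- rep(NA_real_, nc * nr)
      slab[as.integer(names(cell_min))] <- cell_min
      d[, , jj, k] <- slab
    }
  }
  if (anyNA(d)) {
    stop("some (copy, residue) cells contain no protein atoms under the selection")
  }
  d_min <- apply(d, c(1, 2, 3), min)
  structure(list(d = d, d_min = d_min, copies = copies, residues = residues,
                 chains = chains, frame_index = frames,
                 times = vapply(traj$frames[frames], function(f) f$time, numeric(1)),
                 n_copies = nc, n_residues = nr, n_chains = nk, m = m),
            class = "residue_distance_table")
}

#' @export
print.residue_distance_table <- function(x, ...) {
  cat(sprintf("residue_distance_table: %d copies x %d residues x %d frames x %d chains\n",
              x$n_copies, x$n_residues, x$m, x$n_chains))
  invisible(x)
}

#' Pick analysis frames from the tail of a trajectory
#'
#' Selects `m` approximately evenly strided frames from the final
#' `window_ps` picoseconds of the trajectory (the "uncorrelated frames after
#' equilibrium" convention): the last window is identified by time, then m
#' frames are taken at the largest stride that fits, ending at the final
#' frame.
#'
#' @param traj an `md_trajectory`.
#' @param m number of frames to keep (default 10).
#' @param window_ps length of the trailing time window; default the whole
#'   trajectory.
#' @return integer frame indices, length `min(m, frames in window)`.
#' @export
analysis_frames <- function(traj, m = 10L, window_ps = NULL) {
  times <- vapply(traj$frames, function(f) f$time, numeric(1))
  nf <- length(times)
  in_win <- if (is.null(window_ps)) seq_len(nf) else {
    which(times >= times[nf] - window_ps)
  }
  if (length(in_win) <= m) return(in_win)
  stride <- (length(in_win) - 1L) %/% (m - 1L)
  idx <- in_win[length(in_win)] - stride * ((m - 1L):0L)
  as.integer(idx)
}

#' Time-averaged residue distances per copy
#'
#' @param table a `residue_distance_table`.
#' @return matrix (copy x residue) of mean minimum distances d_bar (nm),
#'   dimnames carrying copy and residue ids.
#' @export
mean_residue_distance <- function(table) {
  stopifnot(inherits(table, "residue_distance_table"))
  d_bar <- apply(table$d_min, c(1, 2), mean)
  dimnames(d_bar) <- list(copy = as.character(table$copies),
                          residue = as.character(table$residues))
  d_bar
}

#' Association indicator per (copy, residue)
#'
#' A copy is associated at a residue when its time-averaged minimum distance
#' to any polymer chain is within the threshold (boundary inclusive). The
#' source publication's printed indicator has its inequality directions
#' swapped relative to its stated purpose; this implementation follows the
#' stated purpose: indicator = 1 iff d_bar <= threshold.
#'
#' @param d_bar copy x residue matrix from [mean_residue_distance()].
#' @param threshold association distance threshold in nm (default 0.35, the
#'   hydrogen-bond distance criterion).
#' @return integer 0/1 matrix of the same shape.
#' @export
association_indicator <- function(d_bar, threshold = 0.35) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a positive length in nm")
  }
  ind <- (d_bar <= threshold) + 0L
  storage.mode(ind) <- "integer"
  ind
}

#' Association rate per residue
#'
#' @param indicator 0/1 copy x residue matrix from [association_indicator()].
#' @param n_copies number of protein copies; default `nrow(indicator)`.
#'   Every copy must be present (one row each).
#' @return named numeric vector AR(%) in [0, 100] per residue.
#' @export
association_rate <- function(indicator, n_copies = nrow(indicator)) {
  if (nrow(indicator) != n_copies) {
    stop(sprintf("indicator has %d copies but n_copies = %d; every copy must be present",
                 nrow(indicator), n_copies))
  }
  if (anyNA(indicator)) stop("indicator contains missing (copy, residue) entries")
  100 * colSums(indicator) / n_copies
}

#' Convenience wrapper: association rates from a trajectory
#'
#' Runs [residue_chain_distances()], [mean_residue_distance()],
#' [association_indicator()] and [association_rate()] in one call.
#'
#' @inheritParams residue_chain_distances
#' @inheritParams association_indicator
#' @return list of class `association_result` with `table`, `d_bar`,
#'   `indicator`, `ar` (named % vector), `threshold`.
#' @export
association_analysis <- function(traj, frames = NULL, threshold = 0.35,
                                 protein_sel = NULL, polymer_sel = NULL) {
  table <- residue_chain_distances(traj, frames, protein_sel, polymer_sel)
  d_bar <- mean_residue_distance(table)
  ind <- association_indicator(d_bar, threshold)
  structure(list(table = table, d_bar = d_bar, indicator = ind,
                 ar = association_rate(ind), threshold = threshold),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result: %d residues, %d copies, threshold %.3g nm\n",
              length(x$ar), nrow(x$indicator), x$threshold))
  top <- utils::head(sort(x$ar, decreasing = TRUE), 5)
  cat("  top residues (AR%):",
      paste(sprintf("%s=%.1f", names(top), top), collapse = " "), "\n")
  invisible(x)
}

#' Top-k residues by association rate
#'
#' @param ar named AR(%) vector (names = residue ids).
#' @param k number of residues to report (default 10).
#' @return data.frame (residue_id, ar_percent) sorted by descending AR,
#'   ties broken by ascending residue id.
#' @export
top_residues <- function(ar, k = 10L) {
  ids <- as.integer(names(ar))
  if (anyNA(ids)) ids <- seq_along(ar)
  k <- min(k, length(ar))
  ord <- order(-ar, ids)
  data.frame(residue_id = ids[ord[seq_len(k)]],
             ar_percent = unname(ar[ord[seq_len(k)]]))
}

#' Time-wise and copy-wise variability of a residue's polymer distance
#'
#' Decomposes the d_min values of one residue into a per-frame table (mean
#' and sd across copies at each frame: time-dependent variability) and a
#' per-copy table (mean and sd across frames for each copy: environmental
#' variability). The two grand means coincide by exchange of summation
#' order.
#'
#' @param table a `residue_distance_table`.
#' @param residue residue id.
#' @return list with data.frames `per_frame` (frame, time_ps, mean_nm,
#'   sd_nm), `per_copy` (copy, mean_nm, sd_nm), and `grand_mean_nm`.
#' @export
variability_report <- function(table, residue) {
  ri <- match(residue, table$residues)
  if (is.na(ri)) stop("residue ", residue, " not present in the distance table")
  dmat <- table$d_min[, ri, , drop = TRUE]          # copies x frames
  dmat <- matrix(dmat, nrow = table$n_copies)
  per_frame <- data.frame(
    frame = table$frame_index, time_ps = table$times,
    mean_nm = colMeans(dmat),
    sd_nm = apply(dmat, 2, stats::sd))
  per_copy <- data.frame(
    copy = table$copies,
    mean_nm = rowMeans(dmat),
    sd_nm = apply(dmat, 1, stats::sd))
  per_frame$sd_nm[is.na(per_frame$sd_nm)] <- 0
  per_copy$sd_nm[is.na(per_copy$sd_nm)] <- 0
  list(per_frame = per_frame, per_copy = per_copy, grand_mean_nm = mean(dmat))
}
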