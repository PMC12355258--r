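# Per-copy structural metrics: Kabsch superposition, RMSD, RMSF, radius of
# gyration, and cross-copy aggregation.

#' Least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the unweighted sum
#' of squared deviations of `mobile` onto `reference` over the fit atoms,
#' via SVD of the covariance matrix with the usual sign correction so the
#' rotation determinant is +1 (no reflections).
#'
#' @param mobile,reference N x 3 coordinate matrices, nm.
#' @param fit_sel row indices used for the fit (default: all rows).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `coords` (all mobile rows transformed), `rmsd` (over the fit atoms,
#'   nm).
#' @export
superpose <- function(mobile, reference, fit_sel = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  fit_sel <- fit_sel %||% seq_len(nrow(mobile))
  if (length(fit_sel) < 3L) stop("superposition needs at least 3 fit atoms")
  M <- mobile[fit_sel, , drop = FALSE]
  R0 <- reference[fit_sel, , drop = FALSE]
  if (nrow(M) != nrow(R0)) stop("fit selections of unequal size")
  cm <- colMeans(M); cr <- colMeans(R0)
  Mc <- sweep(M, 2, cm); Rc <- sweep(R0, 2, cr)
  H <- crossprod(Mc, Rc)
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2L) {
    stop("degenerate (collinear) fit set: superposition is ill-defined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)
  fitted_fit <- Mc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted_fit - Rc)^2)))
  coords <- sweep(sweep(mobile, 2, cm) %*% t(rot), 2, cr, "+")
  list(rotation = rot, translation = as.numeric(cr - cm %*% t(rot)),
       coords = coords, rmsd = rmsd)
}

#' RMSD of coordinates against a reference
#'
#' @param mobile,reference N x 3 matrices, nm.
#' @param fit superpose before measuring (default TRUE); FALSE gives the
#'   raw (pre-fit) RMSD.
#' @return RMSD in nm.
#' @export
rmsd_value <- function(mobile, reference, fit = TRUE) {
  if (fit) return(superpose(mobile, reference)$rmsd)
  sqrt(mean(rowSums((as.matrix(mobile) - as.matrix(reference))^2)))
}

#' Per-frame RMSD series for one protein copy
#'
#' Superposes the copy's selected atoms (alpha carbons by default) onto the
#' reference frame for every trajectory frame and reports the residual RMSD.
#'
#' @param traj an `md_trajectory`.
#' @param copy molecule id of the protein copy.
#' @param sel atom indices used for fit and measurement; default atoms named
#'   `"CA"` of that copy.
#' @param reference reference `md_frame` (default: first trajectory frame).
#' @param fit superpose first (default TRUE).
#' @return numeric vector, one RMSD (nm) per frame.
#' @export
rmsd_series <- function(traj, copy, sel = NULL, reference = NULL, fit = TRUE) {
  top <- traj$topology
  sel <- sel %||% select_atoms(top, molecule_id = copy, name = "CA")
  if (length(sel) == 0L) {
    stop("no atoms selected for copy ", copy,
         " (no 'CA' atom names?); pass `sel` explicitly")
  }
  reference <- reference %||% traj$frames[[1]]
  # unwrap both against the box so a periodically split copy fits cleanly
  ref <- unwrap_coords(reference$coords[sel, , drop = FALSE], reference$box)
  vapply(traj$frames, function(f) {
    rmsd_value(unwrap_coords(f$coords[sel, , drop = FALSE], f$box), ref, fit = fit)
  }, numeric(1))
}

#' Per-residue RMSF for one protein copy
#'
#' Root-mean-square fluctuation of each selected atom about its
#' window-mean position after superposing every frame onto the first
#' (removing global rigid motion), aggregated per residue by averaging the
#' RMSF of the residue's selected (backbone) atoms.
#'
#' @param traj an `md_trajectory`.
#' @param copy molecule id of the protein copy.
#' @param sel atom indices; default backbone atoms (names N, CA, C, O) of
#'   the copy, falling back to all atoms of the copy when none match.
#' @param window frame indices to analyze (default all; at least 2).
#' @param fit superpose each frame onto the first before measuring
#'   (default TRUE).
#' @return data.frame (residue_id, rmsf_nm), one row per residue.
#' @export
rmsf <- function(traj, copy, sel = NULL, window = NULL, fit = TRUE) {
  top <- traj$topology
  if (is.null(sel)) {
    sel <- select_atoms(top, molecule_id = copy, name = c("N", "CA", "C", "O"))
    if (length(sel) == 0L) sel <- select_atoms(top, molecule_id = copy)
  }
  window <- window %||% seq_len(n_frames(traj))
  if (length(window) < 2L) stop("RMSF needs a window of at least 2 frames")
  f1 <- traj$frames[[window[1]]]
  ref <- unwrap_coords(f1$coords[sel, , drop = FALSE], f1$box)
  stack <- array(NA_real_, dim = c(length(sel), 3, length(window)))
  for (w in seq_along(window)) {
    f <- traj$frames[[window[w]]]
    co <- unwrap_coords(f$coords[sel, , drop = FALSE], f$box)
    if (fit) co <- superpose(co, ref)$coords
    stack[, , w] <- co
  }
  mean_pos <- apply(stack, c(1, 2), mean)
  dev2 <- sweep(stack, c(1, 2), mean_pos)^2
  atom_rmsf <- sqrt(apply(dev2, 1, mean) * 3)  # mean over (dim, frame) x 3
  res <- top$residue_id[sel]
  agg <- vapply(split(atom_rmsf, res), mean, numeric(1))
  data.frame(residue_id = as.integer(names(agg)), rmsf_nm = unname(agg))
}

#' Radius of gyration of one molecule in one frame
#'
#' Mass-weighted by default: Rg = sqrt( sum_i m_i |r_i - r_com|^2 / sum m_i ).
#' The molecule is made whole across the periodic boundary first; a
#' molecule still spanning more than half the box after unwrapping is an
#' error.
#'
#' @param frame an `md_frame`.
#' @param topology matching `topology`.
#' @param sel atom indices of the molecule (e.g. one protein copy).
#' @param mass_weighted default TRUE; FALSE weights every atom equally.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(frame, topology, sel, mass_weighted = TRUE) {
  if (length(sel) == 0L) stop("empty selection has no radius of gyration")
  co <- unwrap_coords(frame$coords[sel, , drop = FALSE], frame$box)
  ext <- apply(co, 2, function(v) diff(range(v)))
  if (any(ext > frame$box / 2)) {
    stop("molecule spans more than half the box after unwrapping; ",
         "cannot compute a radius of gyration")
  }
  m <- if (mass_weighted) topology$mass[sel] else rep(1, length(sel))
  com <- colSums(co * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(co, 2, com)^2)) / sum(m))
}

#' Cross-copy aggregation of a per-copy metric
#'
#' Averages each copy's metric over the analysis window, then reports the
#' mean and standard deviation across copies -- the convention for
#' reporting one representative value per condition from n independent
#' protein copies.
#'
#' @param per_copy named list (one element per copy) of numeric vectors
#'   (per-frame or per-residue values), or a numeric vector of one value
#'   per copy.
#' @param window indices of each vector to average over (default all).
#' @return list with `per_copy_mean` (named numeric), `mean`, `sd`,
#'   `n_copies`.
#' @export
aggregate_copies <- function(per_copy, window = NULL) {
  if (is.numeric(per_copy) && is.null(dim(per_copy))) {
    per_copy <- as.list(per_copy)
  }
  if (length(per_copy) == 0L) stop("no copies supplied")
  pcm <- vapply(per_copy, function(v) {
    v <- as.numeric(v)
    idx <- window %||% seq_along(v)
    if (any(idx > length(v))) stop("window exceeds metric length for a copy")
    mean(v[idx])
  }, numeric(1))
  list(per_copy_mean = pcm, mean = mean(pcm),
       sd = if (length(pcm) > 1L) stats::sd(pcm) else 0,
       n_copies = length(pcm))
}

#' Full structural-metric summary over all protein copies
#'
#' Computes per-copy RMSD (alpha carbons), Rg and optionally RMSF, and the
#' cross-copy mean +/- sd of each over the analysis window.
#'
#' @param traj an `md_trajectory` with species assigned.
#' @param window frame indices to aggregate over (default all).
#' @param reference reference frame for RMSD (default first frame).
#' @param include_rmsf also compute per-residue RMSF per copy
#'   (default TRUE).
#' @return list of class `structure_metrics`: `rmsd` (copy x frame matrix),
#'   `rg` (copy x frame matrix), `rmsf` (list of per-copy data.frames or
#'   NULL), `summary` (data.frame metric, mean, sd, n_copies).
#' @export
structure_metrics <- function(traj, window = NULL, reference = NULL,
                              include_rmsf = TRUE) {
  top <- traj$topology
  copies <- sort(unique(top$molecule_id[top$species == "PROTEIN"]))
  if (!length(copies)) stop("no PROTEIN molecules in topology")
  window <- window %||% seq_len(n_frames(traj))
  nf <- n_frames(traj)
  rmsd_mat <- matrix(NA_real_, length(copies), nf,
                     dimnames = list(copy = copies, NULL))
  rg_mat <- rmsd_mat
  rmsf_list <- if (include_rmsf) stats::setNames(vector("list", length(copies)),
                                                 copies) else NULL
  for (ci in seq_along(copies)) {
    cp <- copies[ci]
    rmsd_mat[ci, ] <- rmsd_series(traj, cp, reference = reference)
    all_sel <- select_atoms(top, molecule_id = cp)
    rg_mat[ci, ] <- vapply(traj$frames, radius_of_gyration, numeric(1),
                           topology = top, sel = all_sel)
    if (include_rmsf) rmsf_list[[ci]] <- rmsf(traj, cp, window = window)
  }
  ag_rmsd <- aggregate_copies(asplit(rmsd_mat, 1), window)
  ag_rg <- aggregate_copies(asplit(rg_mat, 1), window)
  summ <- data.frame(metric = c("rmsd_nm", "rg_nm"),
                     mean = c(ag_rmsd$mean, ag_rg$mean),
                     sd = c(ag_rmsd$sd, ag_rg$sd),
                     n_copies = length(copies))
  if (include_rmsf) {
    rmsf_means <- vapply(rmsf_list, function(d) mean(d$rmsf_nm), numeric(1))
    ag_rmsf <- aggregate_copies(rmsf_means)
    summ <- rbind(summ, data.frame(metric = "rmsf_nm", mean = ag_rmsf$mean,
                                   sd = ag_rmsf$sd, n_copies = length(copies)))
  }
  structure(list(rmsd = rmsd_mat, rg = rg_mat, rmsf = rmsf_list,
                 summary = summ, window = window),
            class = "structure_metrics")
}

#' @export
print.structure_metrics <- function(x, ...) {
  cat("structure_metrics over", ncol(x$rmsd), "frames,",
      nrow(x$rmsd), "copies\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
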