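# Radial distribution functions under orthorhombic periodic boundaries.

#' Center of mass of a molecule selection
#'
#' Mass-weighted mean position after making the molecule whole across the
#' periodic boundary (every atom is moved to the periodic image nearest the
#' first atom), then re-wrapped into the primary box.
#'
#' @param frame an `md_frame`.
#' @param topology matching `topology` (supplies masses).
#' @param sel atom indices of one molecule.
#' @return length-3 numeric position, nm.
#' @export
center_of_mass <- function(frame, topology, sel) {
  if (length(sel) == 0L) stop("empty selection has no center of mass")
  co <- unwrap_coords(frame$coords[sel, , drop = FALSE], frame$box)
  ext <- apply(co, 2, function(v) diff(range(v)))
  if (any(ext > frame$box / 2)) {
    warning("molecule spans more than half the box after unwrapping; ",
            "center of mass may be ill-defined")
  }
  m <- topology$mass[sel]
  com <- colSums(co * m) / sum(m)
  com %% frame$box
}

#' Radial distribution function
#'
#' Computes g(r) between two selections, either site-site (every atom of A
#' against every atom of B) or com-com (one point per molecule of each
#' selection). Distances use the minimum-image convention; the histogram is
#' normalized per frame by N_A x rho_B x shell volume with rho_B computed
#' from that frame's box volume (self pairs are excluded and rho_B uses
#' N_B - 1 when the two selections are identical), then averaged over
#' frames.
#'
#' @param traj an `md_trajectory`.
#' @param sel_A,sel_B atom index vectors.
#' @param mode `"site"` (default) or `"com"`.
#' @param r_max histogram range, nm; must not exceed half the smallest box
#'   edge (default: half the smallest edge of the first frame, capped at
#'   4 nm).
#' @param bin_width bin width, nm (default 0.02).
#' @param frames frame indices to average over (default all).
#' @return list of class `rdf_result`: `r` (bin centers, nm), `g`,
#'   `bin_edges`, `mode`, `n_frames`, `reference_density` (mean rho_B,
#'   nm^-3), `pair_count` (mean number of A-B pairs with r <= r_max),
#'   `n_A`.
#' @export
rdf <- function(traj, sel_A, sel_B, mode = c("site", "com"), r_max = NULL,
                bin_width = 0.02, frames = NULL) {
  mode <- match.arg(mode)
  if (bin_width <= 0) stop("bin_width must be positive")
  if (length(sel_A) == 0L || length(sel_B) == 0L) stop("empty RDF selection")
  frames <- frames %||% seq_len(n_frames(traj))
  top <- traj$topology
  box1 <- traj$frames[[frames[1]]]$box
  if (is.null(r_max)) r_max <- min(min(box1) / 2, 4)
  if (r_max > min(box1) / 2 + 1e-9) {
    stop(sprintf("r_max = %g nm exceeds half the smallest box edge (%g nm)",
                 r_max, min(box1) / 2))
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  identical_sel <- identical(sort(sel_A), sort(sel_B))

  acc <- numeric(nb)
  rho_acc <- 0
  pair_acc <- 0
  for (fi in frames) {
    f <- traj$frames[[fi]]
    if (mode == "com") {
      A <- com_points(f, top, sel_A)
      B <- if (identical_sel) A else com_points(f, top, sel_B)
    } else {
      A <- f$coords[sel_A, , drop = FALSE]
      B <- if (identical_sel) A else f$coords[sel_B, , drop = FALSE]
    }
    dm <- pair_distance_matrix(A, B, f$box)
    if (identical_sel) diag(dm) <- Inf
    dd <- dm[dm <= r_max]
    h <- graphics::hist(dd, breaks = edges, plot = FALSE)$counts
    vol <- prod(f$box)
    nB <- nrow(B) - if (identical_sel) 1L else 0L
    rho <- nB / vol
    shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
    acc <- acc + h / (nrow(A) * rho * shell)
    rho_acc <- rho_acc + rho
    pair_acc <- pair_acc + length(dd)
  }
  nfr <- length(frames)
  structure(list(r = (edges[-1] + edges[-length(edges)]) / 2,
                 g = acc / nfr, bin_edges = edges, mode = mode,
                 n_frames = nfr, reference_density = rho_acc / nfr,
                 pair_count = pair_acc / nfr,
                 n_A = if (mode == "com") NA_integer_ else length(sel_A)),
            class = "rdf_result")
}

# One COM point per molecule id present in the selection.
com_points <- function(frame, topology, sel) {
  mols <- unique(topology$molecule_id[sel])
  t(vapply(mols, function(m) {
    center_of_mass(frame, topology, sel[topology$molecule_id[sel] == m])
  }, numeric(3)))
}

#' @export
print.rdf_result <- function(x, ...) {
  pk <- which.max(x$g)
  cat(sprintf("rdf_result (%s-%s): %d bins to %.3g nm, %d frames, peak g = %.3g at r = %.3g nm\n",
              x$mode, x$mode, length(x$g), max(x$bin_edges), x$n_frames,
              x$g[pk], x$r[pk]))
  invisible(x)
}
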