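# Superposition, RMSD, RMSF, radius of gyration, and cross-copy
# aggregation.

rot_z <- function(th) rbind(c(cos(th), -sin(th), 0),
                            c(sin(th), cos(th), 0), c(0, 0, 1))

test_that("superposition recovers rigid motions with zero residual", {
  set.seed(5)
  ref <- matrix(rnorm(30), ncol = 3)
  mob <- ref %*% t(rot_z(pi / 2)) + rep(c(1, 2, 3), each = 10)
  fit <- superpose(mob, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(fit$coords, ref, tolerance = 1e-10)
  # identity case
  fit2 <- superpose(ref, ref)
  expect_equal(fit2$rotation, diag(3), tolerance = 1e-10)
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  collinear <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(collinear, collinear + 1), "degenerate|collinear")
})

test_that("fitted RMSD never exceeds the pre-fit RMSD and matches bio3d", {
  set.seed(6)
  for (i in 1:10) {
    ref <- matrix(rnorm(60), ncol = 3)
    mob <- ref + matrix(rnorm(60, sd = 0.3), ncol = 3)
    pre <- rmsd_value(mob, ref, fit = FALSE)
    post <- rmsd_value(mob, ref, fit = TRUE)
    expect_lte(post, pre + 1e-12)
  }
  skip_if_not_installed("bio3d")
  set.seed(7)
  ref <- matrix(rnorm(45), ncol = 3)
  mob <- ref %*% t(rot_z(0.8)) + matrix(rnorm(45, sd = 0.1), ncol = 3) + 2
  ours <- rmsd_value(mob, ref, fit = TRUE)
  theirs <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(mob)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 5e-3)  # bio3d rounds to 3 digits
})

test_that("rmsd_series is zero along a pure rigid-motion trajectory", {
  spec <- synthetic_spec(n_proteins = 2, n_residues = 20, n_chains = 1,
                         chain_length = 4)
  gen <- generate_planted(spec, plant_manifest(), n_frames = 1)
  top <- gen$trajectory$topology
  f0 <- gen$trajectory$frames[[1]]
  frames <- lapply(0:4, function(j) {
    co <- f0$coords %*% t(rot_z(0.3 * j)) + j * 0.5
    new_frame(co %% rep(f0$box, each = nrow(co)), f0$box, time = j)
  })
  traj <- new_trajectory(top, frames)
  for (cp in 1:2) {
    s <- rmsd_series(traj, cp, sel = select_atoms(top, molecule_id = cp))
    expect_equal(s, rep(0, 5), tolerance = 1e-9)
  }
})

test_that("Gaussian jitter gives pre-fit RMSD near sigma * sqrt(3)", {
  set.seed(8)
  sigma <- 0.05
  n <- 1000
  ref <- matrix(rnorm(3 * n), ncol = 3)
  mob <- ref + matrix(rnorm(3 * n, sd = sigma), ncol = 3)
  pre <- rmsd_value(mob, ref, fit = FALSE)
  expect_equal(pre, sigma * sqrt(3), tolerance = 0.05)
})

test_that("RMSF: zero for static, localized for one jittered residue, ~sigma*sqrt(3)", {
  spec <- synthetic_spec(n_proteins = 1, n_residues = 10, n_chains = 1,
                         chain_length = 4)
  gen <- generate_planted(spec, plant_manifest(), n_frames = 1)
  top <- gen$trajectory$topology
  f0 <- gen$trajectory$frames[[1]]
  static <- new_trajectory(top, lapply(0:4, function(j)
    new_frame(f0$coords, f0$box, time = j)))
  r0 <- rmsf(static, 1, sel = select_atoms(top, molecule_id = 1))
  expect_true(all(r0$rmsf_nm < 1e-12))
  # jitter only residue 4 (fit disabled so motion stays local to the residue)
  set.seed(9)
  sel4 <- select_atoms(top, molecule_id = 1, residue_id = 4)
  jit <- new_trajectory(top, lapply(0:9, function(j) {
    co <- f0$coords
    co[sel4, ] <- co[sel4, ] + rnorm(3, sd = 0.02)
    new_frame(co, f0$box, time = j)
  }))
  r1 <- rmsf(jit, 1, sel = select_atoms(top, molecule_id = 1), fit = FALSE)
  expect_gt(r1$rmsf_nm[r1$residue_id == 4], 0.005)
  expect_true(all(r1$rmsf_nm[r1$residue_id != 4] < 1e-12))
  # isotropic jitter on all atoms: per-residue RMSF ~ sigma * sqrt(3)
  set.seed(10)
  sigma <- 0.05
  all1 <- select_atoms(top, molecule_id = 1)
  big <- new_trajectory(top, lapply(0:999, function(j) {
    co <- f0$coords
    co[all1, ] <- co[all1, ] + matrix(rnorm(3 * length(all1), sd = sigma),
                                      ncol = 3)
    new_frame(co, f0$box, time = j)
  }))
  r2 <- rmsf(big, 1, sel = all1, fit = FALSE)
  expect_equal(mean(r2$rmsf_nm), sigma * sqrt(3), tolerance = 0.05)
})

test_that("RMSF of fit atoms is unchanged by per-frame global rigid motion", {
  spec <- synthetic_spec(n_proteins = 1, n_residues = 12, n_chains = 1,
                         chain_length = 4)
  gen <- generate_planted(spec, plant_manifest(), n_frames = 1)
  top <- gen$trajectory$topology
  f0 <- gen$trajectory$frames[[1]]
  sel <- select_atoms(top, molecule_id = 1)
  set.seed(12)
  base_frames <- lapply(0:9, function(j) {
    co <- f0$coords
    co[sel, ] <- co[sel, ] + matrix(rnorm(3 * length(sel), sd = 0.02), ncol = 3)
    co
  })
  plain <- new_trajectory(top, lapply(seq_along(base_frames), function(j)
    new_frame(base_frames[[j]], f0$box, time = j - 1)))
  moved <- new_trajectory(top, lapply(seq_along(base_frames), function(j) {
    co <- base_frames[[j]] %*% t(rot_z(0.2 * j)) + j * 0.3
    new_frame(co %% rep(f0$box, each = nrow(co)), f0$box, time = j - 1)
  }))
  ra <- rmsf(plain, 1, sel = sel)
  rb <- rmsf(moved, 1, sel = sel)
  expect_equal(rb$rmsf_nm, ra$rmsf_nm, tolerance = 1e-6)
})

test_that("radius of gyration: point, shell, solid ball, scaling", {
  top1 <- new_topology(data.frame(name = rep("A", 4), element = "C", mass = 1,
                                  residue_id = 1, residue_name = "X",
                                  molecule_id = 1, species = "PROTEIN"))
  f <- new_frame(matrix(1, 4, 3), c(10, 10, 10))
  expect_equal(radius_of_gyration(f, top1, 1:4), 0)
  # equal masses on a shell of radius R -> Rg = R (exactly, any point set on the shell)
  R <- 1.3
  n <- 200
  set.seed(13)
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * R
  # center the shell so the COM offset does not shift Rg beyond sampling:
  pts <- sweep(pts, 2, colMeans(pts))
  pts <- pts / sqrt(mean(rowSums(pts^2))) * R     # renormalize exactly
  topn <- new_topology(data.frame(name = "A", element = "C", mass = 1,
                                  residue_id = 1, residue_name = "X",
                                  molecule_id = 1, species = "PROTEIN")[rep(1, n), ])
  fshell <- new_frame(sweep(pts, 2, c(5, 5, 5), "+"), c(20, 20, 20))
  expect_equal(radius_of_gyration(fshell, topn, 1:n), R, tolerance = 1e-12)
  # uniform solid ball -> R * sqrt(3/5)
  set.seed(14)
  nb <- 4000
  ball <- matrix(runif(3 * nb * 3, -1, 1), ncol = 3)
  ball <- ball[rowSums(ball^2) <= 1, ][1:nb, ] * R
  topb <- new_topology(data.frame(name = "A", element = "C", mass = 1,
                                  residue_id = 1, residue_name = "X",
                                  molecule_id = 1, species = "PROTEIN")[rep(1, nb), ])
  fball <- new_frame(sweep(ball, 2, c(5, 5, 5), "+"), c(20, 20, 20))
  expect_equal(radius_of_gyration(fball, topb, 1:nb), R * sqrt(3 / 5),
               tolerance = 0.02)
  # linear scaling
  f2 <- new_frame(sweep(pts * 2, 2, c(5, 5, 5), "+"), c(20, 20, 20))
  expect_equal(radius_of_gyration(f2, topn, 1:n),
               2 * radius_of_gyration(fshell, topn, 1:n), tolerance = 1e-12)
  # split molecule is made whole first
  top2 <- new_topology(data.frame(name = c("A", "B"), element = "C", mass = 1,
                                  residue_id = 1, residue_name = "X",
                                  molecule_id = 1, species = "PROTEIN"))
  fsplit <- new_frame(rbind(c(4.9, 0, 0), c(0.1, 0, 0)), c(5, 5, 5))
  expect_equal(radius_of_gyration(fsplit, top2, 1:2), 0.1, tolerance = 1e-12)
})

test_that("cross-copy aggregation reports window means and sd", {
  ag <- aggregate_copies(list(a = rep(0.1, 5), b = rep(0.3, 5)))
  expect_equal(ag$mean, 0.2)
  expect_equal(ag$sd, sd(c(0.1, 0.3)))
  # identical copies -> sd 0
  ag2 <- aggregate_copies(list(rep(1, 3), rep(1, 3), rep(1, 3)))
  expect_equal(ag2$sd, 0)
  # window restriction
  ag3 <- aggregate_copies(list(c(10, 0.2), c(10, 0.4)), window = 2)
  expect_equal(ag3$mean, 0.3)
  expect_error(aggregate_copies(list()), "no copies")
  expect_error(aggregate_copies(list(1:3), window = 9), "window")
})

test_that("structure_metrics aggregates per-copy rmsd and rg over copies", {
  spec <- synthetic_spec(n_proteins = 3, n_residues = 15, n_chains = 1,
                         chain_length = 4, protein_radius = 1.2)
  gen <- generate_planted(spec, plant_manifest(), n_frames = 4)
  sm <- structure_metrics(gen$trajectory, include_rmsf = FALSE)
  expect_equal(dim(sm$rmsd), c(3, 4))
  # static planted frames: rmsd 0, identical copies -> sd 0
  expect_true(all(sm$rmsd < 1e-9))
  expect_equal(sm$summary$sd[sm$summary$metric == "rg_nm"], 0, tolerance = 1e-9)
  # rg of a fibonacci-lattice sphere of radius 1.2: on the shell, so Rg is
  # 1.2 up to the lattice's tiny center-of-mass offset
  expect_equal(sm$summary$mean[sm$summary$metric == "rg_nm"], 1.2,
               tolerance = 1e-3)
})
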