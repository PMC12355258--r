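# Geometric hydrogen-bond detection and species-pair accounting.

# Minimal explicit topologies for donor/acceptor classification.
water_box <- function() {
  top <- new_topology(data.frame(
    name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
    mass = c(16, 1, 1), residue_id = 1, residue_name = "SOL",
    molecule_id = 1, species = "WATER"))
  f <- new_frame(rbind(c(1, 1, 1), c(1.08, 1.06, 1), c(0.92, 1.06, 1)) / 10,
                 c(5, 5, 5))
  list(top = top, frame = f)
}

test_that("donor/acceptor identification: water, alkane, protonation state", {
  w <- water_box()
  da <- find_donors_acceptors(w$top, w$frame)
  expect_equal(nrow(da$donors), 2)        # one donor O with two H
  expect_equal(unique(da$donors$donor), 1)
  expect_equal(da$acceptors, 1)
  # methane-like fragment: no N/O, no donors or acceptors
  ch4 <- new_topology(data.frame(
    name = c("C", "H1", "H2", "H3", "H4"), element = c("C", rep("H", 4)),
    mass = c(12, rep(1, 4)), residue_id = 1, residue_name = "ACR",
    molecule_id = 1, species = "POLYMER"))
  fr <- new_frame(rbind(c(0, 0, 0), c(0.1, 0, 0), c(-0.1, 0, 0),
                        c(0, 0.1, 0), c(0, -0.1, 0)) + 1, c(5, 5, 5))
  da2 <- find_donors_acceptors(ch4, fr)
  expect_equal(nrow(da2$donors), 0)
  expect_length(da2$acceptors, 0)
  # carboxyl: protonated COOH has one donor, deprotonated COO- has none
  cooh <- new_topology(data.frame(
    name = c("C", "O1", "O2", "HO"), element = c("C", "O", "O", "H"),
    mass = c(12, 16, 16, 1), residue_id = 1, residue_name = "ACR",
    molecule_id = 1, species = "POLYMER"))
  fcooh <- new_frame(rbind(c(0, 0, 0), c(0.12, 0, 0), c(-0.06, 0.1, 0),
                           c(0.2, 0.05, 0)) + 1, c(5, 5, 5))
  da3 <- find_donors_acceptors(cooh, fcooh)
  expect_equal(nrow(da3$donors), 1)
  expect_equal(length(da3$acceptors), 2)
  coo <- new_topology(as.data.frame(cooh)[1:3, setdiff(names(cooh), "index")])
  da4 <- find_donors_acceptors(coo, new_frame(fcooh$coords[1:3, ], c(5, 5, 5)))
  expect_equal(nrow(da4$donors), 0)
  expect_equal(length(da4$acceptors), 2)
  # orphan hydrogen is a topology error
  orphan <- new_topology(data.frame(
    name = c("OW", "HX"), element = c("O", "H"), mass = c(16, 1),
    residue_id = c(1, 2), residue_name = "SOL", molecule_id = c(1, 2),
    species = "WATER"))
  forph <- new_frame(rbind(c(0, 0, 0), c(1, 1, 1)), c(5, 5, 5))
  expect_error(find_donors_acceptors(orphan, forph), "no heavy atom")
})

test_that("criteria validation and boundary conventions", {
  expect_error(hbond_criteria(d_cut = 0), "positive")
  expect_error(hbond_criteria(angle_cut = 190), "angle_cut")
  expect_s3_class(hbond_criteria(), "hbond_criteria")
})

test_that("planted triples inside/outside the cutoffs are classified exactly", {
  cases <- data.frame(distance = c(0.30, 0.36, 0.30, 0.349),
                      angle = c(10, 10, 40, 29.9))
  expected <- c(TRUE, FALSE, FALSE, TRUE)
  spec <- synthetic_spec(n_proteins = 1, n_residues = 2, n_chains = 1,
                         chain_length = 4)
  gen <- generate_planted(spec, plant_manifest(hbonds = cases), n_frames = 1)
  top <- gen$trajectory$topology
  f <- gen$trajectory$frames[[1]]
  da <- find_donors_acceptors(top, f)
  ev <- detect_hbonds(f, top, da)
  expect_equal(nrow(ev), sum(expected))
  # each detected event satisfies both criteria
  expect_true(all(ev$distance_nm <= 0.35 + 1e-12))
  expect_true(all(ev$angle_deg <= 30 + 1e-9))
})

test_that("boundary equality counts as bonded on both criteria", {
  # hand-built exact geometry: distance exactly d_cut, angle exactly 90
  top <- new_topology(data.frame(
    name = c("OD", "HD", "OA"), element = c("O", "H", "O"),
    mass = c(16, 1, 16), residue_id = c(1, 1, 2), residue_name = "SOL",
    molecule_id = c(1, 1, 2), species = "WATER"))
  # x-offsets chosen so the distance is the same double as the cutoff
  f_dist <- new_frame(rbind(c(0, 1, 1), c(0.1, 1, 1), c(0.35, 1, 1)),
                      c(5, 5, 5))
  da <- find_donors_acceptors(top, f_dist)
  expect_equal(nrow(detect_hbonds(f_dist, top, da,
                                  hbond_criteria(0.35, 30))), 1)
  f_ang <- new_frame(rbind(c(0, 1, 1), c(0.1, 1, 1), c(0, 1.3, 1)),
                     c(5, 5, 5))
  expect_equal(nrow(detect_hbonds(f_ang, top, da,
                                  hbond_criteria(0.35, 90))), 1)
  expect_equal(nrow(detect_hbonds(f_ang, top, da,
                                  hbond_criteria(0.35, 89.9))), 0)
})

test_that("50 planted triples (25 valid / 25 invalid) give exactly 25 events", {
  set.seed(101)
  valid <- data.frame(distance = runif(25, 0.2, 0.315), angle = runif(25, 0, 27))
  invalid <- rbind(
    data.frame(distance = runif(13, 0.39, 0.6), angle = runif(13, 0, 27)),
    data.frame(distance = runif(12, 0.2, 0.315), angle = runif(12, 33, 150)))
  spec <- synthetic_spec(n_proteins = 1, n_residues = 2, n_chains = 1,
                         chain_length = 4)
  gen <- generate_planted(spec, plant_manifest(hbonds = rbind(valid, invalid)),
                          n_frames = 1)
  top <- gen$trajectory$topology
  f <- gen$trajectory$frames[[1]]
  da <- find_donors_acceptors(top, f)
  ev <- detect_hbonds(f, top, da)
  expect_equal(nrow(ev), 25L)
  expect_equal(gen$manifest$expected$hbond_detected, 25L)
})

test_that("detection equals the brute-force triple loop", {
  set.seed(33)
  # random N/O soup with hydrogens attached 0.1 nm from random heavies:
  # dense enough for many accidental near-criterion geometries
  n_heavy <- 30; n_h <- 25
  el <- c(sample(c("N", "O"), n_heavy, replace = TRUE), rep("H", n_h))
  top <- new_topology(data.frame(
    name = paste0(el, seq_along(el)), element = el, mass = 10,
    residue_id = c(seq_len(n_heavy), sample(n_heavy, n_h, replace = TRUE) + 100L),
    residue_name = "SOL",
    molecule_id = seq_along(el), species = "WATER"))
  box <- c(2.5, 2.5, 2.5)
  crit <- hbond_criteria(0.35, 30)
  tested <- 0L
  for (rep in 1:3) {
    heavy_xyz <- matrix(runif(n_heavy * 3, 0, 2.5), ncol = 3)
    owner <- sample(n_heavy, n_h, replace = TRUE)
    u <- matrix(rnorm(n_h * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    f <- new_frame(rbind(heavy_xyz, heavy_xyz[owner, ] + 0.1 * u) %%
                     rep(box, each = n_heavy + n_h), box)
    da <- find_donors_acceptors(top, f, attach_cut = 0.12)
    expect_gt(nrow(da$donors), 0)
    ev <- detect_hbonds(f, top, da, crit)
    orc <- oracle_detect_hbonds(f, top, da, crit)
    expect_equal(nrow(ev), nrow(orc))
    if (nrow(ev)) {
      tested <- tested + nrow(ev)
      expect_equal(ev[order(ev$donor, ev$acceptor), c("donor", "acceptor")],
                   orc[order(orc$donor, orc$acceptor), c("donor", "acceptor")],
                   ignore_attr = TRUE)
    }
  }
  expect_gt(tested, 0)  # the comparison must actually exercise events
})

test_that("counts are invariant under rigid rotation, translation and wrapping", {
  set.seed(101)
  valid <- data.frame(distance = runif(10, 0.2, 0.315), angle = runif(10, 0, 27))
  spec <- synthetic_spec(n_proteins = 1, n_residues = 2, n_chains = 1,
                         chain_length = 4)
  gen <- generate_planted(spec, plant_manifest(hbonds = valid), n_frames = 1)
  top <- gen$trajectory$topology
  f <- gen$trajectory$frames[[1]]
  da <- find_donors_acceptors(top, f)
  n0 <- nrow(detect_hbonds(f, top, da))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- new_frame(f$coords %*% t(R) + 5, f$box, f$time)       # rotate+shift
  wrapped <- new_frame(rot$coords %% rep(f$box, each = nrow(rot$coords)),
                       f$box, f$time)
  expect_equal(nrow(detect_hbonds(rot, top, da)), n0)
  expect_equal(nrow(detect_hbonds(wrapped, top, da)), n0)
})

test_that("tightening either cutoff never increases the count", {
  set.seed(77)
  hb <- data.frame(distance = runif(40, 0.15, 0.5), angle = runif(40, 0, 60))
  spec <- synthetic_spec(n_proteins = 1, n_residues = 2, n_chains = 1,
                         chain_length = 4)
  gen <- generate_planted(spec, plant_manifest(hbonds = hb), n_frames = 1)
  top <- gen$trajectory$topology
  f <- gen$trajectory$frames[[1]]
  da <- find_donors_acceptors(top, f)
  counts_d <- sapply(seq(0.5, 0.15, -0.05), function(dc)
    nrow(detect_hbonds(f, top, da, hbond_criteria(d_cut = dc, angle_cut = 60))))
  counts_a <- sapply(seq(60, 5, -5), function(ac)
    nrow(detect_hbonds(f, top, da, hbond_criteria(d_cut = 0.5, angle_cut = ac))))
  expect_true(all(diff(counts_d) <= 0))
  expect_true(all(diff(counts_a) <= 0))
})

test_that("species-pair accounting applies the per-molecule normalizers", {
  ev <- data.frame(donor = 1:4, hydrogen = 1:4, acceptor = 5:8,
                   donor_species = c("PROTEIN", "PROTEIN", "POLYMER", "WATER"),
                   acceptor_species = c("POLYMER", "WATER", "POLYMER", "WATER"),
                   donor_molecule = 1:4, acceptor_molecule = 5:8,
                   distance_nm = 0.3, angle_deg = 10)
  top <- tiny_system(n_prot = 2, n_chain = 2)$topology
  pc <- count_by_pair(ev, top, n_lyz = 16, n_paa = 8)
  expect_setequal(pc$pair, c("LYZ-PAA", "LYZ-W", "PAA-PAA", "other"))
  expect_equal(pc$normalized[pc$pair == "LYZ-PAA"], 1 / 16)
  expect_equal(pc$normalized[pc$pair == "PAA-PAA"], 1 / 8)
  expect_equal(pc$normalized[pc$pair == "other"], 1)   # W-W routed, not dropped
  # convention anchor: 160 protein-polymer bonds over 16 proteins = 10 per molecule
  ev2 <- data.frame(donor = 1:160, hydrogen = 1:160, acceptor = 161:320,
                    donor_species = "PROTEIN", acceptor_species = "POLYMER",
                    donor_molecule = 1, acceptor_molecule = 2,
                    distance_nm = 0.3, angle_deg = 10)
  pc2 <- count_by_pair(ev2, top, n_lyz = 16, n_paa = 8)
  expect_equal(pc2$normalized, 10)
  # intermolecular-only filter drops same-molecule events
  ev3 <- ev
  ev3$acceptor_molecule <- ev3$donor_molecule
  expect_equal(nrow(count_by_pair(ev3, top, intermolecular_only = TRUE)), 0)
})

test_that("hbond time series: constant plant, ramp recovery, block error", {
  spec <- synthetic_spec(n_proteins = 2, n_residues = 2, n_chains = 1,
                         chain_length = 4)
  # static plant repeated over 10 frames: constant series, zero error
  hb <- data.frame(distance = rep(0.3, 4), angle = rep(10, 4),
                   donor_species = rep("PROTEIN", 4),
                   acceptor_species = rep("POLYMER", 4))
  gen <- generate_planted(spec, plant_manifest(hbonds = hb), n_frames = 10)
  ts <- hbond_timeseries(gen$trajectory, pair = "LYZ-PAA", n_lyz = 2, n_paa = 1)
  expect_equal(unique(ts$raw), 4L)
  expect_equal(ts$mean, 2)       # 4 bonds / 2 proteins
  expect_equal(ts$se, 0)
  # ramping plants (activation schedule) give a monotone series
  hb2 <- data.frame(distance = rep(0.3, 5), angle = rep(10, 5),
                    donor_species = "PROTEIN", acceptor_species = "POLYMER",
                    active_from = c(1, 3, 5, 7, 9))
  gen2 <- generate_planted(spec, plant_manifest(hbonds = hb2), n_frames = 10)
  ts2 <- hbond_timeseries(gen2$trajectory, pair = "LYZ-PAA", n_lyz = 2, n_paa = 1)
  expect_true(all(diff(ts2$raw) >= 0))
  expect_equal(ts2$raw[1], 1L)
  expect_equal(ts2$raw[10], 5L)
  expect_error(hbond_timeseries(generate_planted(spec, plant_manifest(hbonds = hb),
                                                 n_frames = 3)$trajectory),
               "at least")
})
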