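test_that("collinear geometry makes a bond and the distance cutoff breaks it", {
  atoms <- data.frame(name = c("D", "H", "A"), element = c("O", "H", "O"),
                      resid = 1:3, resname = "TST", mass = 1,
                      charge = 0, eps = 0, sigma = 0,
                      is_donor = c(TRUE, FALSE, FALSE),
                      is_acceptor = c(FALSE, FALSE, TRUE))
  top <- topology(atoms, donor_hydrogens = list("1" = 2L))
  co <- rbind(c(0, 0, 0), c(0.0957, 0, 0), c(0.30, 0, 0))
  hb <- detect_hbonds(co, top, c(5, 5, 5))
  expect_equal(nrow(hb), 1)
  expect_equal(unlist(hb[1, ]), c(donor = 1L, hydrogen = 2L, acceptor = 3L))
  co2 <- co; co2[3, 1] <- 0.36
  expect_equal(nrow(detect_hbonds(co2, top, c(5, 5, 5))), 0)
  # angle cutoff: swing the acceptor past 30 degrees off the D-H axis
  co3 <- co; co3[3, ] <- 0.30 * c(cos(35 * pi / 180), sin(35 * pi / 180), 0)
  expect_equal(nrow(detect_hbonds(co3, top, c(5, 5, 5))), 0)
  # a donor with no attached hydrogens cannot be evaluated
  top_bad <- topology(atoms, donor_hydrogens = list())
  expect_error(detect_hbonds(co, top_bad, c(5, 5, 5)), "without attached")
})

test_that("detector equals the all-pairs brute-force oracle on random water", {
  for (seed in 1:5) {
    fx <- random_water_frame(60, seed = seed)
    hb <- detect_hbonds(fx$coords, fx$top, fx$box)
    or <- oracle_hbonds(fx$coords, fx$top, fx$box)
    key <- function(m) sort(apply(m, 1, paste, collapse = "-"))
    expect_identical(key(as.matrix(hb)), key(or))
  }
})

test_that("bond counting is symmetric in the group arguments", {
  fx <- random_water_frame(40, seed = 9)
  tr <- trajectory(fx$top, array(fx$coords, c(nrow(fx$coords), 3, 1)),
                   fx$box, 0)
  a <- select_atoms(fx$top, "resid 1:20")
  b <- select_atoms(fx$top, "resid 21:40")
  c1 <- hbond_count_series(tr, a, b)
  c2 <- hbond_count_series(tr, b, a)
  expect_equal(c1$count, c2$count)
  expect_error(hbond_count_series(tr, integer(0), b), "empty")
})

test_that("a constructed bond-breaking perturbation shifts the mean count", {
  # 200 donor-acceptor pairs, all bonded; break 67 of them (-33.5%)
  n <- 200
  atoms <- data.frame(name = rep(c("D", "H", "A"), n), element = rep(c("O", "H", "O"), n),
                      resid = rep(seq_len(n), each = 3), resname = "TST",
                      mass = 1, charge = 0, eps = 0, sigma = 0,
                      is_donor = rep(c(TRUE, FALSE, FALSE), n),
                      is_acceptor = rep(c(FALSE, FALSE, TRUE), n))
  dh <- stats::setNames(lapply(seq_len(n), function(i) 3L * i - 1L),
                        as.character(3L * seq_len(n) - 2L))
  top <- topology(atoms, donor_hydrogens = dh)
  base <- matrix(NA_real_, 3 * n, 3)
  for (i in seq_len(n)) {
    orig <- c((i - 1) %% 20, (i - 1) %/% 20, 0) + 0.5
    base[3 * i - 2, ] <- orig
    base[3 * i - 1, ] <- orig + c(0.0957, 0, 0)
    base[3 * i, ] <- orig + c(0.30, 0, 0)
  }
  box <- c(30, 30, 30)
  pert <- base
  broken <- seq_len(67)
  pert[3 * broken, 1] <- pert[3 * broken, 1] + 0.2  # push acceptors out
  tr_b <- trajectory(top, array(base, c(3 * n, 3, 1)), box, 0)
  tr_p <- trajectory(top, array(pert, c(3 * n, 3, 1)), box, 0)
  donors <- which(atoms$is_donor)
  acc <- which(atoms$is_acceptor)
  cb <- attr(hbond_count_series(tr_b, donors, acc), "mean")
  cp <- attr(hbond_count_series(tr_p, donors, acc), "mean")
  change <- (cp - cb) / cb * 100
  expect_lt(abs(change - (-33.5)), 5 * 0.335)  # within 5% of the target drop
})

test_that("Coulomb energy reproduces the conversion factor and 1/r scaling", {
  top <- ion_topology(c(1, -1))
  co <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(coulomb_energy(co, top, c(10, 10, 10), 1, 2), -138.935458,
               tolerance = 1e-9)
  top2 <- ion_topology(c(1, 1))
  co2 <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  expect_equal(coulomb_energy(co2, top2, c(10, 10, 10), 1, 2), 277.870916,
               tolerance = 1e-9)
  expect_error(coulomb_energy(co, top, c(10, 10, 10), 1:2, 2), "overlap")
})

test_that("LJ potential has its root at sigma and its minimum at -epsilon", {
  top <- ion_topology(c(0, 0), eps = c(0.7, 0.7), sigma = c(0.3, 0.3))
  co <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  expect_equal(lj_energy(co, top, c(10, 10, 10), 1, 2), 0, tolerance = 1e-12)
  co2 <- rbind(c(0, 0, 0), c(2^(1 / 6) * 0.3, 0, 0))
  expect_equal(lj_energy(co2, top, c(10, 10, 10), 1, 2), -0.7, tolerance = 1e-9)
})

test_that("group energies equal brute-force oracles and are symmetric", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    n <- 12
    q <- runif(n, -1, 1)
    eps <- runif(n, 0.1, 1)
    sig <- runif(n, 0.25, 0.35)
    top <- ion_topology(q, eps, sig)
    co <- matrix(runif(3 * n, 0, 3), n, 3)
    box <- c(3, 3, 3)
    ia <- 1:6; ib <- 7:12
    expect_equal(coulomb_energy(co, top, box, ia, ib),
                 oracle_coulomb(co, q, ia, ib, box), tolerance = 1e-9)
    expect_equal(lj_energy(co, top, box, ia, ib),
                 oracle_lj(co, eps, sig, ia, ib, box), tolerance = 1e-9)
    expect_equal(coulomb_energy(co, top, box, ia, ib),
                 coulomb_energy(co, top, box, ib, ia), tolerance = 1e-12)
    expect_equal(lj_energy(co, top, box, ia, ib),
                 lj_energy(co, top, box, ib, ia), tolerance = 1e-12)
  }
})

test_that("enlarging the cutoff approaches the full pairwise sum", {
  set.seed(5)
  n <- 10
  top <- ion_topology(runif(n, -0.5, 0.5))
  co <- matrix(runif(3 * n, 0, 4), n, 3)
  box <- c(4, 4, 4)
  full <- lj_energy(co, top, box, 1:5, 6:10)
  errs <- vapply(c(0.5, 1.0, 1.9), function(rc)
    abs(lj_energy(co, top, box, 1:5, 6:10, cutoff = rc) - full), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("ideal-gas RDF is flat at 1 and normalisation is density-free", {
  set.seed(8)
  mk <- function(m, nf) {
    at <- data.frame(name = "P", element = "X", resid = 1:(m + 1),
                     resname = c("REF", rep("GAS", m)), mass = 1, charge = 0,
                     eps = 0, sigma = 0)
    tp <- topology(at)
    co <- array(runif((m + 1) * 3 * nf, 0, 3), c(m + 1, 3, nf))
    trajectory(tp, co, c(3, 3, 3), (0:(nf - 1)) * 0.1)
  }
  tr <- mk(400, 25)
  g <- rdf(tr, "resname REF", "resname GAS", r_max = 1.4, bin = 0.1,
           ref_mode = "atoms")
  # Poisson 3 sigma per bin, skipping the low-count first bin
  rho <- 401 / 27
  for (i in 2:nrow(g)) {
    r0 <- g$r_nm[i] - 0.05
    expected <- rho * 4 / 3 * pi * ((r0 + 0.1)^3 - r0^3) * 25
    expect_lt(abs(g$g[i] - 1), 3 / sqrt(expected))
  }
  # doubling the target density leaves g unchanged within pooled noise
  g2 <- rdf(mk(800, 25), "resname REF", "resname GAS", r_max = 1.4, bin = 0.1,
            ref_mode = "atoms")
  for (i in 2:nrow(g)) {
    r0 <- g$r_nm[i] - 0.05
    shell <- 4 / 3 * pi * ((r0 + 0.1)^3 - r0^3) * 25
    sig <- sqrt(1 / (401 / 27 * shell) + 1 / (801 / 27 * shell))
    expect_lt(abs(g2$g[i] - g$g[i]), 3.5 * sig)
  }
  expect_error(rdf(tr, "resname REF", "resname GAS", r_max = 2), "half")
  # one pair at 0.30 nm: all mass in that bin
  co1 <- array(rbind(c(1, 1, 1), c(1.3, 1, 1)), c(2, 3, 1))
  at1 <- data.frame(name = "P", element = "X", resid = 1:2,
                    resname = c("REF", "GAS"), mass = 1, charge = 0,
                    eps = 0, sigma = 0)
  tr1 <- trajectory(topology(at1), co1, c(3, 3, 3), 0)
  g1 <- rdf(tr1, "resname REF", "resname GAS", r_max = 1, bin = 0.05)
  expect_equal(which(g1$g > 0), 7L)  # bin [0.30, 0.35)
})

test_that("per-residue energies reduce to pair sums and difference to zero", {
  # one charged LJ site and one water at fixed geometry
  g <- generate_jump_trajectory(pore_model(z_max = 0.4), ground_truth(0.5),
                                1, 3, seed = 110)
  site <- reference_sites(matrix(c(0.2, 0.2, 0.05), 1, 3), charges = 0.5,
                          epsilon = 0.4, sigma = 0.3)
  tr <- merge_reference_sites(g$traj, site)
  resid_ref <- unique(tr$topology$atoms$resid[tr$topology$atoms$resname == "REF"])
  et <- interaction_energy_per_residue(tr, resid_ref)
  ir <- which(tr$topology$atoms$resname == "REF")
  iw <- select_atoms(tr$topology, "water")
  ec <- mean(vapply(1:3, function(f)
    coulomb_energy(frame_coords(tr, f), tr$topology, tr$box[f, ], ir, iw),
    numeric(1)))
  el <- mean(vapply(1:3, function(f)
    lj_energy(frame_coords(tr, f), tr$topology, tr$box[f, ], ir, iw),
    numeric(1)))
  expect_equal(et$coulomb_kJmol, ec, tolerance = 1e-9)
  expect_equal(et$lj_kJmol, el, tolerance = 1e-9)
  expect_equal(et$total_kJmol, et$coulomb_kJmol + et$lj_kJmol, tolerance = 1e-12)
  # zero charge and epsilon: zero energy
  site0 <- reference_sites(matrix(c(0.3, 0.3, 0.35), 1, 3))
  tr0 <- merge_reference_sites(g$traj, site0)
  r0 <- unique(tr0$topology$atoms$resid[tr0$topology$atoms$resname == "REF"])
  et0 <- interaction_energy_per_residue(tr0, r0)
  expect_equal(et0$total_kJmol, 0)
  # identical runs: every delta is zero; deltas are additive over residues
  de <- delta_energy(tr, tr, resid_ref)
  expect_equal(de$d_total_kJmol, 0)
  expect_equal(sum(de$d_total_kJmol), sum(de$d_coulomb_kJmol + de$d_lj_kJmol))
})

test_that("removing a bound water destabilises the interaction energy", {
  # attractive site; baseline has one extra water bound next to it
  site <- reference_sites(matrix(c(1, 1, 1), 1, 3), charges = 0.8,
                          epsilon = 0.3, sigma = 0.3)
  near <- matrix(c(1, 1, 1.35), 1, 3)
  far <- matrix(c(1, 1, 2.8), 1, 3)
  mk <- function(opos) {
    tr <- traj_from_oxygens(rep(list(opos), 2), box = c(3, 3, 3.2))
    merge_reference_sites(tr, site)
  }
  tr_base <- mk(near)   # water bound at the site
  tr_field <- mk(far)   # "field" run lost the bound water
  rid <- unique(tr_base$topology$atoms$resid[tr_base$topology$atoms$resname == "REF"])
  de <- delta_energy(tr_field, tr_base, rid)
  expect_gt(de$d_total_kJmol, 0)  # positive = destabilised
})

test_that("local water counts match a periodic brute-force oracle", {
  g <- generate_jump_trajectory(pore_model(z_max = 1), ground_truth(0.5),
                                20, 4, seed = 120)
  site <- reference_sites(matrix(c(0.02, 0.02, 0.02), 1, 3))
  tr <- merge_reference_sites(g$traj, site)
  rid <- unique(tr$topology$atoms$resid[tr$topology$atoms$resname == "REF"])
  lc <- local_water_count(tr, rid, cutoff = 0.5)
  ir <- which(tr$topology$atoms$resname == "REF")
  oracle <- mean(vapply(1:4, function(f)
    oracle_local_count(frame_coords(tr, f), tr$topology, ir, tr$box[f, ], 0.5),
    numeric(1)))
  expect_equal(lc$mean_count, oracle)
  expect_equal(local_water_count(tr, rid, cutoff = 0)$mean_count, 0)
  # three static waters placed inside the cutoff count exactly 3
  o3 <- matrix(c(1, 1, 1.2, 1, 1.2, 1, 1.2, 1, 1), 3, 3, byrow = TRUE)
  tr3 <- merge_reference_sites(traj_from_oxygens(rep(list(o3), 3),
                                                 box = c(3, 3, 3)),
                               reference_sites(matrix(c(1, 1, 1), 1, 3)))
  r3 <- unique(tr3$topology$atoms$resid[tr3$topology$atoms$resname == "REF"])
  expect_equal(local_water_count(tr3, r3, cutoff = 0.5)$mean_count, 3)
})
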