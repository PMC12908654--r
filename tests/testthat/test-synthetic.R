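test_that("generators are pure functions of parameters and seed", {
  pore <- pore_model(z_max = 1)
  a <- generate_jump_trajectory(pore, ground_truth(0.5), 5, 20, seed = 42)
  b <- generate_jump_trajectory(pore, ground_truth(0.5), 5, 20, seed = 42)
  expect_identical(a$traj$coords, b$traj$coords)
  c1 <- generate_exchange_trajectory(0.5, 20, 10, seed = 7)
  c2 <- generate_exchange_trajectory(0.5, 20, 10, seed = 7)
  expect_identical(c1$traj$coords, c2$traj$coords)
  d1 <- generate_brownian_trajectory(pore, 0.001, 5, 10, seed = 3)
  d2 <- generate_brownian_trajectory(pore, 0.001, 5, 10, seed = 3)
  expect_identical(d1$traj$coords, d2$traj$coords)
})

test_that("jump generator recovers a uniform 0.5 ps residence mean", {
  pore <- pore_model(z_max = 0.8)
  g <- generate_jump_trajectory(pore, ground_truth(0.5), 40, 2500, seed = 101)
  rp <- residence_profile(g$traj)
  expect_gt(sum(rp$n_episodes), 1e4)
  pooled <- sum(rp$mean_ps * rp$n_episodes) / sum(rp$n_episodes)
  expect_lt(abs(pooled - 0.5) / 0.5, 0.05)
})

test_that("residence mean below dt is rejected", {
  expect_error(generate_jump_trajectory(pore_model(z_max = 1),
                                        ground_truth(0.05), 2, 5, dt = 0.1),
               "residence mean")
})

test_that("orientation draws hit the configured tilt in the sharp limit", {
  o <- generate_orientations(500, 80, Inf, seed = 1)
  expect_equal(o$polar_deg, rep(80, 500), tolerance = 1e-9)
  o0 <- generate_orientations(200, 0, 1e6, seed = 2)
  expect_true(all(o0$dipole[, 3] > 0.999))
})

test_that("kappa = 0 orientations have zero mean axial cosine", {
  n <- 2e4
  o <- generate_orientations(n, 45, 0, seed = 3)
  m <- mean(o$dipole[, 3])
  # var of cos(theta) for theta uniform on [0,pi] is 1/2
  expect_lt(abs(m), 3 * sqrt(0.5 / n))
})

test_that("libration preserves rigid geometry and amplitude 0 is identity", {
  g <- generate_jump_trajectory(pore_model(z_max = 1), ground_truth(0.5),
                                4, 20, seed = 5)
  expect_identical(add_libration(g$traj, "rock", 0, 25), g$traj)
  for (mode in c("rock", "twist", "wag")) {
    tl <- add_libration(g$traj, mode, 12, 20, seed = 6)
    wt <- tl$topology$waters
    oh1 <- sqrt(apply((tl$coords[wt[, 2], , ] - tl$coords[wt[, 1], , ])^2,
                      c(1, 3), sum))
    oh2 <- sqrt(apply((tl$coords[wt[, 3], , ] - tl$coords[wt[, 1], , ])^2,
                      c(1, 3), sum))
    expect_lt(max(abs(c(oh1, oh2) - 0.09572)), 1e-9)
  }
  expect_error(add_libration(g$traj, "roll", 5, 20), "arg")
})

test_that("wag libration oscillates at the configured frequency", {
  nf <- 512
  tr <- traj_from_oxygens(rep(list(matrix(c(1, 1, 1), 1, 3)), nf),
                          box = c(3, 3, 3), dt = 0.005)
  tw <- add_libration(tr, "wag", 10, 25.6, seed = 3)
  # dipole along +z puts the molecule in the y-z plane: the out-of-plane
  # hydrogen displacement is along x
  x <- tw$coords[2, 1, ] - tr$coords[2, 1, 1]
  sp <- stats::spectrum(stats::ts(x, deltat = 0.005), plot = FALSE, taper = 0.2)
  fpk <- sp$freq[which.max(sp$spec)]
  expect_equal(1 / fpk, 1 / 25.6, tolerance = 0.02)
})

test_that("Brownian free diffusion obeys the Einstein relation", {
  pore <- pore_model(z_max = 3, radius = 50, xy_half_width = 1.5)
  D <- 8e-4
  b <- generate_brownian_trajectory(pore, D, 250, 150, seed = 9,
                                    boundary = "none")
  wt <- b$traj$topology$waters
  L <- 20L
  disp <- b$traj$coords[wt[, 1], , (1 + L):150] - b$traj$coords[wt[, 1], , 1:(150 - L)]
  msd <- mean(apply(disp^2, c(1, 3), sum))
  expect_lt(abs(msd / (6 * L * 0.1) - D) / D, 0.10)
})

test_that("reflecting walls keep Brownian waters inside the pore radius", {
  pore <- pore_model(z_max = 1, radius = 0.4, xy_half_width = 0.8)
  b <- generate_brownian_trajectory(pore, 5e-4, 20, 100, seed = 4)
  wt <- b$traj$topology$waters
  r <- sqrt((b$traj$coords[wt[, 1], 1, ] - 0.8)^2 +
            (b$traj$coords[wt[, 1], 2, ] - 0.8)^2)
  expect_true(all(r <= 0.4 + 1e-9))
  # vanishing diffusivity: displacements vanish with it
  b0 <- generate_brownian_trajectory(pore, 1e-12, 5, 20, seed = 4)
  wt0 <- b0$traj$topology$waters
  dmax <- max(abs(b0$traj$coords[wt0[, 1], , 20] - b0$traj$coords[wt0[, 1], , 1]))
  expect_lt(dmax, 1e-4)
})

test_that("reference sites merge with sequential residues and guard overlap", {
  g <- generate_jump_trajectory(pore_model(z_max = 1), ground_truth(0.5),
                                3, 4, seed = 8)
  pos <- matrix(c(0.1, 0.1, 0.1, 0.1, 0.1, 0.5, 0.1, 0.1, 0.9), 3, 3,
                byrow = TRUE)
  sites <- reference_sites(pos, charges = c(1, 0, -1))
  merged <- merge_reference_sites(g$traj, sites)
  a <- merged$topology$atoms
  expect_equal(sum(a$resname == "REF"), 3)
  expect_equal(sort(unique(a$resid[a$resname == "REF"])), 4:6)
  expect_equal(net_charge(merged$topology),
               net_charge(g$traj$topology), tolerance = 1e-12)
  # a site on top of an existing oxygen is refused
  wt <- g$traj$topology$waters
  clash <- reference_sites(matrix(g$traj$coords[wt[1, 1], , 1], 1, 3))
  expect_error(merge_reference_sites(g$traj, clash), "overlap")
})

test_that("ground truth round-trips losslessly through YAML", {
  tr <- ground_truth(slab_residence = c(0.43, 0.54), slab_tilt_deg = 80,
                     slab_kappa = 12.5, exchange_rate = 0.7062,
                     libration = list(mode = "wag", amplitude_deg = 10,
                                      frequency_THz = 25.6),
                     seed = 99L)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth(tr, p)
  tr2 <- read_ground_truth(p)
  expect_equal(tr2$slab_residence, tr$slab_residence)
  expect_equal(tr2$exchange_rate, tr$exchange_rate)
  expect_equal(tr2$libration$frequency_THz, 25.6)
  expect_equal(tr2$seed, 99L)
})

test_that("exchange survival matches the exponential law within a 99% band", {
  k <- 0.5
  e <- generate_exchange_trajectory(k, 1500, 40, seed = 13)
  rc <- retention_curve(e$traj, "resname REF", cutoff = 1.0, max_lag = 3,
                        origin_stride = 1000)  # single origin
  n0 <- attr(rc, "initial_n")
  for (lag in c(0.5, 1, 2)) {
    i <- which(abs(rc$lag_ps - lag) < 1e-9)
    p <- exp(-k * lag)
    expect_lt(abs(rc$R[i] - p), 2.576 * sqrt(p * (1 - p) / n0))
  }
})
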