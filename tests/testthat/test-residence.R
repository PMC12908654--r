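test_that("episodes follow the inclusive-frame duration and re-entry rules", {
  slab <- region_spec("slab", z = c(1, 2))
  # in for frames 1-10 then out: one (censored-at-start) episode of 1.0 ps
  z <- c(rep(1.5, 10), rep(2.5, 10))
  ep <- compute_episodes(scripted_z_traj(z), slab)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration, 1.0)
  expect_true(ep$censored)  # touches the trajectory start
  # leave at frame 6, re-enter at frame 8: two separate episodes
  z2 <- c(rep(1.5, 5), 2.5, 2.5, rep(1.5, 5), rep(2.5, 3))
  ep2 <- compute_episodes(scripted_z_traj(z2), slab)
  expect_equal(nrow(ep2), 2)
  expect_equal(ep2$duration, c(0.5, 0.5))
  expect_equal(ep2$censored, c(TRUE, FALSE))
  # occupancy conservation: summed durations equal total in-region time
  expect_equal(sum(ep2$duration), sum(z2 >= 1 & z2 < 2) * 0.1)
})

test_that("episode means converge to the jump-process ground truth", {
  pore <- pore_model(z_max = 0.6)
  errs <- vapply(c(300, 2600), function(nf) {
    g <- generate_jump_trajectory(pore, ground_truth(0.5), 40, nf, seed = 21)
    ep <- compute_episodes(g$traj, region_spec("slab", z = c(0.2, 0.3)))
    abs(mean(ep$duration[!ep$censored]) - 0.5) / 0.5
  }, numeric(1))
  expect_lt(errs[2], 0.05)
  expect_lt(errs[2], errs[1] + 0.02)  # error shrinks with episode count
})

test_that("residence profile recovers distinct slab means and flags gaps", {
  pore <- pore_model(z_max = 0.8)
  truth <- ground_truth(slab_residence = c(rep(0.43, 4), rep(0.54, 4)))
  g <- generate_jump_trajectory(pore, truth, 40, 2500, seed = 31)
  rp <- residence_profile(g$traj, c(0, 0.8))
  # pooled per condition (episode-weighted) for stable comparison
  pool <- function(b) sum(rp$mean_ps[b] * rp$n_episodes[b]) / sum(rp$n_episodes[b])
  expect_lt(abs(pool(1:4) - 0.43) / 0.43, 0.05)
  expect_lt(abs(pool(5:8) - 0.54) / 0.54, 0.05)
  expect_error(residence_profile(g$traj, c(0, 99)), "outside the box")
  # a never-visited slab is NA-flagged, not zero
  zs <- scripted_z_traj(rep(0.55, 30), box = c(2, 2, 4))
  rp2 <- residence_profile(zs, c(0, 1))
  expect_true(is.na(rp2$mean_ps[1]))
  expect_equal(rp2$n_episodes[1], 0)
  # all-static waters: only censored episodes, mean undefined
  expect_true(is.na(rp2$mean_ps[6]))
  expect_equal(rp2$n_censored[6], 1)
})

test_that("density profile conserves counts and localises static waters", {
  g <- generate_jump_trajectory(pore_model(z_max = 1), ground_truth(0.5),
                                15, 60, seed = 41)
  dp <- density_profile(g$traj, c(0, 1))
  expect_equal(sum(dp$count), 15, tolerance = 1e-12)  # all waters in range
  zs <- scripted_z_traj(rep(0.55, 10), box = c(2, 2, 4))
  dp2 <- density_profile(zs, c(0, 1))
  expect_equal(sum(dp2$count > 0), 1)
  expect_equal(dp2$count[6], 1)
})

test_that("uniform occupancy gives a flat density profile", {
  pore <- pore_model(z_max = 1)
  g <- generate_jump_trajectory(pore, ground_truth(0.5), 60, 400, seed = 51)
  dp <- density_profile(g$traj, c(0, 1))
  expected <- 60 / 10  # waters spread uniformly over 10 slabs
  # per-slab occupancy is ~Binomial(60, 0.1) per frame; dwell correlation
  # (~5 frames at tau = 0.5 ps) leaves ~400/10 effective samples per slab;
  # 3.5 sigma allows for the max over 10 correlated bins
  se <- sqrt(60 * 0.1 * 0.9 / (400 / 10))
  expect_lt(max(abs(dp$count - expected)), 3.5 * se)
})

test_that("retention curve handles static, counting and censored cases", {
  # static waters inside the cutoff: R identically 1
  o <- matrix(c(1.2, 1.2, 1.2, 1.2, 1.2, 1.6), 2, 3, byrow = TRUE)
  tr <- traj_from_oxygens(rep(list(o), 8), box = c(3, 3, 3))
  tr2 <- merge_reference_sites(tr, reference_sites(matrix(c(1.2, 1.2, 1.4), 1, 3)))
  rc <- retention_curve(tr2, "resname REF", cutoff = 1, max_lag = 0.3)
  expect_true(all(rc$R == 1))
  mr <- mean_residence_from_retention(rc)
  expect_equal(mr$mean_ps, 0.3)
  expect_true(mr$censored)
  # one of two initial waters leaves at the first lag and stays out
  o1 <- o
  frames <- c(list(o1), lapply(1:3, function(i) {
    oo <- o1; oo[2, 3] <- 2.9; oo
  }))
  tr3 <- traj_from_oxygens(frames, box = c(6, 6, 6))
  tr4 <- merge_reference_sites(tr3, reference_sites(matrix(c(1.2, 1.2, 1.4), 1, 3)))
  rc2 <- retention_curve(tr4, "resname REF", cutoff = 1, max_lag = 0.1,
                         origin_stride = 10)
  expect_equal(rc2$R, c(1, 0.5))
})

test_that("survival retention never exceeds the intermittent variant", {
  g <- generate_exchange_trajectory(0.8, 200, 30, seed = 61)
  rs <- retention_curve(g$traj, "resname REF", max_lag = 1.4)
  ri <- retention_curve(g$traj, "resname REF", max_lag = 1.4,
                        mode = "intermittent")
  expect_true(all(rs$R <= ri$R + 1e-12))
  expect_equal(rs$R[1], 1)
  expect_true(all(diff(rs$R) <= 1e-12))  # survival is non-increasing
})

test_that("survival integral recovers an exponential time constant", {
  lag <- seq(0, 20, by = 0.01)
  curve <- structure(data.frame(lag_ps = lag, R = exp(-lag / 2)),
                     class = c("cw_retention", "data.frame"))
  attr(curve, "initial_n") <- 1e4
  mr <- mean_residence_from_retention(curve)
  expect_false(mr$censored)
  expect_equal(mr$mean_ps, 2, tolerance = 0.02)
  fit <- mean_residence_from_retention(curve, method = "expfit")
  expect_equal(fit$mean_ps, 2, tolerance = 1e-6)
})

test_that("a configured residence-time ratio between conditions is recovered", {
  tau_base <- 0.6
  ratio <- 2.36
  base <- generate_exchange_trajectory(1 / tau_base, 700, 170, seed = 71)
  field <- generate_exchange_trajectory(1 / (tau_base * ratio), 700, 170,
                                        seed = 72)
  est <- vapply(list(base, field), function(g) {
    rc <- retention_curve(g$traj, "resname REF", max_lag = 8,
                          origin_stride = 30)
    mean_residence_from_retention(rc)$mean_ps
  }, numeric(1))
  expect_lt(abs(est[2] / est[1] - ratio) / ratio, 0.10)
})

test_that("frequency response finds configured extrema and reports SE", {
  pore <- pore_model(z_max = 0.5)
  taus <- c("0" = 0.60, "8" = 0.50, "16" = 0.40, "24" = 0.80, "32" = 0.60)
  runs <- list()
  for (f in names(taus)) for (rep in 1:2) {
    g <- generate_jump_trajectory(pore, ground_truth(taus[[f]]), 20, 400,
                                  seed = 1000 + as.numeric(f) * 10 + rep)
    runs[[length(runs) + 1L]] <- list(field = field_spec(frequency = as.numeric(f)),
                                      traj = g$traj)
  }
  fr <- frequency_response(runs, region_spec("slab", z = c(0.1, 0.4)))
  expect_equal(attr(fr, "f_min"), 16)
  expect_equal(attr(fr, "f_max"), 24)
  expect_equal(fr$n_rep, rep(2, 5))
  expect_equal(fr$ratio_to_baseline[fr$freq_THz == 0], 1)
  # three identical replicates have zero spread
  g1 <- generate_jump_trajectory(pore, ground_truth(0.5), 10, 100, seed = 5)
  runs3 <- c(list(list(field = field_spec(frequency = 0), traj = g1$traj)),
             rep(list(list(field = field_spec(frequency = 16), traj = g1$traj)), 3))
  fr3 <- frequency_response(runs3, region_spec("slab", z = c(0.1, 0.4)))
  expect_equal(fr3$se_ps[fr3$freq_THz == 16], 0)
  # conflicting directions at one frequency are refused unless grouped
  runs_bad <- list(
    list(field = field_spec(frequency = 0), traj = g1$traj),
    list(field = field_spec(frequency = 16, direction = c(0, 0, 1)), traj = g1$traj),
    list(field = field_spec(frequency = 16, direction = c(1, 0, 0)), traj = g1$traj))
  expect_error(frequency_response(runs_bad, region_spec("slab", z = c(0.1, 0.4))),
               "conflicting")
  expect_s3_class(frequency_response(runs_bad, region_spec("slab", z = c(0.1, 0.4)),
                                     group_directions = TRUE),
                  "cw_freq_response")
})
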