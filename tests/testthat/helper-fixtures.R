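# Fixture builders shared across the suite. Everything is generated in
# code; no stored binary data.

# A trajectory of n rigid waters whose oxygen positions are supplied
# frame-by-frame; orientation fixed (dipole +z) unless dipoles given.
traj_from_oxygens <- function(o_frames, box = c(4, 4, 4), dt = 0.1,
                              dipoles = NULL, rolls = NULL) {
  n <- nrow(o_frames[[1]])
  top <- water_topology(n)
  nf <- length(o_frames)
  co <- array(NA_real_, c(3 * n, 3, nf))
  ow <- 3 * seq_len(n) - 2L
  for (f in seq_len(nf)) {
    o <- o_frames[[f]]
    dip <- if (is.null(dipoles)) matrix(rep(c(0, 0, 1), each = n), n, 3) else dipoles
    rl <- if (is.null(rolls)) rep(0, n) else rolls
    hh <- confinedwater:::water_sites_from_dipole(o, dip, rl)
    co[ow, , f] <- o
    co[ow + 1L, , f] <- hh$H1
    co[ow + 2L, , f] <- hh$H2
  }
  trajectory(top, co, box, (seq_len(nf) - 1) * dt)
}

# Single water walking through a scripted z sequence (x = y = centre).
scripted_z_traj <- function(z, box = c(2, 2, 4), dt = 0.1) {
  traj_from_oxygens(lapply(z, function(zz) matrix(c(1, 1, zz), 1, 3)),
                    box = box, dt = dt)
}

# Random rigid-water frame for oracle comparisons.
random_water_frame <- function(n, box = c(2, 2, 2), seed = 1) {
  set.seed(seed)
  o <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  ori <- generate_orientations(n, 90, 0)
  hh <- confinedwater:::water_sites_from_dipole(o, ori$dipole, ori$roll)
  co <- matrix(NA_real_, 3 * n, 3)
  ow <- 3 * seq_len(n) - 2L
  co[ow, ] <- o
  co[ow + 1L, ] <- hh$H1
  co[ow + 2L, ] <- hh$H2
  list(coords = co, top = water_topology(n), box = box)
}

# Charged point-particle topology for energy oracles.
ion_topology <- function(q, eps = NULL, sigma = NULL) {
  n <- length(q)
  if (is.null(eps)) eps <- rep(0.5, n)
  if (is.null(sigma)) sigma <- rep(0.3, n)
  topology(data.frame(name = paste0("I", seq_len(n)), element = "X",
                      resid = seq_len(n), resname = "ION", mass = 1,
                      charge = q, eps = eps, sigma = sigma,
                      stringsAsFactors = FALSE))
}

# Brute-force pairwise energy oracles (triple loop, no vectorisation).
oracle_coulomb <- function(co, q, ia, ib, box) {
  e <- 0
  for (i in ia) for (j in ib) {
    d <- co[j, ] - co[i, ]
    d <- d - box * round(d / box)
    e <- e + 138.935458 * q[i] * q[j] / sqrt(sum(d^2))
  }
  e
}

oracle_lj <- function(co, eps, sig, ia, ib, box) {
  e <- 0
  for (i in ia) for (j in ib) {
    d <- co[j, ] - co[i, ]
    d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    s <- (sig[i] + sig[j]) / 2
    ee <- sqrt(eps[i] * eps[j])
    if (ee > 0) e <- e + 4 * ee * ((s / r)^12 - (s / r)^6)
  }
  e
}

oracle_hbonds <- function(co, top, box, max_d = 0.35, max_ang = 30) {
  res <- list()
  for (d in which(top$atoms$is_donor)) for (a in which(top$atoms$is_acceptor)) {
    if (d == a) next
    dv <- co[a, ] - co[d, ]
    dv <- dv - box * round(dv / box)
    if (sqrt(sum(dv^2)) > max_d) next
    for (h in top$donor_hydrogens[[as.character(d)]]) {
      hv <- co[h, ] - co[d, ]
      hv <- hv - box * round(hv / box)
      cosang <- sum(hv * dv) / sqrt(sum(hv^2) * sum(dv^2))
      if (acos(min(1, max(-1, cosang))) * 180 / pi <= max_ang)
        res[[length(res) + 1L]] <- c(d, h, a)
    }
  }
  if (!length(res)) return(matrix(integer(0), 0, 3))
  do.call(rbind, res)
}

oracle_local_count <- function(co, top, resid_atoms, box, cutoff) {
  wt <- top$waters
  cnt <- 0
  for (w in seq_len(nrow(wt))) {
    near <- FALSE
    for (j in resid_atoms) {
      d <- co[j, ] - co[wt[w, 1], ]
      d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) <= cutoff) { near <- TRUE; break }
    }
    cnt <- cnt + near
  }
  cnt
}

# Canonical GRO text for a tiny system (used by reader tests).
tiny_gro_text <- function() {
  c("tiny water t= 0.00000",
    "    3",
    "    1SOL    OW    1   1.000   1.000   1.000",
    "    1SOL   HW1    2   1.080   1.020   1.050",
    "    1SOL   HW2    3   0.950   1.080   1.030",
    "   2.00000   2.00000   2.00000")
}
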