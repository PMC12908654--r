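#' Pore model for synthetic trajectories
#'
#' A piecewise-constant pore: the z-range `[0, z_max)` is tiled by slabs of
#' `slab_width` nm, each with a cylinder radius. The cylinder axis is +z
#' through the centre of the (square) xy cross-section.
#'
#' @param z_max Pore extent along z, nm.
#' @param slab_width Slab thickness, nm (default 0.1, the conventional
#'   slicing for residence profiles).
#' @param radius Cylinder radius per slab, nm; scalar recycled.
#' @param xy_half_width Half of the box edge in x and y, nm; default
#'   `max(radius) + 0.25`.
#' @return A `cw_pore`.
#' @export
pore_model <- function(z_max = 4, slab_width = 0.1, radius = 1,
                       xy_half_width = NULL) {
  n_slab <- round(z_max / slab_width)
  if (abs(n_slab * slab_width - z_max) > 1e-9)
    stop("z_max must be a multiple of slab_width")
  radius <- rep_len(radius, n_slab)
  if (any(radius <= 0)) stop("radii must be > 0")
  if (is.null(xy_half_width)) xy_half_width <- max(radius) + 0.25
  structure(list(z_max = z_max, slab_width = slab_width, n_slab = n_slab,
                 radius = radius, xy_half_width = xy_half_width,
                 z_breaks = seq(0, z_max, by = slab_width)),
            class = "cw_pore")
}

#' Ground truth record for a synthetic trajectory
#'
#' Emitted alongside every generated trajectory so analyses can be checked
#' against known values: per-slab mean residence times (ps), per-slab mean
#' dipole tilt (degrees from +z) with a von Mises concentration, an
#' optional exchange rate (ps^-1) around a reference site, optional
#' librational mode parameters, and the seed used.
#'
#' @param slab_residence Per-slab mean residence, ps (recycled).
#' @param slab_tilt_deg Per-slab mean dipole tilt, degrees (recycled;
#'   default 90, i.e. no axial polarisation).
#' @param slab_kappa Per-slab von Mises concentration (recycled; default 0
#'   = isotropic).
#' @param exchange_rate Exchange (exit) rate around the reference site,
#'   ps^-1, or `NULL`.
#' @param libration List with `mode`, `amplitude_deg`, `frequency_THz`, or
#'   `NULL`.
#' @param diffusivity Per-slab diffusivity, nm^2/ps (Brownian mode), or
#'   `NULL`.
#' @param seed Integer seed recorded with the record.
#' @return A `cw_truth`.
#' @export
ground_truth <- function(slab_residence = 0.43, slab_tilt_deg = 90,
                         slab_kappa = 0, exchange_rate = NULL,
                         libration = NULL, diffusivity = NULL, seed = NA) {
  if (any(slab_residence < 0) || (!is.null(exchange_rate) && exchange_rate < 0))
    stop("rates and times must be >= 0")
  structure(list(slab_residence = slab_residence,
                 slab_tilt_deg = slab_tilt_deg, slab_kappa = slab_kappa,
                 exchange_rate = exchange_rate, libration = libration,
                 diffusivity = diffusivity, seed = seed),
            class = "cw_truth")
}

#' Write / read a ground-truth record (YAML)
#'
#' The record round-trips losslessly through the file interface.
#'
#' @param truth A `cw_truth`.
#' @param path File path.
#' @return `read_ground_truth` returns a `cw_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  yaml::write_yaml(unclass(truth), path, precision = 12)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(ground_truth, x[!vapply(x, is.null, logical(1))])
}

#' Build a topology of n rigid three-site waters (TIP3P parameters)
#'
#' Residues SOL with atoms OW/HW1/HW2, full masses, charges, oxygen LJ
#' parameters and donor/acceptor flags assigned.
#'
#' @param n_waters Number of waters.
#' @return A `cw_topology` with `n_waters` disjoint triplets.
#' @export
water_topology <- function(n_waters) {
  atoms <- data.frame(
    name = rep(c("OW", "HW1", "HW2"), n_waters),
    element = rep(c("O", "H", "H"), n_waters),
    resid = rep(seq_len(n_waters), each = 3),
    resname = "SOL",
    mass = rep(c(tip3p$mass_o, tip3p$mass_h, tip3p$mass_h), n_waters),
    charge = rep(c(tip3p$q_o, tip3p$q_h, tip3p$q_h), n_waters),
    eps = rep(c(tip3p$eps_o, 0, 0), n_waters),
    sigma = rep(c(tip3p$sigma_o, 0, 0), n_waters),
    is_donor = rep(c(TRUE, FALSE, FALSE), n_waters),
    is_acceptor = rep(c(TRUE, FALSE, FALSE), n_waters),
    stringsAsFactors = FALSE)
  dh <- stats::setNames(
    lapply(seq_len(n_waters), function(w) c(3 * w - 1L, 3 * w)),
    as.character(3 * seq_len(n_waters) - 2L))
  topology(atoms, donor_hydrogens = dh)
}

# ---- orientation sampling -------------------------------------------------

# von Mises sampler, Best & Fisher (1979) rejection scheme, vectorised in
# batches. kappa = 0 -> uniform; kappa = Inf -> point mass at mu.
rvonmises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (is.infinite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.7) + 10
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    u3 <- stats::runif(m)
    th <- mu + sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
    out <- c(out, th[acc])
  }
  out[seq_len(n)] %% (2 * pi)
}

# Fold a circular angle (radians) to a polar angle in [0, pi].
fold_polar <- function(th) {
  th <- th %% (2 * pi)
  ifelse(th > pi, 2 * pi - th, th)
}

#' Sample rigid-water orientations about a mean dipole tilt
#'
#' Dipole polar angles (to +z) are drawn from a von Mises distribution
#' centred on `mean_tilt_deg` with concentration `kappa`, folded to
#' `[0, 180]` degrees; azimuth and the roll about the dipole axis are
#' uniform. `kappa = 0` gives an isotropy-like axial draw (mean cosine 0);
#' `kappa = Inf` pins every polar angle to the configured tilt. This is an
#' axial von Mises(-Fisher style) model: a modelling choice, since no
#' canonical scatter law exists for confined-water tilt.
#'
#' @param n Number of orientations.
#' @param mean_tilt_deg Mean polar angle of the dipole from +z, degrees.
#' @param kappa Concentration (>= 0, may be `Inf`).
#' @param seed Optional integer seed.
#' @return List with `dipole` (n x 3 unit vectors), `polar_deg`,
#'   `azimuth`, `roll`.
#' @export
generate_orientations <- function(n, mean_tilt_deg = 90, kappa = 0,
                                  seed = NULL) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  th <- fold_polar(rvonmises(n, mean_tilt_deg * pi / 180, kappa))
  phi <- stats::runif(n, 0, 2 * pi)
  roll <- stats::runif(n, 0, 2 * pi)
  dip <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
  list(dipole = dip, polar_deg = th * 180 / pi, azimuth = phi, roll = roll)
}

# Place rigid TIP3P H atoms for O positions `o` (n x 3 nm), unit dipole
# (bisector) directions `u` and roll angles about the bisector.
water_sites_from_dipole <- function(o, u, roll,
                                    r_oh = tip3p$r_oh_A / 10,
                                    hoh_deg = tip3p$hoh_deg) {
  o <- rbind(o); u <- rbind(u)
  n <- nrow(o)
  # reference perpendicular: use x unless u is nearly +-x, then y
  ref <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  swap <- abs(u[, 1]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  w0 <- row_cross(u, ref)
  w0 <- w0 / sqrt(rowSums(w0^2))
  v <- w0 * cos(roll) + row_cross(u, w0) * sin(roll)
  half <- hoh_deg / 2 * pi / 180
  h1 <- o + r_oh * (cos(half) * u + sin(half) * v)
  h2 <- o + r_oh * (cos(half) * u - sin(half) * v)
  list(H1 = h1, H2 = h2)
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# ---- jump-process generator ----------------------------------------------

#' Generate a compartment jump-process trajectory with known ground truth
#'
#' Each water performs a discrete-time jump process over the pore's z-slabs:
#' it dwells in slab s for a geometric number of frames with per-frame exit
#' probability `dt / tau_s` (the discrete-time exponential analogue, mean
#' dwell exactly `tau_s`), then hops to an adjacent slab, cyclically in z
#' (consistent with the periodic box; the stationary slab occupancy is
#' uniform). Within a slab the position is redrawn uniformly in the slab's
#' cylinder every frame; orientations are redrawn per frame from the slab's
#' tilt field (rotation decoupled from translation). The generator is a
#' pure function of its arguments and the seed.
#'
#' @param pore A `cw_pore`.
#' @param truth A `cw_truth`; `slab_residence`, `slab_tilt_deg` and
#'   `slab_kappa` are recycled to the slab count. All residence means must
#'   be >= `dt` (shorter dwells cannot be resolved by sampling).
#' @param n_waters,n_frames Counts.
#' @param dt Frame interval, ps (default 0.1).
#' @param seed Integer seed.
#' @return List with `traj` (a `cw_trajectory`) and `truth` (the
#'   `cw_truth` with the seed recorded).
#' @export
generate_jump_trajectory <- function(pore, truth, n_waters, n_frames,
                                     dt = 0.1, seed = 1) {
  stopifnot(inherits(pore, "cw_pore"), inherits(truth, "cw_truth"))
  if (dt <= 0) stop("dt must be > 0")
  tau <- rep_len(truth$slab_residence, pore$n_slab)
  if (any(tau < dt))
    stop("slab residence mean < dt cannot be resolved by sampling")
  tilt <- rep_len(truth$slab_tilt_deg, pore$n_slab)
  kap <- rep_len(truth$slab_kappa, pore$n_slab)
  set.seed(seed)
  slab_seq <- matrix(0L, n_waters, n_frames)
  for (w in seq_len(n_waters)) {
    t0 <- 1L
    s <- sample.int(pore$n_slab, 1L)
    while (t0 <= n_frames) {
      dwell <- stats::rgeom(1, dt / tau[s]) + 1L
      t1 <- min(n_frames, t0 + dwell - 1L)
      slab_seq[w, t0:t1] <- s
      t0 <- t1 + 1L
      # cyclic adjacent hop (periodic in z, like the box): the stationary
      # slab distribution stays uniform
      s <- if (pore$n_slab == 1L) 1L
           else 1L + (s - 1L + sample(c(-1L, 1L), 1L)) %% pore$n_slab
    }
  }
  cx <- pore$xy_half_width
  w_sl <- pore$slab_width
  nw <- n_waters; nf <- n_frames
  sl <- as.vector(slab_seq)                        # water-major within frame? no:
  # slab_seq is waters x frames; as.vector goes water-fastest per column = frame-major blocks
  z <- (sl - 1) * w_sl + stats::runif(nw * nf) * w_sl
  rr <- pore$radius[sl] * sqrt(stats::runif(nw * nf))
  aa <- stats::runif(nw * nf, 0, 2 * pi)
  o <- cbind(cx + rr * cos(aa), cx + rr * sin(aa), z)
  # orientations grouped by slab for vectorised von Mises draws
  th <- numeric(nw * nf)
  for (s in unique(sl)) {
    ii <- which(sl == s)
    th[ii] <- fold_polar(rvonmises(length(ii), tilt[s] * pi / 180, kap[s]))
  }
  phi <- stats::runif(nw * nf, 0, 2 * pi)
  roll <- stats::runif(nw * nf, 0, 2 * pi)
  dip <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
  hh <- water_sites_from_dipole(o, dip, roll)
  top <- water_topology(nw)
  box <- c(2 * pore$xy_half_width, 2 * pore$xy_half_width, pore$z_max)
  coords <- array(NA_real_, c(3 * nw, 3, nf))
  ow <- 3 * seq_len(nw) - 2L
  for (f in seq_len(nf)) {
    ii <- (f - 1L) * nw + seq_len(nw)
    coords[ow, , f] <- o[ii, ]
    coords[ow + 1L, , f] <- hh$H1[ii, ]
    coords[ow + 2L, , f] <- hh$H2[ii, ]
  }
  truth$seed <- seed
  truth$slab_residence <- tau
  list(traj = trajectory(top, coords, box, (seq_len(nf) - 1) * dt),
       truth = truth)
}

#' Generate an exponential-exchange trajectory around a static reference site
#'
#' Waters start uniformly inside a sphere of `cutoff` nm around a static
#' reference pseudo-atom at the box centre and leave it permanently with
#' per-frame probability `1 - exp(-k dt)`, so the continuous-survival
#' retention curve is exactly `exp(-k tau)` in expectation. Departed waters
#' are parked uniformly in the region outside `cutoff + 0.1` nm. The
#' reference atom is residue `REF`, selectable as `"resname REF"`.
#'
#' @param k Exit rate, ps^-1.
#' @param n_waters,n_frames Counts.
#' @param dt Frame interval, ps.
#' @param cutoff Sphere radius, nm (default 1.0).
#' @param seed Integer seed.
#' @return List with `traj` and `truth` (exchange_rate = k).
#' @export
generate_exchange_trajectory <- function(k, n_waters, n_frames, dt = 0.1,
                                         cutoff = 1.0, seed = 1) {
  if (k < 0) stop("k must be >= 0")
  set.seed(seed)
  L <- 2 * (cutoff + 0.6)
  cen <- rep(L / 2, 3)
  p_exit <- 1 - exp(-k * dt)
  inside <- matrix(TRUE, n_waters, n_frames)
  if (n_frames > 1) for (f in 2:n_frames) {
    stay <- stats::runif(n_waters) >= p_exit
    inside[, f] <- inside[, f - 1] & stay
  }
  # positions: uniform in ball while inside (radius cutoff - 0.05 margin so
  # wrapping/rounding never flips membership), parked outside after exit
  unif_ball <- function(n, r) {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    u * r * stats::runif(n)^(1 / 3)
  }
  top_w <- water_topology(n_waters)
  ref <- reference_sites(matrix(cen, 1, 3), charges = 0)
  coords <- array(NA_real_, c(3 * n_waters + 1L, 3, n_frames))
  ow <- 3 * seq_len(n_waters) - 2L
  out_r <- cutoff + 0.1
  for (f in seq_len(n_frames)) {
    o <- matrix(NA_real_, n_waters, 3)
    nin <- sum(inside[, f])
    if (nin) o[inside[, f], ] <- sweep(unif_ball(nin, cutoff - 0.05), 2, cen, `+`)
    nout <- n_waters - nin
    if (nout) {
      # park on a shell just outside the cutoff (direction uniform)
      u <- matrix(stats::rnorm(3 * nout), nout, 3)
      u <- u / sqrt(rowSums(u^2))
      o[!inside[, f], ] <- sweep(u * (out_r + 0.05), 2, cen, `+`)
    }
    ori <- cbind(0, 0, rep(1, n_waters))
    hh <- water_sites_from_dipole(o, ori, rep(0, n_waters))
    coords[ow, , f] <- o
    coords[ow + 1L, , f] <- hh$H1
    coords[ow + 2L, , f] <- hh$H2
    coords[3 * n_waters + 1L, , f] <- cen
  }
  top <- merge_topologies(top_w, ref)
  truth <- ground_truth(exchange_rate = k, seed = seed)
  list(traj = trajectory(top, coords, c(L, L, L), (seq_len(n_frames) - 1) * dt),
       truth = truth)
}

#' Generate an overdamped Brownian trajectory with per-slab diffusivity
#'
#' Waters take Gaussian steps with standard deviation `sqrt(2 D dt)` per
#' coordinate, with `D` taken from the slab at the current z. With
#' `boundary = "reflect"` positions are reflected at the slab cylinder
#' radius and the z-range ends; `boundary = "none"` gives free diffusion
#' in a periodic cube (positions stored unwrapped), for Einstein-relation
#' checks. A warning is issued if any step scale exceeds the slab width.
#'
#' @param pore A `cw_pore`.
#' @param D Diffusivity per slab, nm^2/ps (scalar recycled); must be > 0.
#' @param n_waters,n_frames Counts.
#' @param dt Frame interval, ps.
#' @param seed Integer seed.
#' @param boundary `"reflect"` or `"none"`.
#' @return List with `traj` and `truth` (diffusivity recorded).
#' @export
generate_brownian_trajectory <- function(pore, D, n_waters, n_frames,
                                         dt = 0.1, seed = 1,
                                         boundary = c("reflect", "none")) {
  boundary <- match.arg(boundary)
  D <- rep_len(D, pore$n_slab)
  if (any(D <= 0)) stop("D must be > 0 everywhere")
  if (any(sqrt(2 * D * dt) > pore$slab_width))
    warning("step length sqrt(2 D dt) exceeds the slab width ",
            pore$slab_width, " nm; slab statistics will be coarse")
  set.seed(seed)
  L <- c(2 * pore$xy_half_width, 2 * pore$xy_half_width, pore$z_max)
  cen <- pore$xy_half_width
  o <- cbind(stats::runif(n_waters, cen - 0.2, cen + 0.2),
             stats::runif(n_waters, cen - 0.2, cen + 0.2),
             stats::runif(n_waters, 0, pore$z_max))
  coords <- array(NA_real_, c(3 * n_waters, 3, n_frames))
  ow <- 3 * seq_len(n_waters) - 2L
  place <- function(o, f) {
    ori <- cbind(0, 0, rep(1, n_waters))
    hh <- water_sites_from_dipole(o, ori, rep(0, n_waters))
    coords[ow, , f] <<- o
    coords[ow + 1L, , f] <<- hh$H1
    coords[ow + 2L, , f] <<- hh$H2
  }
  place(o, 1L)
  for (f in seq_len(n_frames - 1L)) {
    zw <- if (boundary == "reflect") pmin(pmax(o[, 3], 0), pore$z_max - 1e-12)
          else o[, 3] %% pore$z_max
    sl <- pmin(pore$n_slab, pmax(1L, floor(zw / pore$slab_width) + 1L))
    sd_step <- sqrt(2 * D[sl] * dt)
    o <- o + matrix(stats::rnorm(3 * n_waters), n_waters, 3) * sd_step
    if (boundary == "reflect") {
      o[, 3] <- reflect_interval(o[, 3], 0, pore$z_max)
      dx <- o[, 1] - cen; dy <- o[, 2] - cen
      r <- sqrt(dx^2 + dy^2)
      rmax <- pore$radius[pmin(pore$n_slab,
                               pmax(1L, floor(o[, 3] / pore$slab_width) + 1L))]
      over <- r > rmax
      if (any(over)) {
        scale <- (2 * rmax[over] - r[over]) / r[over]
        scale[scale < 0] <- 0
        o[over, 1] <- cen + dx[over] * scale
        o[over, 2] <- cen + dy[over] * scale
      }
    }
    place(o, f + 1L)
  }
  truth <- ground_truth(diffusivity = D, seed = seed)
  list(traj = trajectory(water_topology(n_waters), coords, L,
                         (seq_len(n_frames) - 1) * dt),
       truth = truth)
}

reflect_interval <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

# ---- libration ------------------------------------------------------------

#' Superimpose a sinusoidal librational oscillation on rigid waters
#'
#' Adds a rigid-body rotation of angle `A sin(2 pi f t + phi_w)` about the
#' chosen mode axis through each water's centre of mass: rock rotates about
#' the normal to the molecular plane, twist about the H-O-H bisector, wag
#' about the in-plane axis perpendicular to the bisector. The phase
#' `phi_w` is random per molecule (avoids ensemble coherence); O-H bond
#' lengths and the H-O-H angle are untouched (rigid rotation).
#'
#' @param traj A `cw_trajectory` containing rigid waters.
#' @param mode `"rock"`, `"twist"` or `"wag"`.
#' @param amplitude_deg Oscillation amplitude, degrees.
#' @param frequency_THz Oscillation frequency, THz (cycles/ps).
#' @param seed Integer seed for the per-molecule phases.
#' @return The modified `cw_trajectory`.
#' @export
add_libration <- function(traj, mode = c("rock", "twist", "wag"),
                          amplitude_deg, frequency_THz, seed = 1) {
  mode <- match.arg(mode)
  wt <- traj$topology$waters
  if (!nrow(wt)) stop("trajectory has no rigid waters")
  if (amplitude_deg == 0) return(traj)
  set.seed(seed)
  nw <- nrow(wt)
  phase <- stats::runif(nw, 0, 2 * pi)
  A <- amplitude_deg * pi / 180
  mo <- traj$topology$atoms$mass[wt[, 1]]
  mh <- traj$topology$atoms$mass[wt[, 2]]
  mo[is.na(mo)] <- tip3p$mass_o
  mh[is.na(mh)] <- tip3p$mass_h
  M <- mo + 2 * mh
  for (f in seq_len(n_frames(traj))) {
    O <- matrix(traj$coords[wt[, 1], , f], ncol = 3)
    H1 <- matrix(traj$coords[wt[, 2], , f], ncol = 3)
    H2 <- matrix(traj$coords[wt[, 3], , f], ncol = 3)
    b1 <- H1 - O; b2 <- H2 - O
    normal <- row_cross(b1, b2)
    normal <- normal / sqrt(rowSums(normal^2))
    bis <- b1 + b2
    bis <- bis / sqrt(rowSums(bis^2))
    axis <- switch(mode,
                   rock = normal,
                   twist = bis,
                   wag = row_cross(normal, bis))
    ang <- A * sin(2 * pi * frequency_THz * traj$times[f] + phase)
    com <- (O * mo + (H1 + H2) * mh) / M
    traj$coords[wt[, 1], , f] <- com + rodrigues(O - com, axis, ang)
    traj$coords[wt[, 2], , f] <- com + rodrigues(H1 - com, axis, ang)
    traj$coords[wt[, 3], , f] <- com + rodrigues(H2 - com, axis, ang)
  }
  traj
}

# Row-wise Rodrigues rotation of vectors x about unit axes k by angles a.
rodrigues <- function(x, k, a) {
  ca <- cos(a); sa <- sin(a)
  kdx <- rowSums(k * x)
  x * ca + row_cross(k, x) * sa + k * kdx * (1 - ca)
}

# ---- reference sites ------------------------------------------------------

#' Static pseudo-residue reference sites
#'
#' Builds a topology fragment of point sites (one residue per site, atom
#' name `RF`, residue `REF` by default) with given charges and LJ
#' parameters, mergeable into any generated system as stand-ins for pore
#' residues.
#'
#' @param positions n x 3 matrix of site positions, nm (stored with the
#'   fragment as attribute `positions`).
#' @param charges,epsilon,sigma Per-site parameters (recycled).
#' @param resname Residue name (default `"REF"`).
#' @return A `cw_topology` fragment with attribute `positions`.
#' @export
reference_sites <- function(positions, charges = 0, epsilon = 0, sigma = 0,
                            resname = "REF") {
  positions <- rbind(positions)
  n <- nrow(positions)
  atoms <- data.frame(name = "RF", element = "X",
                      resid = seq_len(n), resname = resname,
                      mass = 100, charge = rep_len(charges, n),
                      eps = rep_len(epsilon, n), sigma = rep_len(sigma, n),
                      is_donor = FALSE, is_acceptor = FALSE,
                      stringsAsFactors = FALSE)
  out <- topology(atoms)
  attr(out, "positions") <- positions
  out
}

#' Merge two topologies (atoms of `b` appended after `a`)
#'
#' Residue ids of `b` are shifted past `a`'s maximum so merged residues
#' stay unique within their residue names.
#'
#' @param a,b `cw_topology` objects.
#' @return A merged `cw_topology`.
#' @export
merge_topologies <- function(a, b) {
  off <- nrow(a$atoms)
  bat <- b$atoms
  bat$resid <- bat$resid + max(a$atoms$resid)
  atoms <- rbind(a$atoms[, setdiff(names(a$atoms), "index")],
                 bat[, setdiff(names(bat), "index")])
  wat <- rbind(a$waters, b$waters + off)
  dh <- c(a$donor_hydrogens,
          stats::setNames(lapply(b$donor_hydrogens, `+`, off),
                          as.character(as.integer(names(b$donor_hydrogens)) + off)))
  topology(atoms, waters = wat, groups = a$groups, donor_hydrogens = dh)
}

#' Merge static reference sites into a trajectory
#'
#' Appends the site atoms (constant positions) to every frame. An error is
#' raised if a site lies within `min_sep` nm of an existing atom in the
#' first frame (overlapping sites are unphysical).
#'
#' @param traj A `cw_trajectory`.
#' @param sites A fragment from [reference_sites()].
#' @param min_sep Overlap threshold, nm (default 0.05).
#' @return A new `cw_trajectory` including the sites.
#' @export
merge_reference_sites <- function(traj, sites, min_sep = 0.05) {
  pos <- attr(sites, "positions")
  if (is.null(pos)) stop("sites fragment has no positions")
  d <- min_image_dist(pos, frame_coords(traj, 1), traj$box[1, ])
  if (any(d < min_sep))
    stop(sprintf("reference site overlaps an existing atom (< %.3f nm)", min_sep))
  top <- merge_topologies(traj$topology, sites)
  nf <- n_frames(traj)
  co <- array(NA_real_, c(nrow(top$atoms), 3, nf))
  co[seq_len(dim(traj$coords)[1]), , ] <- traj$coords
  for (f in seq_len(nf)) co[dim(traj$coords)[1] + seq_len(nrow(pos)), , f] <- pos
  trajectory(top, co, traj$box, traj$times)
}
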