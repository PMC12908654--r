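#' Water dipole unit vectors for one frame
#'
#' The molecular dipole of a three-site water, `mu = sum q_i r_i`, lies
#' along the H-O-H bisector and points from the oxygen toward the
#' hydrogens (for the standard negative-O / positive-H charges). Hydrogen
#' positions are minimum-imaged relative to the oxygen so molecules split
#' across the box boundary stay whole. Collinear (degenerate) geometries
#' are an error.
#'
#' @param coords Frame positions, n_atoms x 3 (nm).
#' @param top A `cw_topology` with water triplets; charges default to the
#'   rigid three-site values when unassigned.
#' @param box Box edges (nm) for the minimum-image correction.
#' @return List with `unit` (n_waters x 3 unit vectors) and
#'   `magnitude_e_nm` (|mu| before normalisation, e nm).
#' @export
water_dipoles <- function(coords, top, box) {
  wt <- top$waters
  if (!nrow(wt)) stop("topology has no waters")
  qo <- top$atoms$charge[wt[, 1]]
  qh1 <- top$atoms$charge[wt[, 2]]
  qh2 <- top$atoms$charge[wt[, 3]]
  qo[is.na(qo)] <- tip3p$q_o
  qh1[is.na(qh1)] <- tip3p$q_h
  qh2[is.na(qh2)] <- tip3p$q_h
  O <- coords[wt[, 1], , drop = FALSE]
  d1 <- min_image(O, coords[wt[, 2], , drop = FALSE], box)
  d2 <- min_image(O, coords[wt[, 3], , drop = FALSE], box)
  # with O at the origin of each molecule: mu = q_h1 d1 + q_h2 d2
  mu <- d1 * qh1 + d2 * qh2
  dimnames(mu) <- NULL
  mag <- as.numeric(sqrt(rowSums(mu^2)))
  cross <- row_cross(d1, d2)
  if (any(rowSums(cross^2) < 1e-20))
    stop("degenerate (collinear) water geometry: dipole direction undefined")
  list(unit = mu / mag, magnitude_e_nm = mag)
}

#' Dipole-orientation profile along the pore axis
#'
#' Per z-bin mean of the angle between the water dipole and +z (degrees,
#' in [0, 180]; not folded) with the circular spread (angular deviation)
#' and sample count. Bins without samples are `NA`-flagged.
#'
#' @param traj A `cw_trajectory`.
#' @param z_range `c(z_lo, z_hi)`, nm; default full box.
#' @param bin Bin width, nm (default 0.1).
#' @param region Optional `cw_region` restricting which waters count.
#' @return A `cw_dipole_profile`: data.frame `z_nm`, `mean_deg`,
#'   `spread_deg`, `n`.
#' @export
dipole_angle_profile <- function(traj, z_range = NULL, bin = 0.1,
                                 region = NULL) {
  Lz <- traj$box[1, 3]
  if (is.null(z_range)) z_range <- c(0, Lz)
  nb <- max(1L, round(diff(z_range) / bin))
  breaks <- z_range[1] + (0:nb) * bin
  wt <- traj$topology$waters
  ang_all <- vector("list", n_frames(traj))
  bin_all <- vector("list", n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, f)
    dip <- water_dipoles(co, traj$topology, traj$box[f, ])
    ow <- wrap_positions(co[wt[, 1], , drop = FALSE], traj$box[f, ])
    keep <- rep(TRUE, nrow(wt))
    if (!is.null(region))
      keep <- region_membership(region, co[wt[, 1], , drop = FALSE],
                                traj$box[f, ], traj$topology, co)
    ix <- floor((ow[, 3] - z_range[1]) / bin) + 1L
    keep <- keep & ix >= 1L & ix <= nb
    ang_all[[f]] <- acos(pmin(1, pmax(-1, dip$unit[keep, 3]))) * 180 / pi
    bin_all[[f]] <- ix[keep]
  }
  ang <- unlist(ang_all); ib <- unlist(bin_all)
  mean_deg <- spread_deg <- rep(NA_real_, nb)
  n <- tabulate(ib, nbins = nb)
  for (b in which(n > 0)) {
    a <- ang[ib == b]
    mean_deg[b] <- mean(a)
    spread_deg[b] <- if (length(a) >= 2) circular_spread_deg(a) else 0
  }
  out <- data.frame(z_nm = (breaks[-1] + breaks[-(nb + 1)]) / 2,
                    mean_deg = mean_deg, spread_deg = spread_deg, n = n)
  class(out) <- c("cw_dipole_profile", "data.frame")
  out
}

#' @export
print.cw_dipole_profile <- function(x, ...) {
  cat(sprintf("<cw_dipole_profile> %d bins, %d samples\n", nrow(x), sum(x$n)))
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("...\n")
  invisible(x)
}

#' H-H vectors of all waters in one frame
#'
#' Vector from H1 to H2 with the minimum-image correction; magnitude is
#' ~0.15139 nm for rigid three-site water. Swapping the hydrogen labels
#' only flips the sign.
#'
#' @param coords Frame positions, n_atoms x 3 (nm).
#' @param top A `cw_topology` with water triplets.
#' @param box Box edges, nm.
#' @return n_waters x 3 matrix, nm.
#' @export
hh_vectors <- function(coords, top, box) {
  wt <- top$waters
  min_image(coords[wt[, 2], , drop = FALSE], coords[wt[, 3], , drop = FALSE], box)
}

#' 2D histogram of H-H vector components on a Cartesian plane
#'
#' Collects the two named components of every in-region water's H-H
#' vector over all frames. Because H1/H2 labelling is arbitrary, each
#' vector is oriented so its first-axis component is >= 0 (head-tail
#' symmetry removed); the spread metric per axis is then well defined.
#'
#' @param traj A `cw_trajectory`.
#' @param region Optional `cw_region` restricting waters.
#' @param plane `"xz"` (default), `"xy"` or `"yz"`.
#' @param bin Histogram bin width, nm (default 0.01).
#' @param lim Half-range of the histogram, nm (default 0.16, just past the
#'   rigid H-H length).
#' @return A `cw_hh_hist`: list with `counts` (matrix), `c1`, `c2` (bin
#'   centres, nm), `plane`, `spread_nm` (per-axis SD of the components)
#'   and `n` (sample count; equals `sum(counts)`).
#' @export
hh_plane_histogram <- function(traj, region = NULL, plane = c("xz", "xy", "yz"),
                               bin = 0.01, lim = 0.16) {
  plane <- match.arg(plane)
  ax <- switch(plane, xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L))
  cs <- vector("list", n_frames(traj))
  wt <- traj$topology$waters
  for (f in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, f)
    hh <- hh_vectors(co, traj$topology, traj$box[f, ])
    keep <- rep(TRUE, nrow(hh))
    if (!is.null(region))
      keep <- region_membership(region, co[wt[, 1], , drop = FALSE],
                                traj$box[f, ], traj$topology, co)
    v <- hh[keep, , drop = FALSE][, ax, drop = FALSE]
    flip <- v[, 1] < 0
    v[flip, ] <- -v[flip, ]
    cs[[f]] <- v
  }
  v <- do.call(rbind, cs)
  breaks <- seq(-lim, lim, by = bin)
  nb <- length(breaks) - 1L
  i1 <- findInterval(v[, 1], breaks, rightmost.closed = TRUE)
  i2 <- findInterval(v[, 2], breaks, rightmost.closed = TRUE)
  ok <- i1 >= 1L & i1 <= nb & i2 >= 1L & i2 <= nb
  counts <- matrix(0L, nb, nb)
  tab <- table(factor(i1[ok], levels = 1:nb), factor(i2[ok], levels = 1:nb))
  counts <- matrix(as.integer(tab), nb, nb)
  cent <- (breaks[-1] + breaks[-(nb + 1)]) / 2
  structure(list(counts = counts, c1 = cent, c2 = cent, plane = plane,
                 spread_nm = apply(v, 2, stats::sd), n = nrow(v)),
            class = "cw_hh_hist")
}

#' @export
print.cw_hh_hist <- function(x, ...) {
  cat(sprintf("<cw_hh_hist> plane %s, %d samples, spread (%.4f, %.4f) nm\n",
              x$plane, x$n, x$spread_nm[1], x$spread_nm[2]))
  invisible(x)
}

#' Spread of orientation samples
#'
#' For angles (degrees): the circular angular deviation
#' `sqrt(2 (1 - Rbar)) * 180/pi`, where `Rbar` is the mean resultant
#' length — bounded by `sqrt(2)` rad (~81.03 deg), attained for balanced
#' antipodal samples; robust to the 0/360 wrap unlike a naive SD. For
#' vector components (nm): the ordinary standard deviation.
#'
#' @param samples Numeric vector (degrees or nm), length >= 2.
#' @param type `"angle"` or `"component"`.
#' @return Spread in the input's units.
#' @export
orientation_spread <- function(samples, type = c("angle", "component")) {
  type <- match.arg(type)
  if (length(samples) < 2) stop("need at least 2 samples")
  if (type == "component") return(stats::sd(samples))
  circular_spread_deg(samples)
}

circular_spread_deg <- function(angles_deg) {
  th <- angles_deg * pi / 180
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  sqrt(2 * (1 - rbar)) * 180 / pi
}
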