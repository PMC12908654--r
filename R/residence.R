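#' Occupancy episodes of waters in regions
#'
#' An episode is a maximal run of consecutive frames during which a
#' water's oxygen stays inside a region; leaving and re-entering starts a
#' new episode. Episodes touching the first or last frame are flagged
#' censored (their true duration is unobserved). Durations follow the
#' inclusive-frame convention `(end - start + 1) * frame_interval`.
#'
#' @param traj A `cw_trajectory` with at least one frame and waters.
#' @param regions A `cw_region` or list of them.
#' @return A data.frame with columns `water`, `region`, `start_frame`,
#'   `end_frame`, `duration` (ps) and `censored`.
#' @export
compute_episodes <- function(traj, regions) {
  if (inherits(regions, "cw_region")) regions <- list(regions)
  nf <- n_frames(traj)
  if (nf == 0) stop("empty trajectory")
  dt <- traj$frame_interval
  if (is.na(dt)) dt <- 1  # single frame: durations in frame units
  wt <- traj$topology$waters
  if (!nrow(wt)) stop("trajectory has no waters")
  out <- list()
  for (rg in regions) {
    inside <- matrix(FALSE, nrow(wt), nf)
    for (f in seq_len(nf)) {
      co <- frame_coords(traj, f)
      inside[, f] <- region_membership(rg, co[wt[, 1], , drop = FALSE],
                                       traj$box[f, ], traj$topology, co)
    }
    out[[length(out) + 1L]] <- episodes_from_mask(inside, rg$id, dt)
  }
  do.call(rbind, out)
}

# Runs of TRUE per row of a logical mask -> episode table.
episodes_from_mask <- function(inside, region_id, dt) {
  nf <- ncol(inside)
  eps <- lapply(seq_len(nrow(inside)), function(w) {
    r <- rle(inside[w, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(water = w, region = region_id,
               start_frame = starts[keep], end_frame = ends[keep])
  })
  ep <- do.call(rbind, eps)
  if (is.null(ep))
    return(data.frame(water = integer(0), region = character(0),
                      start_frame = integer(0), end_frame = integer(0),
                      duration = numeric(0), censored = logical(0)))
  ep$duration <- (ep$end_frame - ep$start_frame + 1L) * dt
  ep$censored <- ep$start_frame == 1L | ep$end_frame == nf
  rownames(ep) <- NULL
  ep
}

#' Slab residence-time profile along the pore axis
#'
#' Tiles `z_range` with slabs of `slab_width` nm (0.1 nm by default), finds
#' every water-oxygen occupancy episode per slab, and reports the per-slab
#' mean of uncensored episode durations together with episode counts and
#' the time-averaged occupancy density. Censored episodes never enter the
#' mean (they would bias it downward) but are counted. Slabs without any
#' uncensored episode get `NA` means — flagged, never silently zero.
#'
#' @param traj A `cw_trajectory`.
#' @param z_range `c(z_lo, z_hi)` in nm; default the full box height.
#'   Must lie within the box.
#' @param slab_width Slab thickness, nm (default 0.1).
#' @return A `cw_residence_profile`: data.frame with `z_nm` (bin centres),
#'   `mean_ps`, `n_episodes`, `n_censored`, `density` (waters/nm).
#' @export
residence_profile <- function(traj, z_range = NULL, slab_width = 0.1) {
  if (slab_width <= 0) stop("slab_width must be > 0")
  Lz <- traj$box[1, 3]
  if (is.null(z_range)) z_range <- c(0, Lz)
  if (z_range[1] < 0 || z_range[2] > Lz + 1e-9)
    stop("z_range outside the box [0, ", Lz, "]")
  nf <- n_frames(traj)
  if (nf == 0) stop("empty trajectory")
  dt <- traj$frame_interval
  if (is.na(dt)) dt <- 1
  wt <- traj$topology$waters
  if (!nrow(wt)) stop("trajectory has no waters")
  nb <- max(1L, round(diff(z_range) / slab_width))
  breaks <- z_range[1] + (0:nb) * slab_width
  # slab index per water per frame; 0 = outside z_range
  zmat <- matrix(NA_real_, nrow(wt), nf)
  for (f in seq_len(nf)) {
    z <- wrap_positions(matrix(traj$coords[wt[, 1], , f], ncol = 3),
                        traj$box[f, ])[, 3]
    zmat[, f] <- z
  }
  slab <- floor((zmat - z_range[1]) / slab_width) + 1L
  slab[zmat < z_range[1] | zmat >= breaks[nb + 1L]] <- 0L
  sums <- numeric(nb); n_ep <- integer(nb); n_cen <- integer(nb)
  for (w in seq_len(nrow(wt))) {
    r <- rle(slab[w, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values > 0L
    if (!any(keep)) next
    s <- r$values[keep]
    cen <- starts[keep] == 1L | ends[keep] == nf
    dur <- r$lengths[keep] * dt
    for (i in seq_along(s)) {
      if (cen[i]) n_cen[s[i]] <- n_cen[s[i]] + 1L
      else { sums[s[i]] <- sums[s[i]] + dur[i]; n_ep[s[i]] <- n_ep[s[i]] + 1L }
    }
  }
  occ <- tabulate(slab[slab > 0L], nbins = nb) / nf
  out <- data.frame(z_nm = (breaks[-1] + breaks[-(nb + 1)]) / 2,
                    mean_ps = ifelse(n_ep > 0, sums / pmax(n_ep, 1L), NA_real_),
                    n_episodes = n_ep, n_censored = n_cen,
                    density = occ / slab_width)
  class(out) <- c("cw_residence_profile", "data.frame")
  attr(out, "slab_width") <- slab_width
  attr(out, "frame_interval") <- dt
  out
}

#' @export
print.cw_residence_profile <- function(x, ...) {
  cat(sprintf("<cw_residence_profile> %d slabs of %.3g nm; mean residence %s ps (defined bins)\n",
              nrow(x), attr(x, "slab_width"),
              signif(mean(x$mean_ps, na.rm = TRUE), 3)))
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("...\n")
  invisible(x)
}

#' Time-averaged axial density profile of water oxygens
#'
#' @param traj A `cw_trajectory`.
#' @param z_range `c(z_lo, z_hi)`, nm; default full box.
#' @param bin Bin width, nm.
#' @return Data.frame with `z_nm`, `count` (mean oxygens per frame in the
#'   bin) and `density` (waters/nm). The bin `count` column sums to the
#'   mean in-range water count.
#' @export
density_profile <- function(traj, z_range = NULL, bin = 0.1) {
  Lz <- traj$box[1, 3]
  if (is.null(z_range)) z_range <- c(0, Lz)
  nb <- max(1L, round(diff(z_range) / bin))
  breaks <- z_range[1] + (0:nb) * bin
  wt <- traj$topology$waters
  nf <- n_frames(traj)
  counts <- numeric(nb)
  for (f in seq_len(nf)) {
    z <- wrap_positions(matrix(traj$coords[wt[, 1], , f], ncol = 3),
                        traj$box[f, ])[, 3]
    ix <- floor((z - z_range[1]) / bin) + 1L
    ix <- ix[ix >= 1L & ix <= nb]
    counts <- counts + tabulate(ix, nbins = nb)
  }
  data.frame(z_nm = (breaks[-1] + breaks[-(nb + 1)]) / 2,
             count = counts / nf, density = counts / nf / bin)
}

#' Retention (survival) curve around a reference selection
#'
#' Fraction of waters, among those inside a sphere of `cutoff` nm around
#' the per-frame centroid of `reference` at a time origin, that have
#' remained *continuously* inside up to lag tau (survival convention),
#' averaged over multiple time origins. The intermittent alternative
#' (present at origin and at lag, regardless of excursions) is available
#' via `mode = "intermittent"`; it bounds the survival curve from above.
#'
#' @param traj A `cw_trajectory`.
#' @param reference Selection string or atom index vector.
#' @param cutoff Sphere radius, nm (default 1.0).
#' @param max_lag Maximum lag, ps; default half the trajectory length.
#' @param origin_stride Use every k-th eligible frame as an origin.
#' @param mode `"survival"` (default) or `"intermittent"`.
#' @return A `cw_retention`: data.frame `lag_ps`, `R`, with attributes
#'   `initial_n` (summed origin populations) and `mode`.
#' @export
retention_curve <- function(traj, reference, cutoff = 1.0, max_lag = NULL,
                            origin_stride = 1L,
                            mode = c("survival", "intermittent")) {
  mode <- match.arg(mode)
  nf <- n_frames(traj)
  dt <- traj$frame_interval
  if (is.na(dt)) dt <- 1
  if (is.null(max_lag)) max_lag <- floor((nf - 1) / 2) * dt
  L <- round(max_lag / dt)
  if (L < 1 || L > nf - 1) stop("max_lag must give 1..n_frames-1 lag frames")
  wt <- traj$topology$waters
  ref_idx <- resolve_selection(traj$topology, reference)
  if (!length(ref_idx)) stop("reference selects no atoms")
  inside <- matrix(FALSE, nrow(wt), nf)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    cen <- colMeans(rbind(co[ref_idx, , drop = FALSE]))
    d <- min_image_dist(co[wt[, 1], , drop = FALSE], matrix(cen, 1, 3),
                        traj$box[f, ])
    inside[, f] <- d[, 1] <= cutoff
  }
  origins <- seq(1L, nf - L, by = origin_stride)
  retained <- numeric(L + 1)
  n0_total <- 0
  for (t0 in origins) {
    sel <- which(inside[, t0])
    if (!length(sel)) next
    blk <- inside[sel, t0:(t0 + L), drop = FALSE]
    if (mode == "survival") {
      surv <- t(apply(blk, 1, cumprod))
      retained <- retained + colSums(surv)
    } else {
      retained <- retained + colSums(blk)
    }
    n0_total <- n0_total + length(sel)
  }
  if (n0_total == 0) stop("no water inside the cutoff at any origin")
  out <- data.frame(lag_ps = (0:L) * dt, R = retained / n0_total)
  class(out) <- c("cw_retention", "data.frame")
  attr(out, "initial_n") <- n0_total
  attr(out, "mode") <- mode
  out
}

#' @export
print.cw_retention <- function(x, ...) {
  cat(sprintf("<cw_retention> %s convention, %d lags to %.3g ps, pooled origin population %d\n",
              attr(x, "mode"), nrow(x) - 1, max(x$lag_ps), attr(x, "initial_n")))
  invisible(x)
}

#' Mean residence time from a retention curve
#'
#' Default estimator: the trapezoidal integral of R(tau) over the observed
#' window (for an exponential curve this converges to the time constant).
#' If `R` at the longest lag still exceeds 0.05 the integral is a lower
#' bound and the result is flagged right-censored. An exponential-fit
#' alternative (`method = "expfit"`, least squares on log R over R > 0) is
#' provided because the survival-integral vs fitted-time-constant choice
#' is a genuine convention split.
#'
#' @param curve A `cw_retention`.
#' @param method `"integral"` (default) or `"expfit"`.
#' @return List with `mean_ps` and `censored`.
#' @export
mean_residence_from_retention <- function(curve,
                                          method = c("integral", "expfit")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "cw_retention"))
  lag <- curve$lag_ps; R <- curve$R
  tau <- if (method == "integral") {
    sum(diff(lag) * (utils::head(R, -1) + utils::tail(R, -1)) / 2)
  } else {
    ok <- R > 0
    stats::coef(stats::lm(log(R[ok]) ~ lag[ok]))[[2]]^-1 * -1
  }
  list(mean_ps = tau, censored = R[length(R)] > 0.05)
}

#' Frequency-response table of mean residence times
#'
#' Combines labelled runs (field specification + trajectory) into a table
#' of mean in-region residence time per field frequency, with the standard
#' error over replicate runs. Frequency 0 is the field-free baseline; the
#' ratio of each row to the baseline is reported, and the field
#' frequencies minimising / maximising the mean residence are attached as
#' attributes.
#'
#' @param runs List of lists with elements `field` (`cw_field`) and `traj`
#'   (`cw_trajectory`).
#' @param region A `cw_region` giving where residence is measured.
#' @param group_directions If `FALSE` (default), two runs at the same
#'   frequency but different field directions are an error; set `TRUE` to
#'   pool them.
#' @return A `cw_freq_response`: data.frame `freq_THz`, `mean_ps`, `se_ps`,
#'   `n_rep`, `ratio_to_baseline`, sorted by frequency, with attributes
#'   `f_min` and `f_max` (THz, over field rows).
#' @export
frequency_response <- function(runs, region, group_directions = FALSE) {
  freqs <- vapply(runs, function(r) r$field$frequency, numeric(1))
  if (!any(freqs == 0)) stop("need at least one field-free (0 THz) run as baseline")
  if (!group_directions) {
    for (f in unique(freqs)) {
      dirs <- lapply(runs[freqs == f], function(r) r$field$direction)
      if (length(dirs) > 1) {
        ref <- dirs[[1]]
        if (any(vapply(dirs, function(d) max(abs(d - ref)) > 1e-9, logical(1))))
          stop("runs at ", f, " THz have conflicting field directions; ",
               "set group_directions = TRUE to pool them")
      }
    }
  }
  per_run <- vapply(runs, function(r) {
    ep <- compute_episodes(r$traj, region)
    ok <- !ep$censored
    if (!any(ok)) return(NA_real_)
    mean(ep$duration[ok])
  }, numeric(1))
  agg <- lapply(sort(unique(freqs)), function(f) {
    v <- per_run[freqs == f]
    v <- v[!is.na(v)]
    data.frame(freq_THz = f, mean_ps = mean(v),
               se_ps = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n_rep = length(v))
  })
  out <- do.call(rbind, agg)
  base <- out$mean_ps[out$freq_THz == 0][1]
  out$ratio_to_baseline <- out$mean_ps / base
  class(out) <- c("cw_freq_response", "data.frame")
  fld <- out[out$freq_THz > 0, ]
  if (nrow(fld)) {
    attr(out, "f_min") <- fld$freq_THz[which.min(fld$mean_ps)]
    attr(out, "f_max") <- fld$freq_THz[which.max(fld$mean_ps)]
  }
  out
}

#' @export
print.cw_freq_response <- function(x, ...) {
  cat("<cw_freq_response>\n")
  print.data.frame(as.data.frame(x))
  if (!is.null(attr(x, "f_min")))
    cat(sprintf("residence minimised at %g THz, maximised at %g THz\n",
                attr(x, "f_min"), attr(x, "f_max")))
  invisible(x)
}
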