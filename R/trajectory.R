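#' Construct a trajectory
#'
#' Frames of positions bound to a topology. Positions are stored as an
#' `n_atoms x 3 x n_frames` array in nm, exactly as read (unwrapped if the
#' source was unwrapped); analyses apply the minimum-image convention or
#' wrap on demand.
#'
#' @param topology A `cw_topology`.
#' @param coords Numeric array `n_atoms x 3 x n_frames`, nm.
#' @param box Numeric `n_frames x 3` matrix (or length-3 vector recycled)
#'   of orthorhombic box edges, nm.
#' @param times Frame time stamps, ps; must be strictly increasing.
#' @return An object of class `cw_trajectory` with a `frame_interval`
#'   element (ps; `NA` for a single frame, with a warning suppressed).
#' @export
trajectory <- function(topology, coords, box, times) {
  stopifnot(inherits(topology, "cw_topology"))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  n_at <- dim(coords)[1]; n_fr <- dim(coords)[3]
  if (n_at != nrow(topology$atoms))
    stop(sprintf("coordinate atom count (%d) != topology atom count (%d)",
                 n_at, nrow(topology$atoms)))
  if (is.null(dim(box))) box <- matrix(box, n_fr, 3, byrow = TRUE)
  if (nrow(box) == 1L && n_fr > 1L) box <- box[rep(1L, n_fr), , drop = FALSE]
  if (any(box <= 0)) stop("box edges must be positive")
  if (length(times) != n_fr) stop("times length != frame count")
  if (n_fr > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("frame times must be strictly increasing")
    frame_interval <- dt[1]
    if (any(abs(dt - frame_interval) > 1e-6))
      stop("frame times are not evenly spaced (tolerance 1e-6 ps)")
  } else {
    frame_interval <- NA_real_
  }
  structure(list(topology = topology, coords = coords, box = box,
                 times = as.numeric(times), frame_interval = frame_interval),
            class = "cw_trajectory")
}

#' @export
print.cw_trajectory <- function(x, ...) {
  cat(sprintf("<cw_trajectory> %d atoms x %d frames, dt = %s ps, box %s nm\n",
              dim(x$coords)[1], n_frames(x),
              format(x$frame_interval), paste(signif(x$box[1, ], 4), collapse = " x ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `cw_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame's positions
#' @param traj A `cw_trajectory`.
#' @param i Frame index (1-based).
#' @return n_atoms x 3 matrix, nm.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$coords[, , i], ncol = 3)
}

#' Subset a trajectory by frames
#' @param traj A `cw_trajectory`.
#' @param frames Integer frame indices to keep (in order).
#' @export
subset_frames <- function(traj, frames) {
  trajectory(traj$topology, traj$coords[, , frames, drop = FALSE],
             traj$box[frames, , drop = FALSE], traj$times[frames])
}
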