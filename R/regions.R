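#' Define a geometric analysis region
#'
#' Regions along the pore axis (taken as +z): an axial slab `[z_lo, z_hi)`,
#' a cylinder (axis parallel to z through a centre point, with a radius and
#' z-range), or a sphere of given radius around the per-frame centroid of a
#' reference atom selection.
#'
#' @param kind `"slab"`, `"cylinder"` or `"sphere"`.
#' @param z For slab/cylinder: `c(z_lo, z_hi)` in nm, `z_lo < z_hi`.
#' @param center For cylinder: `c(x, y)` of the axis, nm.
#' @param radius For cylinder/sphere: radius in nm (> 0).
#' @param reference For sphere: selection string or atom index vector whose
#'   centroid is the sphere centre, recomputed each frame.
#' @param id Optional region label.
#' @return A `cw_region`.
#' @export
region_spec <- function(kind = c("slab", "cylinder", "sphere"), z = NULL,
                        center = c(0, 0), radius = NULL, reference = NULL,
                        id = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("slab", "cylinder")) {
    if (is.null(z) || length(z) != 2 || z[1] >= z[2])
      stop("need z = c(z_lo, z_hi) with z_lo < z_hi")
  }
  if (kind %in% c("cylinder", "sphere")) {
    if (is.null(radius) || radius <= 0) stop("radius must be > 0")
  }
  if (kind == "sphere" && is.null(reference))
    stop("sphere region needs a reference selection")
  if (is.null(id))
    id <- switch(kind,
                 slab = sprintf("slab[%.3f,%.3f)", z[1], z[2]),
                 cylinder = sprintf("cyl r%.2f [%.3f,%.3f)", radius, z[1], z[2]),
                 sphere = sprintf("sphere r%.2f", radius))
  structure(list(kind = kind, z = z, center = center, radius = radius,
                 reference = reference, id = id), class = "cw_region")
}

#' @export
print.cw_region <- function(x, ...) {
  cat("<cw_region>", x$id, "\n"); invisible(x)
}

# Membership of positions (n x 3, nm) in a region for one frame.
# Coordinates are wrapped into the primary box first (documented default
# for region tests); sphere membership uses minimum-image distance to the
# reference centroid.
region_membership <- function(region, pos, box, top = NULL, coords_frame = NULL) {
  pos <- wrap_positions(rbind(pos), box)
  if (region$kind == "slab") {
    return(pos[, 3] >= region$z[1] & pos[, 3] < region$z[2])
  }
  if (region$kind == "cylinder") {
    inz <- pos[, 3] >= region$z[1] & pos[, 3] < region$z[2]
    dx <- pos[, 1] - region$center[1]
    dy <- pos[, 2] - region$center[2]
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    return(inz & (dx^2 + dy^2) <= region$radius^2)
  }
  # sphere: centroid of the reference selection in this frame
  ref_idx <- resolve_selection(top, region$reference)
  if (!length(ref_idx)) stop("sphere region reference selects no atoms")
  cen <- colMeans(rbind(coords_frame[ref_idx, , drop = FALSE]))
  d <- min_image_dist(pos, matrix(cen, 1, 3), box)
  d[, 1] <= region$radius
}

resolve_selection <- function(top, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  if (is.character(sel)) return(select_atoms(top, sel))
  stop("selection must be a string or an index vector")
}

#' Define an oscillating external field
#'
#' A linearly polarised field `E(t) = E0 cos(2 pi f t) u` with amplitude
#' `E0` (V/nm), frequency `f` (THz; 0 means field-free) and unit direction
#' `u`.
#'
#' @param amplitude_E0 Field strength, V/nm (>= 0). Default 0.4 V/nm, a
#'   magnitude comparable to intrinsic local fields in biomolecules.
#' @param frequency THz (>= 0).
#' @param direction Length-3 direction vector; normalised internally.
#' @return A `cw_field`.
#' @export
field_spec <- function(amplitude_E0 = 0.4, frequency = 0,
                       direction = c(0, 0, 1)) {
  if (amplitude_E0 < 0) stop("amplitude must be >= 0")
  if (frequency < 0) stop("frequency must be >= 0")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero")
  structure(list(amplitude_E0 = amplitude_E0, frequency = frequency,
                 direction = direction / nrm), class = "cw_field")
}

#' @export
print.cw_field <- function(x, ...) {
  cat(sprintf("<cw_field> E0 = %g V/nm, f = %g THz, u = (%s)\n",
              x$amplitude_E0, x$frequency,
              paste(signif(x$direction, 3), collapse = ", ")))
  invisible(x)
}
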