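#' Minimum-image displacement in an orthorhombic box
#'
#' Component-wise displacement `b - a` mapped to the nearest periodic image,
#' so each component lies in (-L/2, L/2].
#'
#' @param a,b Numeric matrices (n x 3) or length-3 vectors of positions, nm.
#' @param box Length-3 numeric vector of orthorhombic edge lengths, nm.
#' @return An n x 3 matrix (or length-3 vector) of displacements, nm.
#' @export
min_image <- function(a, b, box) {
  d <- rbind(b) - rbind(a)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive edge lengths")
  for (k in 1:3) {
    d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    # map the -L/2 boundary image to +L/2 so components lie in (-L/2, L/2]
    at_edge <- d[, k] == -box[k] / 2
    d[at_edge, k] <- box[k] / 2
  }
  if (is.null(dim(a)) && is.null(dim(b))) drop(d) else d
}

#' Minimum-image distances between two point sets
#'
#' @param a n x 3 matrix of positions, nm.
#' @param b m x 3 matrix of positions, nm.
#' @param box Box edge lengths, nm; `NULL` for no periodicity.
#' @return n x m matrix of distances, nm.
#' @export
min_image_dist <- function(a, b, box = NULL) {
  a <- rbind(a); b <- rbind(b)
  n <- nrow(a); m <- nrow(b)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- outer(b[, k], rep(1, n)) - outer(rep(1, m), a[, k])  # m x n
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + t(dk)^2
  }
  sqrt(d2)
}

#' Wrap positions into the primary box [0, L)
#'
#' @param x n x 3 matrix of positions, nm.
#' @param box Box edge lengths, nm.
#' @return Wrapped n x 3 matrix.
#' @export
wrap_positions <- function(x, box) {
  x <- rbind(x)
  for (k in 1:3) x[, k] <- x[, k] - box[k] * floor(x[, k] / box[k])
  x
}

# Rotation matrix for angle theta (radians) about unit axis u (Rodrigues).
rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Angle at vertex v between points p and q (degrees).
vertex_angle <- function(p, v, q) {
  u1 <- p - v; u2 <- q - v
  c1 <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
  acos(pmin(1, pmax(-1, c1))) * 180 / pi
}
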