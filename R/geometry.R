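# Internal vector geometry used across modules. Coordinates are always
# n x 3 matrices in Angstrom; angles are degrees in (-180, 180].

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# wrap degrees into (-180, 180]
.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

.vnorm <- function(m) sqrt(rowSums(m * m))

.cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @noRd
#' Dihedral angle for four points per row, degrees in (-180, 180].
#' Arguments are n x 3 matrices (one row per frame). IUPAC sign convention:
#' looking from b to c, the far bond rotates clockwise for positive angles.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, b2 / .vnorm(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  .wrap180(.rad2deg(atan2(-y, x)))
}

#' @noRd
#' Angle a-b-c in degrees (single points as length-3 vectors).
.angle3 <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cs <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  .rad2deg(acos(pmin(1, pmax(-1, cs))))
}

#' @noRd
#' Place one atom from internal coordinates (NeRF): returns the position of a
#' new atom bonded to `c`, with bond length `bond`, angle b-c-new `angle`
#' (degrees) and dihedral a-b-c-new `dihedral` (degrees).
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- .deg2rad(angle)
  dih <- .deg2rad(dihedral)
  d2 <- c(bond * cos(pi - ang),
          bond * cos(dih) * sin(pi - ang),
          bond * sin(dih) * sin(pi - ang))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  rot <- cbind(bc, m, n)
  c + as.vector(rot %*% d2)
}

#' @noRd
#' Rotation of points about the axis through `origin` with direction `axis`
#' by `theta` degrees (Rodrigues). `pts` is n x 3.
.rotate_about_axis <- function(pts, origin, axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  th <- .deg2rad(theta)
  p <- sweep(pts, 2, origin)
  kx <- cbind(p[, 2] * k[3] - p[, 3] * k[2],
              p[, 3] * k[1] - p[, 1] * k[3],
              p[, 1] * k[2] - p[, 2] * k[1])
  kdp <- as.vector(p %*% k)
  rot <- p * cos(th) + kx * sin(th) + outer(kdp, k) * (1 - cos(th))
  sweep(rot, 2, origin, `+`)
}

#' @noRd
#' Quasi-uniform unit sphere points (golden-spiral lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' @noRd
#' Round half away from zero to `digits` decimals (table convention; base R
#' round() is half-to-even).
.round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' @noRd
#' Minimum cross distance between two point sets (na x 3, nb x 3).
.min_cross_dist <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}
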