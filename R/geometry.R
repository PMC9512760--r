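# Geometric primitives: torsions, internal-coordinate atom placement,
# rigid-body superposition. All coordinates in Angstrom, angles in degrees.

DEG <- 180 / pi

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-10) stop("cannot normalize a zero-length vector")
  v / n
}

#' Signed dihedral angle of four points
#'
#' Standard signed torsion about the p2--p3 axis, returned in degrees in
#' the half-open range (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8)
    stop("dihedral undefined: three consecutive points are collinear")
  m1 <- vcross(n1, b2 / vnorm(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Planar angle at p2 between p1 and p3, degrees
#' @param p1,p2,p3 Numeric 3-vectors.
#' @export
angle3 <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * DEG
}

# Wrap degrees into (-180, 180]
wrap180 <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y <= -180] <- y[y <= -180] + 360
  ifelse(abs(y + 180) < 1e-12, 180, y)
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Returns the position `d` such that |c-d| = `len`, the angle b-c-d equals
#' `ang` and the dihedral a-b-c-d equals `dih`.
#'
#' @param a,b,c Numeric 3-vectors of the three reference atoms.
#' @param len Bond length c-d in Angstrom.
#' @param ang Bond angle b-c-d in degrees.
#' @param dih Dihedral a-b-c-d in degrees.
#' @export
place_atom <- function(a, b, c, len, ang, dih) {
  theta <- ang / DEG
  phi <- dih / DEG
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_local <- len * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  c + bc * d_local[1L] + m * d_local[2L] + n * d_local[3L]
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds rotation `R` and translation `t` minimizing the RMSD between
#' `R %*% x + t` over the paired rows of `mobile` and `reference`.
#'
#' @param mobile,reference n x 3 coordinate matrices with paired rows.
#' @return List with `rotation` (3x3), `translation` (length 3) and `rmsd`.
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("paired coordinate sets must have equal row counts")
  if (nrow(mobile) < 3)
    stop("superposition requires at least 3 paired atoms")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  # collinearity check: rank of the paired point clouds
  if (svd(P)$d[2L] < 1e-8 || svd(Q)$d[2L] < 1e-8)
    stop("superposition undefined: paired atoms are collinear")
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cr - as.vector(R %*% cm)
  moved <- t(R %*% t(mobile)) + matrix(t_vec, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Apply a rigid transform to an n x 3 coordinate matrix
#' @param xyz n x 3 matrix. @param rotation 3x3 matrix.
#' @param translation length-3 vector.
#' @export
apply_transform <- function(xyz, rotation, translation) {
  xyz <- as.matrix(xyz)
  t(rotation %*% t(xyz)) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
}

# Rotation matrix taking unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  u <- vunit(u); v <- vunit(v)
  w <- vcross(u, v)
  s <- vnorm(w)
  cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite vectors: rotate 180 deg about any perpendicular axis
    p <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- vunit(vcross(u, p))
    return(rotation_about_axis(ax, 180))
  }
  K <- matrix(c(0, w[3L], -w[2L], -w[3L], 0, w[1L], w[2L], -w[1L], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# Rotation matrix about a unit axis by angle in degrees.
rotation_about_axis <- function(axis, angle_deg) {
  axis <- vunit(axis)
  th <- angle_deg / DEG
  K <- matrix(c(0, axis[3L], -axis[2L],
                -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotate points about the axis through `origin` along `axis` by angle_deg.
rotate_about_line <- function(xyz, origin, axis, angle_deg) {
  R <- rotation_about_axis(axis, angle_deg)
  sweep(t(R %*% t(sweep(as.matrix(xyz), 2, origin))), 2, origin, "+")
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}
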