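# Low-level vector geometry shared by the construction, dihedral and
# alignment code.  Angles in degrees throughout the public surface.

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

.vnorm <- function(v) sqrt(sum(v * v))
.unit <- function(v) v / .vnorm(v)
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Torsion angle a-b-c-d in degrees, wrapped to [-180, 180)
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(.cross(n1, n2) * .unit(b2))
  wrap_angle(.deg(atan2(y, x)))
}

# Wrap degrees to [-180, 180)
wrap_angle <- function(a) {
  ((a + 180) %% 360) - 180
}

# Natural-extension-reference-frame placement: position of a new atom at
# given bond length from c, bond angle b-c-new, and torsion a-b-c-new.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- .rad(angle)
  tor <- .rad(torsion)
  d2 <- c(bond * cos(pi - ang),
          bond * sin(pi - ang) * cos(tor),
          bond * sin(pi - ang) * sin(tor))
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- cbind(bc, .cross(n, bc), n)
  as.numeric(c + m %*% d2)
}

# Angle a-b-c in degrees
vector_angle <- function(a, b, c) {
  u <- .unit(a - b); v <- .unit(c - b)
  .deg(acos(max(-1, min(1, sum(u * v)))))
}
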