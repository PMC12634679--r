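# Internal numerical and geometric helpers shared across modules.

# Gas constant in kcal mol^-1 K^-1
.RGAS <- 1.9872e-3

#' Numerically stable log of a mean of exponentials
#'
#' Computes log(mean(exp(x))) without overflow, used by the exponential
#' (Zwanzig) free-energy average.
#'
#' @param x numeric vector.
#' @return log(mean(exp(x))) as a scalar.
#' @keywords internal
logMeanExp <- function(x) {
  stopifnot(length(x) >= 1L)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector in geometry construction")
  v / n
}

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) construction: given positions of three reference
#' atoms a, b, c, returns the position d such that |c-d| = bond,
#' angle(b,c,d) = theta and dihedral(a,b,c,d) = phi.
#'
#' @param a,b,c numeric 3-vectors, reference positions.
#' @param bond bond length c-d in Angstrom.
#' @param theta bond angle b-c-d in degrees.
#' @param phi dihedral a-b-c-d in degrees.
#' @return numeric 3-vector, the placed position.
#' @keywords internal
placeInternal <- function(a, b, c, bond, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Dihedral angle of four points
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return dihedral a-b-c-d in degrees in (-180, 180].
#' @keywords internal
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Signed volume of the tetrahedron spanned by (p1-p0, p2-p0, p3-p0);
# the sign encodes chirality about p0.
.signedVolume <- function(p0, p1, p2, p3) {
  sum(.cross(p1 - p0, p2 - p0) * (p3 - p0))
}
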