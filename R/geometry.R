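# Geometric primitives: dihedral angles, Kabsch superposition, internal
# coordinate atom placement, rigid transforms.

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking from p2 towards p3, the far bond rotating
#' clockwise from the near bond gives a positive angle.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) < 1e-12 || sum(b2^2) < 1e-12 || sum(b3^2) < 1e-12)
    stop("degenerate geometry: coincident consecutive points")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop("degenerate geometry: collinear points")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the rotation and translation minimising the RMSD of `X` onto `Y`
#' (moving X), excluding reflections.
#'
#' @param X,Y n x 3 coordinate matrices in row correspondence, n >= 3.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   apply as `X %*% t(rotation) + translation`), and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("coordinate sets differ in length")
  if (nrow(X) < 3) stop("need at least 3 points")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(crossprod(Xc, Yc))           # t(Xc) %*% Yc
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)             # Y ~ Xc %*% t(R)
  Xr <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Xr - Yc)^2)))
  list(rotation = R, translation = as.numeric(cy - (cx %*% t(R))), rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param X n x 3 matrix.
#' @param tr list with `rotation`, `translation` as from [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(X, tr) {
  sweep(as.matrix(X) %*% t(tr$rotation), 2, tr$translation, "+")
}

#' @noRd
rigid_transform_structure <- function(model, tr) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- apply_transform(xyz, tr)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# Place atom D from reference atoms A-B-C and internal coordinates:
# bond length |C-D|, bond angle B-C-D (degrees), dihedral A-B-C-D (degrees).
#' @noRd
place_atom <- function(A, B, C, length, angle, dih) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) {                      # collinear reference: pick any normal
    ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- cross3(ref, bc)
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- cross3(n, bc)
  ang <- angle * pi / 180
  dh <- -dih * pi / 180
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(dh),
          length * sin(ang) * sin(dh))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}
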