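# ---------------------------------------------------------------------------
# Similarity metrics and optimal superposition
#
# dRMSD compares all intramolecular pairwise distances and is therefore
# invariant under rigid motion and reflection of either structure.  cRMSD
# compares matched coordinates in a common frame; the Kabsch algorithm gives
# the optimal proper rotation, and reflection is handled by explicitly
# scoring the point-reflected copy of the model.
# ---------------------------------------------------------------------------

metric_points <- function(x) {
  p <- real_points(x)
  if (!is.numeric(p)) lf_domain_error("coordinates must be numeric")
  p
}

#' Distance RMSD between two point sets
#'
#' \deqn{dRMSD = \sqrt{ \sum_{i<j} (|P_i-P_j| - |M_i-M_j|)^2 / n_{pairs} }}
#' with \eqn{n_{pairs} = \binom{n}{2}}: for a side-chain model of l residues
#' (n = 2l points) this is \eqn{l(2l-1)}; for a backbone model it is
#' \eqn{l(l-1)/2}. Invariant under rigid motion or reflection of either
#' argument.
#'
#' @param P,M Coordinate matrices (n x 3, same ordering), or `real_model`s.
#' @return dRMSD in the coordinate units (Angstrom).
#' @export
drmsd <- function(P, M) {
  P <- metric_points(P); M <- metric_points(M)
  if (!all(dim(P) == dim(M))) lf_domain_error("coordinate sets differ in size")
  if (nrow(P) < 2L) lf_domain_error("dRMSD requires at least 2 points")
  dp <- dist(P); dm <- dist(M)
  sqrt(mean((dp - dm)^2))
}

#' Coordinate RMSD between two matched point sets
#'
#' \deqn{cRMSD = \sqrt{ \sum_i |P_i - M_i|^2 / n }}; for side-chain models
#' the points are the l backbone and l side-chain monomers (n = 2l), for
#' backbone models n = l. Coordinates must already be in a common frame
#' (see [kabsch()] / [best_superposition()]).
#'
#' @param P,M Coordinate matrices (n x 3, same ordering), or `real_model`s.
#' @return cRMSD in the coordinate units (Angstrom).
#' @export
crmsd <- function(P, M) {
  P <- metric_points(P); M <- metric_points(M)
  if (!all(dim(P) == dim(M))) lf_domain_error("coordinate sets differ in size")
  if (nrow(P) < 1L) lf_domain_error("cRMSD requires at least 1 point")
  sqrt(mean(rowSums((P - M)^2)))
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Computes the proper rotation (det +1) and translation minimising the
#' coordinate RMSD of `M` onto `P`, via singular value decomposition with
#' determinant correction. Degenerate inputs (all points coincident) yield
#' the identity rotation and centroid translation.
#'
#' @param P,M Matched coordinate matrices (n x 3).
#' @return Object of class `superposition`: `rotation` (3x3, orthonormal,
#'   det +1), `translation` (length-3), `reflected = FALSE`. Apply with
#'   [apply_superposition()].
#' @export
kabsch <- function(P, M) {
  P <- metric_points(P); M <- metric_points(M)
  if (!all(dim(P) == dim(M))) lf_domain_error("coordinate sets differ in size")
  cp <- colMeans(P); cm <- colMeans(M)
  Pc <- sweep(P, 2, cp); Mc <- sweep(M, 2, cm)
  H <- crossprod(Mc, Pc)                      # 3x3 covariance
  if (sum(H^2) < 1e-24) {
    R <- diag(3)
  } else {
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  structure(list(rotation = R, translation = as.numeric(cp - R %*% cm),
                 reflected = FALSE),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' If the superposition was obtained from the mirror branch of
#' [best_superposition()], the coordinates are first point-reflected through
#' the centroid recorded at fit time.
#'
#' @param sup A `superposition`.
#' @param X Coordinate matrix (n x 3).
#' @return Transformed coordinates.
#' @export
apply_superposition <- function(sup, X) {
  stopifnot(inherits(sup, "superposition"))
  X <- metric_points(X)
  if (isTRUE(sup$reflected))
    X <- sweep(-X, 2, 2 * sup$reflect_center, "+")
  sweep(X %*% t(sup$rotation), 2, sup$translation, "+")
}

#' Best superposition including the mirror image
#'
#' Runs the Kabsch superposition on `M` and on its point reflection
#' `M' = 2c - M` (c the centroid of `M`); distance-RMSD optimisation cannot
#' distinguish a structure from its mirror image, so both branches must be
#' scored and the one with the lower coordinate RMSD kept. Ties are broken
#' to the non-reflected branch.
#'
#' @param P Target coordinates (n x 3) or `real_model`.
#' @param M Model coordinates (n x 3) or `real_model`.
#' @return List with `superposition` (reflected flag set accordingly),
#'   `crmsd`, and `coords` (the superposed model coordinates).
#' @export
best_superposition <- function(P, M) {
  P <- metric_points(P); M <- metric_points(M)
  ctr <- colMeans(M)
  Mref <- sweep(-M, 2, 2 * ctr, "+")
  s1 <- kabsch(P, M)
  s2 <- kabsch(P, Mref)
  c1 <- crmsd(P, apply_superposition(s1, M))
  x2 <- sweep(Mref %*% t(s2$rotation), 2, s2$translation, "+")
  c2 <- crmsd(P, x2)
  if (c2 < c1) {
    s2$reflected <- TRUE
    s2$reflect_center <- ctr
    list(superposition = s2, crmsd = c2, coords = x2)
  } else {
    list(superposition = s1, crmsd = c1, coords = apply_superposition(s1, M))
  }
}
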