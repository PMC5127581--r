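# Closed-form least-squares rigid superposition (Kabsch), shared by the
# pharmacophore matcher and the trajectory analytics.

# rotation/translation mapping P onto Q (rows are points): x -> R x + t
# minimises sum ||R p_i + t - q_i||^2; det(R) = +1 enforced (reflection guard)
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cq - R %*% cp)
  list(rotation = R, translation = t)
}

#' Least-squares rigid superposition of two point sets
#'
#' Finds the proper rotation and translation minimising the RMSD of `mobile`
#' onto `ref` (no reflection: the rotation determinant is forced to +1).
#'
#' @param ref,mobile Matching n x 3 coordinate matrices, n >= 3.
#' @return List with `rotation` (3x3), `translation` (length 3) such that
#'   `mobile %*% t(rotation) + translation` best fits `ref`, and the residual
#'   `rmsd` in Angstrom.
#' @examples
#' ref <- matrix(rnorm(12), 4, 3)
#' fit <- kabsch_superpose(ref, ref + 5)
#' fit$rmsd
#' @export
kabsch_superpose <- function(ref, mobile) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  if (nrow(ref) != nrow(mobile) || ncol(ref) != 3L || ncol(mobile) != 3L)
    stop("ref and mobile must be matching n x 3 matrices")
  if (nrow(ref) < 3L) stop("superposition needs at least 3 points")
  sv <- svd(sweep(ref, 2, colMeans(ref)))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("reference points are collinear; superposition is degenerate")
  fit <- kabsch_fit(mobile, ref)
  moved <- apply_rigid(mobile, fit$rotation, fit$translation)
  fit$rmsd <- sqrt(mean(rowSums((moved - ref)^2)))
  fit
}
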