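#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Computes the proper rotation and translation that minimize the RMSD of the
#' moving point set `Q` onto the fixed set `P`, by SVD of the covariance
#' matrix with reflection correction.
#'
#' The returned transform maps moving coordinates as
#' `Q %*% t(rotation) + translation` (rows are points).
#'
#' @param P fixed points, n x 3 matrix.
#' @param Q moving points, n x 3 matrix (same n >= 3).
#' @return a `Superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) and `rmsd` (Angstrom, at the optimum).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("point lists must have equal length")
  if (nrow(P) < 3L) stop("need at least 3 point pairs")
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  H <- crossprod(Q0, P0)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cP - as.numeric(cQ %*% t(R))
  moved <- Q %*% t(R) + matrix(tr, nrow(Q), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((P - moved)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "Superposition")
}

#' Apply a rigid transform to coordinates
#'
#' @param X n x 3 coordinate matrix.
#' @param transform a `Superposition` (list with `rotation`, `translation`).
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(X, transform) {
  X %*% t(transform$rotation) +
    matrix(transform$translation, nrow(X), 3, byrow = TRUE)
}

# Inverse of a rigid transform: maps transformed coordinates back.
invert_transform <- function(transform) {
  Rinv <- t(transform$rotation)
  structure(list(rotation = Rinv,
                 translation = as.numeric(-transform$translation %*% t(Rinv)),
                 rmsd = transform$rmsd),
            class = "Superposition")
}

identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0), rmsd = 0),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("<Superposition: rmsd %.3f A>\n", x$rmsd))
  invisible(x)
}
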