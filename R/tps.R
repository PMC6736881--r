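#' Thin-plate spline interpolation in 3D
#'
#' Fits the interpolating thin-plate spline mapping `source` control points
#' exactly onto `target` points, using the 3D kernel U(r) = r plus an affine
#' part, by solving the standard bordered linear system. No smoothing is
#' applied: the transform reproduces the targets at the controls to machine
#' precision.
#'
#' @param source,target m x 3 matrices of corresponding control points,
#'   m >= 5, not all coplanar.
#' @return object of class `tps_transform` with elements `control_source`,
#'   `control_target`, `weights` (m x 3 kernel coefficients), `affine`
#'   (3 x 3 matrix) and `translation` (length-3).
#' @export
tps_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  m <- nrow(source)
  if (m < 5) stop("need at least 5 control points")
  if (nrow(target) != m || ncol(source) != 3 || ncol(target) != 3)
    stop("source and target must be matching m x 3 matrices")
  dd <- as.matrix(stats::dist(source))
  dup <- which(dd < 1e-12 & upper.tri(dd), arr.ind = TRUE)
  if (nrow(dup))
    stop("duplicated control points: ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "))
  K <- dd                      # U(r) = r
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(target, matrix(0, 4, 3))
  qrL <- qr(L)
  if (qrL$rank < ncol(L))
    stop("singular TPS system (coplanar or degenerate controls)")
  sol <- qr.coef(qrL, rhs)
  sol <- sol + qr.coef(qrL, rhs - L %*% sol)   # one refinement step
  W <- sol[1:m, , drop = FALSE]
  A <- sol[(m + 1):(m + 4), , drop = FALSE]
  structure(list(control_source = source, control_target = target,
                 weights = W, affine = A[2:4, , drop = FALSE],
                 translation = A[1, ]),
            class = "tps_transform")
}

#' @rdname tps_fit
#' @param transform a fitted `tps_transform`.
#' @param points n x 3 matrix of points to map.
#' @return `tps_apply` returns the mapped n x 3 matrix.
#' @export
tps_apply <- function(transform, points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3")
  src <- transform$control_source
  # pairwise distances points -> controls, difference-first for accuracy
  # at and near the controls
  U <- matrix(0, nrow(points), nrow(src))
  for (j in seq_len(nrow(src)))
    U[, j] <- sqrt((points[, 1] - src[j, 1])^2 +
                   (points[, 2] - src[j, 2])^2 +
                   (points[, 3] - src[j, 3])^2)
  sweep(points %*% transform$affine, 2, transform$translation, `+`) +
    U %*% transform$weights
}

#' @export
print.tps_transform <- function(x, ...) {
  cat("Thin-plate spline transform:", nrow(x$control_source),
      "control points (3D kernel U(r) = r)\n")
  invisible(x)
}

#' Bending energy of a thin-plate-spline mapping
#'
#' The quadratic bending-energy functional of the TPS taking `reference` onto
#' `shape`, i.e. `tr(V' Be V)` with `Be` the bending energy matrix of the
#' reference and `V` the target coordinates. Zero iff the mapping is affine.
#'
#' @param reference k x 3 reference landmarks (defines the energy form).
#' @param shape k x 3 target landmarks.
#' @return non-negative scalar.
#' @export
bending_energy <- function(reference, shape) {
  be <- bending_energy_matrix(reference)
  e <- sum(diag(t(as.matrix(shape)) %*% be %*% as.matrix(shape)))
  max(e, 0)
}

#' @rdname bending_energy
#' @details `bending_energy_matrix` returns the positive semidefinite k x k
#'   quadratic form `Be` of the reference (the negated upper-left block of
#'   the inverse bordered TPS matrix; with the 3D kernel U(r) = r that block
#'   is negative semidefinite on the interpolation subspace). Its null space
#'   contains all affine functions of the reference coordinates.
#' @export
bending_energy_matrix <- function(reference) {
  reference <- as.matrix(reference)
  m <- nrow(reference)
  K <- as.matrix(stats::dist(reference))
  P <- cbind(1, reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  Linv <- tryCatch(solve(L), error = function(e)
    stop("singular TPS system (coplanar or degenerate controls)"))
  -Linv[1:m, 1:m, drop = FALSE]
}
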