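#' Population mean shapes from an aligned sample
#'
#' Arithmetic mean of the aligned coordinates per group, rescaled to unit
#' centroid size. Note the mean of group means is not the grand mean when
#' groups are unbalanced; downstream analyses operate on the means.
#'
#' @param aligned an `aligned_sample` from [gpa()] (or
#'   [symmetric_component()]).
#' @param grouping optional character vector of group labels per specimen;
#'   defaults to the `group` field of each configuration.
#' @return named list of k x 3 mean shape matrices, one per group.
#' @export
population_mean_shapes <- function(aligned, grouping = NULL) {
  if (!inherits(aligned, "aligned_sample")) stop("aligned must come from gpa()")
  if (is.null(grouping))
    grouping <- vapply(aligned$configs, function(cf)
      if (is.null(cf$group)) NA_character_ else as.character(cf$group), "")
  if (anyNA(grouping)) stop("every specimen needs a group label")
  if (length(grouping) != length(aligned$configs))
    stop("grouping length mismatch")
  out <- lapply(split(seq_along(grouping), grouping), function(ii) {
    m <- Reduce(`+`, lapply(aligned$configs[ii], `[[`, "coords")) / length(ii)
    m / csize(m)
  })
  out[unique(grouping)]
}

vec_shape <- function(m) as.vector(t(m))          # x1 y1 z1 x2 ...
unvec_shape <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Principal component analysis of mean shapes
#'
#' Eigendecomposition of the covariance of the vectorized shapes. All
#' non-zero components are retained (q = min(n - 1, 3k)); projection onto
#' the orthonormal eigenvectors is an isometry, so full-space score
#' distances equal shape-space distances. Axis signs are canonicalized so
#' each component's largest-magnitude loading is positive.
#'
#' @param shapes named list of k x 3 matrices (e.g. from
#'   [population_mean_shapes()]) or an n x 3k matrix with row names.
#' @return object of class `shape_pca`: `mean` (3k), `eigenvectors`
#'   (q x 3k), `eigenvalues` (q), `scores` (n x q), `variance_fractions`,
#'   `k`.
#' @export
shape_pca <- function(shapes) {
  X <- if (is.matrix(shapes)) shapes else
    do.call(rbind, lapply(shapes, vec_shape))
  if (is.null(rownames(X)) && !is.matrix(shapes)) rownames(X) <- names(shapes)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 shapes")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc, nu = n, nv = 0)
  keep <- which(s$d > max(s$d) * 1e-9)
  d <- s$d[keep]
  V <- crossprod(Xc, s$u[, keep, drop = FALSE]) %*% diag(1 / d, length(keep))
  # canonical sign: largest-magnitude loading positive
  for (j in seq_along(keep)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_along(keep))
  ev <- d^2 / (n - 1)
  structure(list(mean = mu, eigenvectors = t(V), eigenvalues = ev,
                 scores = scores, variance_fractions = ev / sum(ev),
                 k = length(mu) / 3),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA:", nrow(x$scores), "shapes,", length(x$eigenvalues),
      "components\n")
  vf <- x$variance_fractions
  cat(sprintf("  PC1-%d variance: %s\n", min(3, length(vf)),
              paste(sprintf("%.1f%%", 100 * vf[seq_len(min(3, length(vf)))]),
                    collapse = " ")))
  invisible(x)
}

#' Project shapes onto an existing shape PCA basis
#'
#' @param pca a `shape_pca`.
#' @param shapes list of k x 3 matrices or an m x 3k matrix.
#' @return m x q score matrix.
#' @export
project_shapes <- function(pca, shapes) {
  X <- if (is.matrix(shapes)) shapes else
    do.call(rbind, lapply(shapes, vec_shape))
  sweep(X, 2, pca$mean) %*% t(pca$eigenvectors)
}

#' Reconstruct landmark shapes from PC scores
#'
#' @param pca a `shape_pca`.
#' @param scores m x q (or length-q) score matrix.
#' @return list of k x 3 matrices.
#' @export
backrotate_scores <- function(pca, scores) {
  scores <- if (is.null(dim(scores))) matrix(scores, 1) else as.matrix(scores)
  X <- sweep(scores %*% pca$eigenvectors[seq_len(ncol(scores)), , drop = FALSE],
             2, pca$mean, `+`)
  out <- lapply(seq_len(nrow(X)), function(i) unvec_shape(X[i, ]))
  names(out) <- rownames(scores)
  out
}
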