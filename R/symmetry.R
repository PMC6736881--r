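# Reflect a configuration (negate x) and swap bilateral labels so the result
# is the same anatomical object seen in the mirror.
mirror_relabel <- function(coords, scheme) {
  out <- coords %*% diag(c(-1, 1, 1))
  if (nrow(scheme$symmetry_pairs)) {
    l <- scheme$symmetry_pairs[, 1]; r <- scheme$symmetry_pairs[, 2]
    tmp <- out[l, , drop = FALSE]
    out[l, ] <- out[r, , drop = FALSE]
    out[r, ] <- tmp
  }
  out
}

#' Symmetric shape component of a bilaterally symmetric structure
#'
#' Corrects for bilateral asymmetry: each specimen is paired with its
#' mirrored, relabelled copy, all copies are superimposed jointly by GPA, the
#' joint consensus is oriented so its mid-sagittal plane coincides exactly
#' with x = 0, every copy is re-aligned to that consensus, and each
#' specimen's two aligned copies are averaged. The averaged configurations
#' are exactly symmetric (paired landmarks mirror across x = 0, midline
#' landmarks on the plane) and are rescaled to unit centroid size.
#'
#' @param sample list of complete [landmark_config] objects or an
#'   `aligned_sample`.
#' @param scheme a [landmark_scheme] declaring `symmetry_pairs` and
#'   `midline`; every landmark must be either paired or on the midline (the
#'   scheme constructor enforces this).
#' @return an `aligned_sample` of symmetric components.
#' @export
symmetric_component <- function(sample, scheme) {
  configs <- if (inherits(sample, "aligned_sample")) sample$configs else
    lapply(seq_along(sample), function(i) as_config(sample[[i]], paste0("specimen_", i)))
  k <- nrow(configs[[1]]$coords)
  if (k != scheme$n_landmarks)
    stop("configuration size does not match scheme")
  n <- length(configs)
  mirrored <- lapply(configs, function(cf)
    landmark_config(mirror_relabel(cf$coords, scheme),
                    paste0(cf$specimen_id, "_mirror"), group = cf$group))
  g <- gpa(c(configs, mirrored))
  cons <- symmetrize_consensus(g$consensus, scheme)
  # align every copy to the exactly-symmetric consensus
  align_one <- function(cf) {
    x <- center_config(cf$coords); x <- x / csize(x)
    x %*% kabsch(cons, x)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- (align_one(configs[[i]]) + align_one(mirrored[[i]])) / 2
    s <- s / csize(s)
    out[[i]] <- landmark_config(s, configs[[i]]$specimen_id,
                                group = configs[[i]]$group)
  }
  m <- Reduce(`+`, lapply(out, `[[`, "coords")) / n
  structure(list(configs = out, consensus = m / csize(m),
                 centroid_sizes = if (inherits(sample, "aligned_sample"))
                   sample$centroid_sizes else
                   vapply(configs, function(cf) csize(cf$coords), 1),
                 n_iterations = g$n_iterations),
            class = "aligned_sample")
}

# Orient a (nearly) bilaterally symmetric consensus so its symmetry plane is
# exactly x = 0, then project onto the symmetric subspace. The mirror-relabel
# map M satisfies M(c) ~ c R_x Q for the optimal OPA rotation Q; the improper
# orthogonal map B = R_x Q has a -1 eigenvector which is the plane normal.
symmetrize_consensus <- function(cons, scheme) {
  mc <- mirror_relabel(cons, scheme)
  q <- kabsch(cons, mc)
  B <- diag(c(-1, 1, 1)) %*% q
  e <- eigen(B)
  i <- which.min(abs(Re(e$values) + 1))
  nvec <- Re(e$vectors[, i]); nvec <- nvec / sqrt(sum(nvec^2))
  sign3 <- function(v) {                  # index-weighted odd moment
    s <- cons %*% v
    t3 <- sum(seq_along(s) * s^3)
    if (abs(t3) < 1e-12) t3 <- sum(seq_along(s)^2 * s^3)
    if (t3 < 0) -v else v
  }
  nvec <- sign3(nvec)
  # in-plane axes: principal directions of the consensus orthogonal to nvec,
  # so the whole frame is a deterministic function of the shape alone
  u <- if (abs(nvec[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * nvec) * nvec; u <- u / sqrt(sum(u^2))
  v <- c(nvec[2] * u[3] - nvec[3] * u[2],
         nvec[3] * u[1] - nvec[1] * u[3],
         nvec[1] * u[2] - nvec[2] * u[1])
  Y2 <- cons %*% cbind(u, v)
  w <- eigen(crossprod(Y2), symmetric = TRUE)$vectors
  v1 <- sign3(cbind(u, v) %*% w[, 1])
  v2 <- cbind(u, v) %*% w[, 2]
  R <- cbind(nvec, v1, v2)
  if (det(R) < 0) R[, 3] <- -R[, 3]
  cc <- cons %*% R
  cc <- (cc + mirror_relabel(cc, scheme)) / 2   # exact projection
  cc / csize(cc)
}
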