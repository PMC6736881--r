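#' Slide curve and surface semilandmarks
#'
#' Relaxes the arbitrary spacing of semilandmarks: per iteration the sample
#' consensus is recomputed, each specimen's curve semilandmarks are allowed
#' to move along their local tangent (central difference of the chain
#' neighbours) and each surface semilandmark within its local tangent plane
#' (least-squares plane of the declared neighbours), with all displacements
#' of a specimen solved jointly in closed form to minimise the thin-plate
#' spline bending energy between the consensus and the specimen
#' (`method = "bending"`, the default) or the Procrustes distance to the
#' consensus (`method = "procrustes"`); GPA is then re-run. Chain endpoints
#' (no two neighbours) and fixed landmarks never move; a degenerate
#' (zero-length) tangent leaves the landmark unmoved with a warning.
#'
#' @param sample an `aligned_sample` from [gpa()].
#' @param scheme a [landmark_scheme] with curve/surface topology.
#' @param iterations number of slide-and-realign iterations (default 3).
#' @param method sliding criterion, `"bending"` or `"procrustes"`.
#' @return an `aligned_sample`; attribute `energy` is an iterations x 2
#'   matrix of the total bending energy to the consensus before and after
#'   sliding in each iteration.
#' @export
slide_semilandmarks <- function(sample, scheme, iterations = 3,
                                method = c("bending", "procrustes")) {
  method <- match.arg(method)
  if (!inherits(sample, "aligned_sample")) stop("sample must come from gpa()")
  k <- scheme$n_landmarks
  if (nrow(sample$consensus) != k) stop("scheme does not match sample")
  energy <- matrix(NA_real_, iterations, 2,
                   dimnames = list(NULL, c("before", "after")))
  for (it in seq_len(iterations)) {
    cons <- sample$consensus
    be <- if (method == "bending") bending_energy_matrix(cons) else NULL
    xs <- lapply(sample$configs, function(cf)
      slide_one(cf$coords, cons, scheme, be, method))
    if (method == "bending") {
      energy[it, 1] <- sum(vapply(sample$configs, function(cf)
        max(sum(diag(t(cf$coords) %*% be %*% cf$coords)), 0), 1))
      energy[it, 2] <- sum(vapply(xs, function(x)
        max(sum(diag(t(x) %*% be %*% x)), 0), 1))
    }
    configs <- lapply(seq_along(xs), function(i)
      landmark_config(xs[[i]], sample$configs[[i]]$specimen_id,
                      group = sample$configs[[i]]$group))
    g <- gpa(configs)
    g$centroid_sizes <- sample$centroid_sizes
    sample <- g
  }
  attr(sample, "energy") <- energy
  sample
}

#' Relax one configuration's semilandmarks against a fixed reference
#'
#' Applies the semilandmark sliding step of [slide_semilandmarks()] to a
#' single configuration against a fixed reference shape (no GPA re-run).
#' Useful for projecting a new specimen — or a known ground-truth shape —
#' into the tangential correspondence of an already-slid sample, so that
#' coordinate comparisons are not confounded by semilandmark
#' re-parameterization.
#'
#' @param shape k x 3 configuration (will be centred, unit-scaled and
#'   rotated onto the reference).
#' @param reference k x 3 reference (e.g. a slid sample's consensus).
#' @param scheme a [landmark_scheme].
#' @param iterations sliding passes (default 3).
#' @param method `"bending"` or `"procrustes"`.
#' @return unit-size k x 3 matrix aligned to the reference.
#' @export
relax_to_reference <- function(shape, reference, scheme, iterations = 3,
                               method = c("bending", "procrustes")) {
  method <- match.arg(method)
  x <- center_config(as.matrix(shape)); x <- x / csize(x)
  ref <- center_config(as.matrix(reference)); ref <- ref / csize(ref)
  x <- x %*% kabsch(ref, x)
  be <- if (method == "bending") bending_energy_matrix(ref) else NULL
  for (i in seq_len(iterations)) {
    x <- slide_one(x, ref, scheme, be, method)
    x <- center_config(x); x <- x / csize(x)
    x <- x %*% kabsch(ref, x)
  }
  x
}

# Tangent directions for every sliding landmark of one specimen:
# list of (index, 3 x d matrix of orthonormal directions).
tangent_directions <- function(coords, scheme) {
  dirs <- list()
  warned <- FALSE
  for (ch in scheme$curves) {
    if (length(ch) < 3) next
    for (j in 2:(length(ch) - 1)) {
      i <- ch[j]
      t_ <- coords[ch[j + 1], ] - coords[ch[j - 1], ]
      len <- sqrt(sum(t_^2))
      if (len < 1e-12) { warned <- TRUE; next }
      dirs[[length(dirs) + 1]] <- list(i = i, u = matrix(t_ / len, 3, 1))
    }
  }
  si <- scheme$surfaces$indices
  for (j in seq_along(si)) {
    i <- si[j]
    nb <- scheme$surfaces$neighbors[[j]]
    p <- coords[nb, , drop = FALSE]
    cen <- colMeans(p)
    e <- eigen(crossprod(sweep(p, 2, cen)), symmetric = TRUE)
    if (e$values[2] < 1e-12) { warned <- TRUE; next }
    dirs[[length(dirs) + 1]] <- list(i = i, u = e$vectors[, 1:2, drop = FALSE])
  }
  if (warned) warning("degenerate tangent; landmark(s) left unmoved")
  dirs
}

slide_one <- function(coords, cons, scheme, be, method) {
  dirs <- tangent_directions(coords, scheme)
  if (!length(dirs)) return(coords)
  if (method == "procrustes") {
    out <- coords
    for (d in dirs) {
      u <- d$u
      out[d$i, ] <- coords[d$i, ] + as.vector(u %*% (t(u) %*% (cons[d$i, ] - coords[d$i, ])))
    }
    return(out)
  }
  idx <- unlist(lapply(dirs, function(d) rep(d$i, ncol(d$u))))
  U <- do.call(cbind, lapply(dirs, `[[`, "u"))   # 3 x d, columns are dofs
  nd <- length(idx)
  # M[a,b] = Be[i_a, i_b] * (u_a . u_b);   rhs_a = u_a . (Be X)[i_a, ]
  M <- be[idx, idx] * crossprod(U)
  bx <- be %*% coords
  rhs <- colSums(U * t(bx[idx, , drop = FALSE]))
  diag(M) <- diag(M) + 1e-10 * mean(abs(diag(M)))
  t_ <- tryCatch(solve(M, -rhs), error = function(e) qr.solve(M, -rhs, tol = 1e-12))
  out <- coords
  for (a in seq_len(nd))
    out[idx[a], ] <- out[idx[a], ] + U[, a] * t_[a]
  out
}
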