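# Closest point on each reference triangle to point p, vectorized over
# triangles (Eberly-style region analysis via clamped barycentric solve).
closest_points_on_triangles <- function(p, v0, e1, e2) {
  d0 <- sweep(-v0, 2, p, `+`)       # p - v0, per triangle
  a <- rowSums(e1 * e1); b <- rowSums(e1 * e2); c_ <- rowSums(e2 * e2)
  d <- rowSums(e1 * d0); e <- rowSums(e2 * d0)
  det <- a * c_ - b * b
  s <- (c_ * d - b * e) / det
  t <- (a * e - b * d) / det
  inside <- s >= 0 & t >= 0 & s + t <= 1
  # clamp to the three edges and take the best
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  s1 <- clamp01(d / a); t1 <- 0                      # edge v0 + s e1
  t2 <- clamp01(e / c_); s2 <- 0                     # edge v0 + t e2
  # edge v0 + e1 + u (e2 - e1)
  u <- clamp01(rowSums((e2 - e1) * (d0 - e1)) / rowSums((e2 - e1)^2))
  best_s <- ifelse(inside, s, NA); best_t <- ifelse(inside, t, NA)
  cand_s <- cbind(s1, s2, 1 - u)
  cand_t <- cbind(t1, t2, u)
  qdist <- function(ss, tt) {
    q <- v0 + ss * e1 + tt * e2
    rowSums(sweep(q, 2, p)^2)
  }
  dcand <- cbind(qdist(cand_s[, 1], cand_t[, 1]),
                 qdist(cand_s[, 2], cand_t[, 2]),
                 qdist(cand_s[, 3], cand_t[, 3]))
  pick <- max.col(-dcand, ties.method = "first")
  sel <- cbind(seq_along(pick), pick)
  s_out <- ifelse(inside, s, cand_s[sel])
  t_out <- ifelse(inside, t, cand_t[sel])
  list(s = s_out, t = t_out,
       points = v0 + s_out * e1 + t_out * e2)
}

#' Vertex-wise surface deviation between two meshes
#'
#' Quantifies the deviation of a `test` mesh from a `reference` mesh. In
#' `nearest_point` mode each test vertex is matched to the exactly closest
#' point on any reference triangle; in `corresponding_vertex` mode vertices
#' are compared index-by-index (requires equal vertex counts sharing
#' provenance, e.g. two warps of the same model). Distances are signed by
#' the reference's outward normal interpolated at the matched point:
#' positive means the test vertex lies outside the reference surface. The
#' meshes are assumed pre-aligned (in the package pipeline ancestral
#' landmark configurations are GPA-aligned before warping); no ICP is
#' performed.
#'
#' @param test,reference [mesh3d_simple] meshes.
#' @param mode `"nearest_point"` (default) or `"corresponding_vertex"`.
#' @param bins number of fixed-width histogram bins spanning the observed
#'   range (default 50).
#' @return object of class `deviation_report`: `per_vertex` signed
#'   distances (mm), `histogram` (`breaks`, `counts`), and `stats`
#'   (`max_pos`, `max_neg`, `mean_pos`, `mean_neg`, `sd`, all mm).
#' @export
deviation <- function(test, reference,
                      mode = c("nearest_point", "corresponding_vertex"),
                      bins = 50) {
  mode <- match.arg(mode)
  if (!nrow(test$vertices) || !nrow(reference$vertices)) stop("empty mesh")
  rn <- vertex_normals(reference)
  if (mode == "corresponding_vertex") {
    if (nrow(test$vertices) != nrow(reference$vertices))
      stop("corresponding_vertex mode requires equal vertex counts")
    dv <- test$vertices - reference$vertices
    dist <- sqrt(rowSums(dv^2))
    sgn <- sign(rowSums(dv * rn))
    sgn[sgn == 0] <- 1
    signed <- dist * sgn
  } else {
    f <- reference$faces
    v0 <- reference$vertices[f[, 1], , drop = FALSE]
    e1 <- reference$vertices[f[, 2], , drop = FALSE] - v0
    e2 <- reference$vertices[f[, 3], , drop = FALSE] - v0
    nv <- nrow(test$vertices)
    signed <- numeric(nv)
    for (i in seq_len(nv)) {
      p <- test$vertices[i, ]
      cp <- closest_points_on_triangles(p, v0, e1, e2)
      d2 <- rowSums(sweep(cp$points, 2, p)^2)
      j <- which.min(d2)
      w <- c(1 - cp$s[j] - cp$t[j], cp$s[j], cp$t[j])
      nrm <- w[1] * rn[f[j, 1], ] + w[2] * rn[f[j, 2], ] + w[3] * rn[f[j, 3], ]
      sgn <- sign(sum((p - cp$points[j, ]) * nrm))
      if (sgn == 0) sgn <- 1
      signed[i] <- sgn * sqrt(d2[j])
    }
  }
  rng <- range(signed)
  if (diff(rng) < 1e-12) rng <- rng + c(-5e-13, 5e-13)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- graphics::hist(signed, breaks = breaks, plot = FALSE)$counts
  pos <- signed[signed > 0]; neg <- signed[signed < 0]
  stats <- list(max_pos = if (length(pos)) max(pos) else 0,
                max_neg = if (length(neg)) min(neg) else 0,
                mean_pos = if (length(pos)) mean(pos) else 0,
                mean_neg = if (length(neg)) mean(neg) else 0,
                sd = stats::sd(signed))
  structure(list(per_vertex = signed,
                 histogram = list(breaks = breaks, counts = counts),
                 stats = stats, mode = mode),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("Surface deviation (%s): max +%.4f / %.4f mm, ",
                     "mean +%.4f / %.4f mm, sd %.4f mm\n"),
              x$mode, s$max_pos, s$max_neg, s$mean_pos, s$mean_neg, s$sd))
  invisible(x)
}

#' @rdname deviation
#' @param report a `deviation_report`.
#' @param path base path; writes `<path>.csv` (per-vertex) and
#'   `<path>.json` (stats).
#' @export
write_deviation_report <- function(report, path) {
  utils::write.csv(data.frame(vertex = seq_along(report$per_vertex),
                              deviation_mm = report$per_vertex),
                   paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(report$stats, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
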