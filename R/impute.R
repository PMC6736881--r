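# Least-squares plane through a set of points: centroid + unit normal
# (eigenvector of the smallest eigenvalue of the point covariance).
fit_plane <- function(points) {
  cen <- colMeans(points)
  e <- eigen(crossprod(sweep(points, 2, cen)), symmetric = TRUE)
  list(center = cen, normal = e$vectors[, 3])
}

reflect_across_plane <- function(points, plane) {
  d <- sweep(points, 2, plane$center)
  points - 2 * (d %*% plane$normal) %*% t(plane$normal)
}

#' Impute missing landmarks by mirroring, then thin-plate splines
#'
#' Two-stage estimation of unobserved landmarks. Stage 1: any missing
#' landmark whose bilateral partner is preserved is filled by reflecting the
#' partner across the specimen's mid-sagittal plane, estimated by least
#' squares through the preserved midline landmarks. Stage 2: remaining gaps
#' are filled by the thin-plate spline mapping the complete `template` onto
#' the specimen's preserved landmarks, evaluated at the template's positions
#' for the missing landmarks.
#'
#' @param config a [landmark_config] with missing landmarks.
#' @param template a complete [landmark_config] (or k x 3 matrix) of the same
#'   scheme, e.g. the sample consensus.
#' @param scheme a [landmark_scheme].
#' @return a complete [landmark_config]; the element `provenance` records per
#'   landmark whether it was `"observed"`, imputed by `"mirror"` or by
#'   `"tps"`.
#' @export
impute_missing <- function(config, template, scheme) {
  config <- as_config(config)
  template <- as_config(template, "template")
  if (any(template$missing)) stop("template must be complete")
  k <- nrow(config$coords)
  if (k != scheme$n_landmarks || nrow(template$coords) != k)
    stop("configuration/template size does not match scheme")
  if (sum(!config$missing) < 4)
    stop("fewer than 4 preserved landmarks; cannot impute")
  coords <- config$coords
  provenance <- ifelse(config$missing, "missing", "observed")
  miss <- config$missing

  # stage 1: mirror preserved partners across the midline plane
  partner <- integer(k)
  partner[scheme$symmetry_pairs[, 1]] <- scheme$symmetry_pairs[, 2]
  partner[scheme$symmetry_pairs[, 2]] <- scheme$symmetry_pairs[, 1]
  mid_obs <- intersect(scheme$midline, which(!miss))
  if (length(mid_obs) >= 3) {
    plane <- fit_plane(coords[mid_obs, , drop = FALSE])
    for (i in which(miss)) {
      j <- partner[i]
      if (j > 0 && !miss[j]) {
        coords[i, ] <- reflect_across_plane(coords[j, , drop = FALSE], plane)
        miss[i] <- FALSE
        provenance[i] <- "mirror"
      }
    }
  }

  # stage 2: TPS from template to the preserved (incl. mirrored) landmarks
  if (any(miss)) {
    obs <- which(!miss)
    if (length(obs) < 5)
      stop("cannot impute landmarks ", paste(which(miss), collapse = ", "),
           ": fewer than 5 preserved control points for TPS")
    tr <- tryCatch(
      tps_fit(template$coords[obs, , drop = FALSE], coords[obs, , drop = FALSE]),
      error = function(e)
        stop("cannot impute landmarks ", paste(which(miss), collapse = ", "),
             ": ", conditionMessage(e)))
    coords[miss, ] <- tps_apply(tr, template$coords[miss, , drop = FALSE])
    provenance[miss] <- "tps"
    miss[miss] <- FALSE
  }
  out <- landmark_config(coords, config$specimen_id,
                         missing = rep(FALSE, k), group = config$group)
  out$provenance <- provenance
  out
}
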