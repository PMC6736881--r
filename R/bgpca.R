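#' Landmark subsets emulating fossil preservation (analyses A-D)
#'
#' Each named analysis restricts the landmark template to the subset
#' preserved in a target fossil: A is the full-skull configuration (255
#' landmarks on the 780-landmark template), B the calvarium only (148,
#' excluding the specimen whose preservation defines it is not needed
#' there), C calvarium and face (112) and D calvarium and face (181). On a
#' template of a different size the counts scale proportionally. Subsets are
#' drawn deterministically, stratified over the template's fixed, curve and
#' surface landmarks: A samples all three roles, B only fixed + surface
#' (the calvaria carries the surface semilandmarks), C mostly curve (facial)
#' landmarks, D a balanced mixture. Specimens listed in
#' `excluded_specimens` (by id) are dropped from the analysis: by default
#' Florisbad from B and Omo II and LH18 from C.
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param scheme a [landmark_scheme].
#' @param excluded_specimens specimen ids to drop; `NULL` gives the
#'   per-analysis default.
#' @return object of class `analysis_spec` with `name`, `landmark_indices`,
#'   `excluded_specimens`.
#' @export
make_analysis_spec <- function(name, scheme, excluded_specimens = NULL) {
  counts_780 <- c(A = 255, B = 148, C = 112, D = 181)
  if (!name %in% names(counts_780))
    stop("unknown analysis '", name, "'; use A, B, C or D")
  k <- scheme$n_landmarks
  count <- if (k == 780) counts_780[[name]] else
    max(8, round(counts_780[[name]] / 780 * k))
  fixed <- which(scheme$roles == "fixed")
  curve <- which(scheme$roles == "curve")
  surf <- which(scheme$roles == "surface")
  take <- function(pool, m) {
    m <- min(m, length(pool))
    if (m <= 0) integer(0) else pool[unique(round(seq(1, length(pool), length.out = m)))]
  }
  idx <- switch(name,
    A = {      # full skull, proportional over roles
      nf <- round(count * length(fixed) / k)
      ncv <- round(count * length(curve) / k)
      c(take(fixed, nf), take(curve, ncv), take(surf, count - nf - ncv))
    },
    B = {      # calvarium: surface semilandmarks plus fixed points
      nf <- min(length(fixed), round(count * 0.25))
      c(take(fixed, nf), take(surf, count - nf))
    },
    C = {      # mostly facial: curves plus some fixed and surface
      ncv <- min(length(curve), round(count * 0.6))
      nf <- min(length(fixed), round(count * 0.2))
      c(take(curve, ncv), take(fixed, nf), take(surf, count - ncv - nf))
    },
    D = {      # calvarium and face, balanced
      nf <- min(length(fixed), round(count * 0.2))
      ncv <- min(length(curve), round(count * 0.3))
      c(take(fixed, nf), take(curve, ncv), take(surf, count - nf - ncv))
    })
  idx <- sort(unique(idx))
  # pad deterministically if rounding fell short
  if (length(idx) < count) {
    pool <- setdiff(seq_len(k), idx)
    idx <- sort(c(idx, take(pool, count - length(idx))))
  }
  if (is.null(excluded_specimens))
    excluded_specimens <- switch(name, B = "Florisbad",
                                 C = c("Omo II", "LH18"), character(0))
  structure(list(name = name, landmark_indices = idx,
                 excluded_specimens = excluded_specimens),
            class = "analysis_spec")
}

#' @export
print.analysis_spec <- function(x, ...) {
  cat("Analysis", x$name, "-", length(x$landmark_indices), "landmarks")
  if (length(x$excluded_specimens))
    cat("; excludes:", paste(x$excluded_specimens, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Between-group principal component analysis
#'
#' PCA of the unweighted group mean shapes (centred on the mean of means),
#' with every individual and every "passive" (ungrouped) specimen projected
#' onto the resulting axes. The g group means span at most g - 1
#' dimensions, and their full-space Euclidean distances are reproduced
#' exactly by their score-space distances. Axis signs are canonicalized
#' (largest-magnitude loading positive) so results are reproducible
#' bit-for-bit for identical input ordering.
#'
#' @param individuals list of aligned [landmark_config] objects with group
#'   labels (all from one common GPA restricted to the analysis subset), or
#'   an `aligned_sample`.
#' @param passive optional list of aligned ungrouped configurations (e.g.
#'   vLCAs, fossils) from the same superimposition.
#' @param grouping optional group labels overriding the configs' own.
#' @return object of class `bgpca_result` with `group_means` (g x 3k),
#'   `eigenvectors` ((g-1) x 3k), `eigenvalues`, `variance_fractions`,
#'   `scores` (individuals), `passive_scores`, `groups`.
#' @export
bgpca <- function(individuals, passive = NULL, grouping = NULL) {
  if (inherits(individuals, "aligned_sample")) individuals <- individuals$configs
  if (is.null(grouping))
    grouping <- vapply(individuals, function(cf)
      if (is.null(cf$group)) NA_character_ else as.character(cf$group), "")
  if (anyNA(grouping)) stop("every individual needs a group")
  if (length(unique(grouping)) < 2) stop("need at least 2 groups")
  X <- do.call(rbind, lapply(individuals, function(cf) vec_shape(cf$coords)))
  means <- do.call(rbind, lapply(split(seq_along(grouping), grouping),
                                 function(ii) colMeans(X[ii, , drop = FALSE])))
  means <- means[unique(grouping), , drop = FALSE]
  g <- nrow(means)
  mu <- colMeans(means)                 # mean of means, unweighted
  Mc <- sweep(means, 2, mu)
  s <- svd(Mc, nu = g, nv = 0)
  keep <- which(s$d > max(s$d) * 1e-9)
  V <- crossprod(Mc, s$u[, keep, drop = FALSE]) %*% diag(1 / s$d[keep], length(keep))
  for (j in seq_along(keep)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  ev <- s$d[keep]^2 / max(g - 1, 1)
  scores <- sweep(X, 2, mu) %*% V
  rownames(scores) <- vapply(individuals, `[[`, "", "specimen_id")
  colnames(scores) <- paste0("bgPC", seq_along(keep))
  ps <- NULL
  if (!is.null(passive)) {
    P <- do.call(rbind, lapply(passive, function(cf)
      vec_shape(if (inherits(cf, "landmark_config")) cf$coords else cf)))
    ps <- sweep(P, 2, mu) %*% V
    rownames(ps) <- if (inherits(passive[[1]], "landmark_config"))
      vapply(passive, `[[`, "", "specimen_id") else names(passive)
    colnames(ps) <- colnames(scores)
  }
  gm_scores <- sweep(means, 2, mu) %*% V
  colnames(gm_scores) <- colnames(scores)
  structure(list(group_means = means, group_mean_scores = gm_scores,
                 eigenvectors = t(V), eigenvalues = ev,
                 variance_fractions = ev / sum(ev),
                 scores = scores, passive_scores = ps,
                 groups = grouping, center = mu),
            class = "bgpca_result")
}

#' @export
print.bgpca_result <- function(x, ...) {
  cat("Between-group PCA:", nrow(x$group_means), "groups,",
      nrow(x$scores), "individuals")
  if (!is.null(x$passive_scores))
    cat(",", nrow(x$passive_scores), "passive specimens")
  cat("\n  bgPC1-2 variance:",
      sprintf("%.1f%%", 100 * sum(x$variance_fractions[1:min(2, length(x$variance_fractions))])), "\n")
  invisible(x)
}

#' Euclidean distance table from a between-group PCA
#'
#' Pairwise Euclidean distances among group means and passive specimens in
#' the full (g-1)-dimensional between-group score space (for the means this
#' equals their full shape-space distance), plus the nearest group for each
#' passive specimen.
#'
#' @param result a `bgpca_result`.
#' @return object of class `distance_table`: list with `matrix` (labelled,
#'   symmetric) and `nearest` (data frame: passive specimen, nearest group,
#'   distance).
#' @export
euclidean_distance_table <- function(result) {
  stopifnot(inherits(result, "bgpca_result"))
  pts <- result$group_mean_scores
  if (!is.null(result$passive_scores)) pts <- rbind(pts, result$passive_scores)
  d <- as.matrix(stats::dist(pts))
  nearest <- NULL
  if (!is.null(result$passive_scores)) {
    gm <- rownames(result$group_mean_scores)
    nearest <- do.call(rbind, lapply(rownames(result$passive_scores), function(p) {
      dd <- d[p, gm]
      data.frame(specimen = p, nearest_group = gm[which.min(dd)],
                 distance = min(dd))
    }))
  }
  structure(list(matrix = d, nearest = nearest), class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat("Euclidean distance table (", nrow(x$matrix), " points)\n", sep = "")
  if (!is.null(x$nearest)) {
    cat("Nearest group per passive specimen:\n")
    print(x$nearest, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @rdname euclidean_distance_table
#' @param path CSV path.
#' @export
write_distance_table <- function(result, path) {
  utils::write.csv(round(result$matrix, 6), path)
  invisible(path)
}

#' Procrustes distance distributions of references against groups
#'
#' For each reference specimen (vLCA or fossil) the Procrustes distances to
#' all individuals of each group, summarised for boxplots (min, quartiles,
#' median, max).
#'
#' @param aligned an `aligned_sample` containing the grouped individuals.
#' @param references named list of aligned k x 3 configurations (or
#'   [landmark_config]s) from the same superimposition.
#' @param grouping optional labels overriding the configs' groups.
#' @return object of class `procdist_report`: list with `distances` (long
#'   data frame reference/group/specimen/distance) and `summary` (per
#'   reference x group: n, min, q1, median, q3, max).
#' @export
procrustes_distance_report <- function(aligned, references, grouping = NULL) {
  stopifnot(inherits(aligned, "aligned_sample"))
  if (is.null(grouping))
    grouping <- vapply(aligned$configs, function(cf)
      if (is.null(cf$group)) NA_character_ else as.character(cf$group), "")
  if (anyNA(grouping)) stop("every individual needs a group")
  if (is.null(names(references)))
    names(references) <- vapply(references, function(r)
      if (inherits(r, "landmark_config")) r$specimen_id else "reference", "")
  rows <- list()
  for (rn in names(references)) {
    r <- references[[rn]]
    rc <- if (inherits(r, "landmark_config")) r$coords else as.matrix(r)
    for (i in seq_along(aligned$configs)) {
      rows[[length(rows) + 1]] <- data.frame(
        reference = rn, group = grouping[i],
        specimen = aligned$configs[[i]]$specimen_id,
        distance = procrustes_distance(rc, aligned$configs[[i]]$coords))
    }
  }
  long <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(split(long, long[c("reference", "group")]), function(d) {
    q <- stats::quantile(d$distance, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(reference = d$reference[1], group = d$group[1], n = nrow(d),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  }))
  rownames(sm) <- NULL
  structure(list(distances = long, summary = sm), class = "procdist_report")
}

#' @export
print.procdist_report <- function(x, ...) {
  cat("Procrustes distance report:",
      length(unique(x$summary$reference)), "references x",
      length(unique(x$summary$group)), "groups\n")
  print(utils::head(x$summary, 12), row.names = FALSE, digits = 4)
  invisible(x)
}
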