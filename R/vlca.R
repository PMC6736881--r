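#' Estimate virtual last common ancestor (vLCA) shapes on a chronogram
#'
#' The central model fit of the package. Tip taxa are described by the
#' principal components of their mean shapes; every PC evolves independently
#' by Brownian motion on the dated tree (the PCs are mathematically
#' uncorrelated), so the maximum likelihood ancestral state of each PC at
#' each internal node is the re-rooted GLS estimate of
#' [bm_ancestral_states()], with a 95% confidence envelope from the ML rate.
#' The per-node score vectors are then rotated back into landmark space
#' (mean shape + scores x eigenvectors) and rescaled to unit centroid size,
#' giving a virtual ancestral landmark configuration for every node —
#' including the "virtual last common ancestor" of any clade of interest.
#'
#' @param shapes named list of k x 3 mean shapes, one per tip taxon (names
#'   must match the tree's tip labels), or a precomputed `shape_pca` whose
#'   score rows are named by tip.
#' @param tree a [chronogram] or preset name (`"h1"`, `"h2"`, `"h1b"`,
#'   `"h2b"`).
#' @param reml passed to [bm_ancestral_states()].
#' @return an object of class `vlca`: list with `tree`, `pca`, `ancestral`
#'   (the `ancestral_estimates`), `node_landmarks` (named list of k x 3
#'   unit-size configurations per internal node), and `call`. Methods:
#'   `print`, `summary`, `coef` (ancestral PC scores), `confint`, `predict`
#'   (landmarks or scores for chosen nodes), `plot` (phylomorphospace).
#' @export
vlca <- function(shapes, tree, reml = FALSE) {
  tree <- as_chronogram(tree)
  pca <- if (inherits(shapes, "shape_pca")) shapes else {
    if (is.null(names(shapes))) stop("shapes must be named by tip taxon")
    bad <- union(setdiff(names(shapes), tree$phy$tip.label),
                 setdiff(tree$phy$tip.label, names(shapes)))
    if (length(bad))
      stop("tip/taxon mismatch: ", paste(bad, collapse = ", "))
    shape_pca(shapes)
  }
  if (!setequal(rownames(pca$scores), tree$phy$tip.label))
    stop("tip/taxon mismatch: ",
         paste(union(setdiff(rownames(pca$scores), tree$phy$tip.label),
                     setdiff(tree$phy$tip.label, rownames(pca$scores))),
               collapse = ", "))
  anc <- bm_ancestral_states(tree, pca$scores, reml = reml)
  lms <- backrotate_scores(pca, anc$estimates)
  lms <- lapply(lms, function(m) { m <- center_config(m); m / csize(m) })
  names(lms) <- rownames(anc$estimates)
  structure(list(tree = tree, pca = pca, ancestral = anc,
                 node_landmarks = lms, call = match.call()),
            class = "vlca")
}

#' @export
print.vlca <- function(x, ...) {
  cat("Virtual LCA model\n")
  cat("  tree:", length(x$tree$phy$tip.label), "tips, root age",
      format(x$tree$root_age), "ka\n")
  cat("  shape space:", x$pca$k, "landmarks,",
      length(x$pca$eigenvalues), "PCs\n")
  cat("  internal nodes estimated:", nrow(x$ancestral$estimates), "\n")
  invisible(x)
}

#' @export
summary.vlca <- function(object, ...) {
  vf <- object$pca$variance_fractions
  root <- object$ancestral$estimates[1, ]
  se <- sqrt(object$ancestral$variances[1, ])
  structure(list(n_tips = length(object$tree$phy$tip.label),
                 root_age = object$tree$root_age,
                 n_pcs = length(vf),
                 pc_var = vf,
                 sigma2 = object$ancestral$sigma2,
                 root = cbind(estimate = root, se = se,
                              lower = root - 1.96 * se,
                              upper = root + 1.96 * se)),
            class = "summary.vlca")
}

#' @export
print.summary.vlca <- function(x, ...) {
  cat("Virtual LCA model:", x$n_tips, "tip taxa, root age",
      format(x$root_age), "ka\n")
  cat(sprintf("Shape PCA: %d components; PC1-%d carry %.1f%% of variance\n",
              x$n_pcs, min(3, x$n_pcs),
              100 * sum(x$pc_var[seq_len(min(3, x$n_pcs))])))
  cat("Root (tree-wide ancestor) on the leading PCs:\n")
  print(round(x$root[seq_len(min(3, nrow(x$root))), , drop = FALSE], 4))
  invisible(x)
}

#' @export
coef.vlca <- function(object, ...) object$ancestral$estimates

#' @export
confint.vlca <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(object$ancestral$variances)
  lo <- object$ancestral$estimates - z * se
  hi <- object$ancestral$estimates + z * se
  if (!missing(parm)) { lo <- lo[, parm, drop = FALSE]; hi <- hi[, parm, drop = FALSE] }
  list(lower = lo, upper = hi)
}

#' Predict ancestral landmarks or scores at tree nodes
#'
#' @param object a fitted [vlca] model.
#' @param nodes ape node numbers (default: all internal nodes). The MRCA of
#'   a set of tips can be found with `ape::getMRCA(fit$tree$phy, tips)`.
#' @param type `"landmarks"` (unit-size k x 3 configurations) or `"scores"`.
#' @param ... unused.
#' @export
predict.vlca <- function(object, nodes = NULL,
                         type = c("landmarks", "scores"), ...) {
  type <- match.arg(type)
  ids <- rownames(object$ancestral$estimates)
  if (is.null(nodes)) nodes <- ids
  nodes <- as.character(nodes)
  if (!all(nodes %in% ids))
    stop("unknown node(s): ", paste(setdiff(nodes, ids), collapse = ", "))
  if (type == "scores") object$ancestral$estimates[nodes, , drop = FALSE]
  else object$node_landmarks[nodes]
}

#' Phylomorphospace projection of a fitted vLCA model
#'
#' Places tips at their PCA scores and internal nodes at their ancestral
#' score estimates on the selected PCs, connects them along the tree's
#' edges, and attaches per-node 95% confidence ellipses whose semi-axes are
#' 1.96 standard errors on each displayed PC (axis-aligned: the per-PC
#' variances are the only uncertainty the BM model yields).
#'
#' @param fit a [vlca] object.
#' @param pcs integer vector of PCs to include (default first 3).
#' @return list of data frames `points` (label, type tip/node, scores),
#'   `edges` (from/to coordinates) and `ellipses` (node, per-PC semi-axes).
#' @export
phylomorphospace <- function(fit, pcs = 1:3) {
  stopifnot(inherits(fit, "vlca"))
  q <- ncol(fit$pca$scores)
  pcs <- as.integer(pcs)
  if (!length(pcs) || any(pcs < 1) || any(pcs > q))
    stop("requested PC beyond available components (q = ", q, ")")
  phy <- fit$tree$phy
  n <- length(phy$tip.label)
  tip_sc <- fit$pca$scores[phy$tip.label, pcs, drop = FALSE]
  node_sc <- fit$ancestral$estimates[, pcs, drop = FALSE]
  all_sc <- rbind(tip_sc, node_sc)
  lab <- c(phy$tip.label, rownames(node_sc))
  pts <- data.frame(label = lab,
                    type = rep(c("tip", "node"), c(n, nrow(node_sc))),
                    all_sc, row.names = NULL, check.names = FALSE)
  idx <- function(node) if (node <= n) node else n + which(rownames(node_sc) == as.character(node))
  e_from <- t(vapply(phy$edge[, 1], function(nd) all_sc[idx(nd), ], numeric(length(pcs))))
  e_to <- t(vapply(phy$edge[, 2], function(nd) all_sc[idx(nd), ], numeric(length(pcs))))
  colnames(e_from) <- paste0("from_", colnames(tip_sc))
  colnames(e_to) <- paste0("to_", colnames(tip_sc))
  ell <- data.frame(node = rownames(node_sc),
                    1.96 * sqrt(fit$ancestral$variances[, pcs, drop = FALSE]),
                    row.names = NULL, check.names = FALSE)
  names(ell)[-1] <- paste0("semi_", colnames(tip_sc))
  list(points = pts, edges = data.frame(e_from, e_to), ellipses = ell)
}

#' @export
#' @param x a `vlca` fit.
#' @param pcs two PCs to display.
#' @param ... passed to `plot`.
#' @rdname phylomorphospace
plot.vlca <- function(x, pcs = c(1, 2), ...) {
  pm <- phylomorphospace(x, pcs = pcs)
  cn <- names(pm$points)[-(1:2)]
  xy <- as.matrix(pm$points[, cn])
  plot(xy, type = "n",
       xlab = cn[1], ylab = cn[2], asp = 1, ...)
  segments(pm$edges[, 1], pm$edges[, 2],
           pm$edges[, 3], pm$edges[, 4], col = "grey60")
  tip <- pm$points$type == "tip"
  points(xy[tip, , drop = FALSE], pch = 19)
  points(xy[!tip, , drop = FALSE], pch = 21, bg = "white")
  theta <- seq(0, 2 * pi, length.out = 60)
  for (i in seq_len(nrow(pm$ellipses))) {
    cx <- xy[!tip, , drop = FALSE][i, ]
    a <- pm$ellipses[i, 2]; b <- pm$ellipses[i, 3]
    lines(cx[1] + a * cos(theta), cx[2] + b * sin(theta),
          col = "grey40", lty = 3)
  }
  invisible(pm)
}

#' Warp a reference mesh onto a target landmark configuration
#'
#' Thin-plate spline warping: the TPS mapping the reference landmarks onto
#' the target landmarks is applied to every mesh vertex; faces are
#' unchanged. Used to render a fully surfaced "virtual ancestor" from a real
#' skull model.
#'
#' @param reference_mesh a [mesh3d_simple] (see [read_ply()]).
#' @param reference_landmarks k x 3 landmarks in the mesh's space.
#' @param target k x 3 target landmarks, or a k x 3 element of
#'   `vlca$node_landmarks`, or a [landmark_config].
#' @return a warped mesh.
#' @export
warp_reference <- function(reference_mesh, reference_landmarks, target) {
  if (inherits(target, "landmark_config")) target <- target$coords
  target <- as.matrix(target)
  reference_landmarks <- as.matrix(reference_landmarks)
  if (nrow(reference_landmarks) != nrow(target))
    stop("landmark count mismatch between reference and target")
  tr <- tps_fit(reference_landmarks, target)
  out <- reference_mesh
  out$vertices <- tps_apply(tr, reference_mesh$vertices)
  out$normals <- NULL
  out
}
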