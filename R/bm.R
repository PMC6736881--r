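#' Maximum likelihood ancestral states under Brownian motion
#'
#' For each trait (column of `tip_values`) the root state is the generalized
#' least squares estimate a = (1'C^-1 1)^-1 1'C^-1 y with C the phylogenetic
#' covariance matrix, and the Brownian rate is the ML estimator
#' sigma2 = (y - 1a)' C^-1 (y - 1a) / N. Every internal node is estimated by
#' re-rooting the tree at that node and applying the root formula; the
#' re-rooted covariance C_node is obtained directly from patristic distances
#' (C_node[i, j] = (d(x, i) + d(x, j) - d(i, j)) / 2 for node x and tips
#' i, j). The estimation variance at a node is sigma2 * (1'C_node^-1 1)^-1
#' and the 95% confidence envelope is the estimate +/- 1.96 standard errors.
#' These are the per-node "most likely ancestral shapes with 95% confidence
#' envelopes" when the traits are principal components of shape.
#'
#' @param tree a [chronogram] or preset name (`"h1"`, ...).
#' @param tip_values N x p matrix of trait values; row names must match the
#'   tree's tip labels (rows are reordered to the tree's order), or rows are
#'   assumed to already be in tip order.
#' @param reml if `TRUE` divide the rate quadratic form by N - 1 instead of
#'   N (restricted maximum likelihood); default `FALSE` (ML).
#' @return object of class `ancestral_estimates`: list with `estimates`,
#'   `variances`, `ci_lower`, `ci_upper` (internal nodes x p, row names are
#'   ape node numbers, the first row is the root), `sigma2` (length p) and
#'   `tree`.
#' @export
bm_ancestral_states <- function(tree, tip_values, reml = FALSE) {
  tree <- as_chronogram(tree)
  phy <- tree$phy
  n <- length(phy$tip.label)
  Y <- as.matrix(tip_values)
  if (ncol(Y) < 1) stop("need at least one trait (p >= 1)")
  if (!is.null(rownames(Y))) {
    if (!setequal(rownames(Y), phy$tip.label))
      stop("tip_values rows do not match tree tips; offenders: ",
           paste(union(setdiff(rownames(Y), phy$tip.label),
                       setdiff(phy$tip.label, rownames(Y))), collapse = ", "))
    Y <- Y[phy$tip.label, , drop = FALSE]
  } else if (nrow(Y) != n) stop("tip_values must have one row per tip")
  D <- ape::dist.nodes(phy)
  nodes <- (n + 1):(n + phy$Nnode)
  root <- n + 1
  est <- var_ <- matrix(NA_real_, length(nodes), ncol(Y),
                        dimnames = list(as.character(nodes), colnames(Y)))
  dtt <- D[seq_len(n), seq_len(n)]
  sigma2 <- NULL
  for (m in seq_along(nodes)) {
    x <- nodes[m]
    dx <- D[x, seq_len(n)]
    Cx <- (outer(dx, dx, `+`) - dtt) / 2
    w <- tryCatch(solve(Cx, rep(1, n)), error = function(e)
      stop("singular phylogenetic covariance at node ", x))
    sw <- sum(w)
    est[m, ] <- as.vector(crossprod(w, Y)) / sw
    if (x == root) {
      R <- sweep(Y, 2, est[m, ])
      CiR <- solve(Cx, R)
      sigma2 <- colSums(R * CiR) / (if (reml) n - 1 else n)
    }
    var_[m, ] <- 1 / sw   # scaled by sigma2 below
  }
  var_ <- sweep(var_, 2, sigma2, `*`)
  se <- sqrt(var_)
  structure(list(estimates = est, variances = var_,
                 ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se,
                 sigma2 = sigma2, tree = tree, reml = reml),
            class = "ancestral_estimates")
}

#' @export
print.ancestral_estimates <- function(x, ...) {
  cat("Brownian-motion ancestral estimates:", nrow(x$estimates),
      "internal nodes,", ncol(x$estimates), "trait(s)\n")
  cat("  rate sigma2 (", if (x$reml) "REML" else "ML", "): ",
      paste(signif(x$sigma2, 4), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Multivariate phylogenetic signal (Kmult)
#'
#' Multivariate generalization of Blomberg's K: the ratio of the observed to
#' the Brownian-expected partitioning of trait variation on the phylogeny,
#'
#'   K = \[ tr(Z'Z) / tr(Z'C^-1 Z) \] / \[ (tr(C) - N (1'C^-1 1)^-1) / (N-1) \]
#'
#' with Z = Y - 1a, a the phylogenetic GLS mean and C the phylogenetic
#' covariance matrix. K = 1 is the Brownian expectation; significance is
#' assessed by permuting tip rows of Y.
#'
#' @param tree a [chronogram] or preset name.
#' @param tip_values N x p matrix (row names matched to tip labels if
#'   present).
#' @param n_perm number of permutations (default 999).
#' @param seed mandatory integer seed for the permutations.
#' @return object of class `kmult_result`: list with `K`, `p_value`,
#'   `n_perm`, `seed` and `K_perm`.
#' @export
kmult <- function(tree, tip_values, n_perm = 999, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  tree <- as_chronogram(tree)
  n <- length(tree$phy$tip.label)
  if (n < 4) stop("need at least 4 tips")
  Y <- as.matrix(tip_values)
  if (!is.null(rownames(Y))) Y <- Y[tree$phy$tip.label, , drop = FALSE]
  if (sum(scale(Y, scale = FALSE)^2) < 1e-300)
    stop("zero total variance in tip values; K undefined")
  C <- phylo_covariance(tree)
  Ci <- solve(C)
  w <- Ci %*% rep(1, n)
  denom_const <- (sum(diag(C)) - n / sum(w)) / (n - 1)
  kstat <- function(Ym) {
    a <- as.vector(crossprod(w, Ym)) / sum(w)
    Z <- sweep(Ym, 2, a)
    (sum(Z * Z) / sum(Z * (Ci %*% Z))) / denom_const
  }
  K_obs <- kstat(Y)
  K_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    kstat(Y[sample.int(n), , drop = FALSE]), 1))
  p <- (1 + sum(K_perm >= K_obs)) / (1 + n_perm)
  structure(list(K = K_obs, p_value = p, n_perm = n_perm,
                 seed = as.integer(seed), K_perm = K_perm),
            class = "kmult_result")
}

#' @export
print.kmult_result <- function(x, ...) {
  cat(sprintf("Kmult = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$K, x$p_value, x$n_perm, x$seed))
  invisible(x)
}
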