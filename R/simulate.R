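#' Skull-like bilaterally symmetric landmark template
#'
#' Builds a deterministic, exactly symmetric point configuration on an
#' ellipsoid (semi-axes 70 x 90 x 65 mm, a skull-scale surface) together
#' with its [landmark_scheme]: fixed landmarks spread over the surface,
#' curve semilandmarks along great-ellipse arcs on the anterior ("facial")
#' region, and surface semilandmarks covering the upper ("calvarial")
#' region with 6-nearest-neighbour tangent graphs. Defaults reproduce the
#' proportions of a dense cranial template: 56 fixed, 116 curve and 608
#' surface points (780 in total).
#'
#' @param k_fixed number of fixed landmarks (>= 10, even; 8 lie on the
#'   midline).
#' @param n_curves number of curve chains (even; chains come in mirror
#'   pairs).
#' @param curve_len points per chain.
#' @param n_surface number of surface semilandmarks (even).
#' @param seed integer seed controlling the quasi-random surface placement.
#' @return list with `scheme` (a [landmark_scheme]) and `base_shape`
#'   (k x 3 matrix, mm).
#' @export
make_template <- function(k_fixed = 56, n_curves = 4, curve_len = 29,
                          n_surface = 608, seed = 1) {
  if (k_fixed < 10 || k_fixed %% 2 != 0) stop("k_fixed must be even and >= 10")
  if (n_curves %% 2 != 0) stop("n_curves must be even (mirror pairs)")
  if (n_surface %% 2 != 0) stop("n_surface must be even (mirror pairs)")
  radii <- c(70, 90, 65)
  on_ell <- function(theta, phi)      # x: left-right, y: antero-post, z: up
    cbind(radii[1] * cos(phi) * sin(theta),
          radii[2] * cos(phi) * cos(theta),
          radii[3] * sin(phi))
  n_mid <- 8L
  n_pair_fixed <- (k_fixed - n_mid) / 2
  # midline fixed landmarks: sagittal arc (x = 0)
  mid_phi <- seq(-0.9 * pi / 2, 0.9 * pi / 2, length.out = n_mid)
  mid_pts <- cbind(0, radii[2] * cos(mid_phi), radii[3] * sin(mid_phi))
  # paired fixed landmarks: ring at mid-height, right side, mirrored
  fx_th <- seq(0.25, pi - 0.25, length.out = n_pair_fixed)
  fx_r <- on_ell(fx_th, rep(-0.35, n_pair_fixed))
  half_curves <- n_curves / 2
  cv_r <- list()
  for (cchain in seq_len(half_curves)) {
    phi0 <- -0.15 - 0.22 * (cchain - 1)   # anterior arcs, facial region
    th <- seq(0.12, 1.25, length.out = curve_len)
    cv_r[[cchain]] <- on_ell(th, phi0 + 0.1 * sin(th * 2))
  }
  ns_half <- n_surface / 2
  # quasi-random (golden-angle spiral) points on the upper right octant
  ii <- seq_len(ns_half)
  jit <- with_seed(seed, stats::runif(2 * ns_half, -0.01, 0.01))
  frac <- (ii * 0.61803398875) %% 1
  th_s <- 0.15 + frac * (pi - 0.3) + jit[ii]
  ph_s <- 0.15 + (ii / (ns_half + 1)) * 1.15 + jit[ns_half + ii]
  sf_r <- on_ell(th_s, ph_s)

  mirror_x <- function(m) m %*% diag(c(-1, 1, 1))
  coords <- rbind(mid_pts, fx_r, mirror_x(fx_r),
                  do.call(rbind, cv_r), mirror_x(do.call(rbind, cv_r)),
                  sf_r, mirror_x(sf_r))
  k <- nrow(coords)
  roles <- c(rep("fixed", n_mid + 2 * n_pair_fixed),
             rep("curve", n_curves * curve_len),
             rep("surface", n_surface))
  i_fix_r <- n_mid + seq_len(n_pair_fixed)
  i_fix_l <- n_mid + n_pair_fixed + seq_len(n_pair_fixed)
  cv_start <- n_mid + 2 * n_pair_fixed
  i_cv_r <- cv_start + seq_len(half_curves * curve_len)
  i_cv_l <- cv_start + half_curves * curve_len + seq_len(half_curves * curve_len)
  sf_start <- cv_start + n_curves * curve_len
  i_sf_r <- sf_start + seq_len(ns_half)
  i_sf_l <- sf_start + ns_half + seq_len(ns_half)
  pairs <- rbind(cbind(i_fix_l, i_fix_r), cbind(i_cv_l, i_cv_r),
                 cbind(i_sf_l, i_sf_r))
  curves <- list()
  for (cchain in seq_len(half_curves)) {
    base <- cv_start + (cchain - 1) * curve_len
    curves[[length(curves) + 1]] <- base + seq_len(curve_len)
    curves[[length(curves) + 1]] <- base + half_curves * curve_len + seq_len(curve_len)
  }
  surf_idx <- c(i_sf_r, i_sf_l)
  nb <- lapply(seq_along(surf_idx), function(j) {
    p <- coords[surf_idx[j], ]
    d2 <- colSums((t(coords[surf_idx, , drop = FALSE]) - p)^2)
    surf_idx[order(d2)[2:7]]
  })
  scheme <- landmark_scheme(k, roles, curves,
                            surfaces = list(indices = surf_idx, neighbors = nb),
                            symmetry_pairs = pairs,
                            midline = seq_len(n_mid))
  list(scheme = scheme, base_shape = coords)
}

#' Simulate Brownian-motion evolution of a shape on a chronogram
#'
#' Each of the 3k coordinates evolves independently along the tree: a child
#' node's shape is its parent's shape plus Gaussian increments with variance
#' `rate` x branch length. Shapes are recorded at every node; the root shape
#' is `base_shape`. No renormalization is applied during simulation (size
#' variation emerges and is removed downstream by GPA).
#'
#' @param tree a [chronogram] or preset name.
#' @param base_shape k x 3 matrix (mm).
#' @param rate Brownian rate, mm^2 per ka per coordinate.
#' @param seed integer seed.
#' @return list with `tip_shapes` (named list, k x 3) and `node_shapes`
#'   (named by ape node number; the root entry equals `base_shape`).
#' @export
simulate_bm_shapes <- function(tree, base_shape, rate, seed) {
  if (rate < 0) stop("rate must be >= 0")
  tree <- as_chronogram(tree)
  phy <- ape::reorder.phylo(tree$phy, "cladewise")
  n <- length(phy$tip.label)
  base_shape <- as.matrix(base_shape)
  k3 <- length(base_shape)
  shapes <- vector("list", n + phy$Nnode)
  shapes[[n + 1]] <- base_shape
  with_seed(seed, {
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      bl <- phy$edge.length[e]
      shapes[[ch]] <- shapes[[par]] +
        matrix(stats::rnorm(k3, 0, sqrt(rate * bl)), nrow(base_shape), 3)
    }
  })
  tips <- shapes[seq_len(n)]
  names(tips) <- phy$tip.label
  nodes <- shapes[(n + 1):(n + phy$Nnode)]
  names(nodes) <- as.character((n + 1):(n + phy$Nnode))
  list(tip_shapes = tips, node_shapes = nodes)
}

#' Sample individuals around a population mean shape
#'
#' Adds isotropic, landmark-independent Gaussian noise (`within_sd` mm per
#' coordinate) to the mean shape.
#'
#' @param mean_shape k x 3 matrix.
#' @param n number of individuals.
#' @param within_sd within-population standard deviation (mm).
#' @param seed integer seed.
#' @param group optional group label attached to each individual.
#' @return list of [landmark_config]s.
#' @export
sample_population <- function(mean_shape, n, within_sd, seed, group = NULL) {
  stopifnot(n >= 1)
  mean_shape <- as.matrix(mean_shape)
  with_seed(seed, lapply(seq_len(n), function(i)
    landmark_config(mean_shape + matrix(stats::rnorm(length(mean_shape), 0, within_sd),
                                        nrow(mean_shape), 3),
                    paste0(if (is.null(group)) "ind" else group, "_", i),
                    group = group)))
}

#' Apply a fossil preservation mask to a configuration
#'
#' Marks as missing every landmark outside the named analysis subset (see
#' [make_analysis_spec()]), optionally plus random unilateral deletions
#' (right-side members of bilateral pairs) to exercise mirror imputation.
#'
#' @param config a [landmark_config].
#' @param pattern `"A"`, `"B"`, `"C"`, `"D"`, or `"custom"` (then
#'   `keep_indices` must be given).
#' @param scheme a [landmark_scheme].
#' @param seed integer seed (used only for unilateral deletions).
#' @param unilateral_frac fraction of preserved bilateral pairs whose right
#'   member is additionally deleted (default 0).
#' @param keep_indices custom preserved index set for `pattern = "custom"`.
#' @return a [landmark_config] with an updated missing mask.
#' @export
apply_fossil_mask <- function(config, pattern, scheme, seed = 1,
                              unilateral_frac = 0, keep_indices = NULL) {
  config <- as_config(config)
  k <- scheme$n_landmarks
  keep <- if (identical(pattern, "custom")) {
    if (is.null(keep_indices)) stop("custom pattern needs keep_indices")
    as.integer(keep_indices)
  } else make_analysis_spec(pattern, scheme)$landmark_indices
  miss <- rep(TRUE, k)
  miss[keep] <- FALSE
  if (unilateral_frac > 0 && nrow(scheme$symmetry_pairs)) {
    pr <- scheme$symmetry_pairs
    alive <- which(!miss[pr[, 1]] & !miss[pr[, 2]])
    ndel <- floor(unilateral_frac * length(alive))
    if (ndel > 0) {
      del <- with_seed(seed, sample(alive, ndel))
      miss[pr[del, 2]] <- TRUE
    }
  }
  coords <- config$coords
  coords[miss, ] <- NA
  landmark_config(coords, config$specimen_id, missing = miss,
                  group = config$group)
}

#' Generate a complete synthetic landmark dataset on a chronogram
#'
#' End-to-end data generator with known truth: population mean shapes evolve
#' by Brownian motion from the template's base shape along the chosen
#' chronogram; extant taxa receive `individuals_per_taxon` individuals with
#' isotropic within-population noise, fossil (non-contemporaneous) taxa one
#' individual each; fossil stand-ins cut to the analysis preservation
#' patterns can be added. Regeneration with the same seed is bit-identical.
#'
#' Defaults emulate the structure of a 21-population modern human cranial
#' sample with fossil outgroups: preset tree `h1`, a 780-landmark template,
#' 10 individuals per extant population, Brownian rate 0.004 mm^2/ka and
#' within-population standard deviation 1 mm.
#'
#' @param tree a [chronogram] or preset name (default `"h1"`).
#' @param template result of [make_template()]; built with defaults if
#'   `NULL`.
#' @param rate Brownian rate (mm^2/ka).
#' @param within_sd within-population standard deviation (mm).
#' @param individuals_per_taxon individuals per extant taxon.
#' @param fossil_masks named character vector mapping synthetic fossil
#'   stand-in ids to preservation patterns, e.g.
#'   `c(fossil_syn_1 = "A")`; each stand-in is drawn from the root shape
#'   lineage with independent noise and masked. Empty by default.
#' @param seed integer seed; all randomness derives from it.
#' @return object of class `synthetic_dataset`: list with `tree`,
#'   `scheme`, `base_shape`, `individuals` (list of [landmark_config]),
#'   `true_tip_shapes`, `true_node_shapes`, `fossils` (masked configs),
#'   `params`.
#' @export
simulate_dataset <- function(tree = "h1", template = NULL, rate = 0.004,
                             within_sd = 1, individuals_per_taxon = 10,
                             fossil_masks = character(0), seed = 1) {
  tree <- as_chronogram(tree)
  if (is.null(template)) template <- make_template(seed = seed)
  seed <- as.integer(seed)
  sim <- simulate_bm_shapes(tree, template$base_shape, rate, seed)
  individuals <- list()
  tipnames <- tree$phy$tip.label
  for (i in seq_along(tipnames)) {
    tn <- tipnames[i]
    n_i <- if (tree$tip_ages[tn] > 1e-8) 1L else as.integer(individuals_per_taxon)
    individuals <- c(individuals,
                     sample_population(sim$tip_shapes[[tn]], n_i, within_sd,
                                       seed = seed + 1000L + i, group = tn))
  }
  fossils <- list()
  if (length(fossil_masks)) {
    root_shape <- template$base_shape
    for (j in seq_along(fossil_masks)) {
      id <- names(fossil_masks)[j]
      raw <- sample_population(root_shape, 1, within_sd,
                               seed = seed + 5000L + j, group = NULL)[[1]]
      raw$specimen_id <- id
      fossils[[id]] <- apply_fossil_mask(raw, fossil_masks[[j]],
                                         template$scheme,
                                         seed = seed + 6000L + j)
    }
  }
  structure(list(tree = tree, scheme = template$scheme,
                 base_shape = template$base_shape,
                 individuals = individuals,
                 true_tip_shapes = sim$tip_shapes,
                 true_node_shapes = sim$node_shapes,
                 fossils = fossils,
                 params = list(rate = rate, within_sd = within_sd,
                               individuals_per_taxon = individuals_per_taxon,
                               seed = seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic landmark dataset:", length(x$individuals), "individuals,",
      length(x$tree$phy$tip.label), "taxa,",
      x$scheme$n_landmarks, "landmarks\n")
  cat("  rate =", x$params$rate, "mm^2/ka, within_sd =", x$params$within_sd,
      "mm, seed =", x$params$seed, "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk for exact regeneration
#'
#' Writes per-specimen landmark CSVs, the tree as Newick, the scheme as
#' YAML, and a JSON manifest holding the generator parameters and seed.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  write_scheme(dataset$scheme, file.path(dir, "scheme.yaml"))
  for (cf in c(dataset$individuals, unname(dataset$fossils)))
    write_landmarks_csv(cf, file.path(dir, paste0(cf$specimen_id, ".csv")))
  jsonlite::write_json(c(dataset$params,
                         list(n_individuals = length(dataset$individuals))),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
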