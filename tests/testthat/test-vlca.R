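make_means <- function(n = 6, k = 12, seed = 71, spread = 0.1) {
  set.seed(seed)
  base <- rand_config(k, seed = seed)
  out <- lapply(seq_len(n), function(i)
    unit_shape(base + matrix(rnorm(3 * k, sd = spread), k, 3)))
  names(out) <- paste0("t", seq_len(n))
  out
}

test_that("population mean shapes: identity, midpoint and unbalanced caveat", {
  x <- unit_shape(rand_config(10, seed = 72))
  y <- unit_shape(rand_config(10, seed = 73))
  al <- structure(list(
    configs = list(landmark_config(x, "a", group = "G"),
                   landmark_config(x, "b", group = "G"),
                   landmark_config(y, "c", group = "H")),
    consensus = x, centroid_sizes = c(1, 1, 1), n_iterations = 1),
    class = "aligned_sample")
  ms <- population_mean_shapes(al)
  expect_equal(ms$G, x, tolerance = 1e-12)
  # two-individual group -> midpoint
  al$configs[[2]] <- landmark_config(y, "b", group = "G")
  ms2 <- population_mean_shapes(al)
  mid <- (x + y) / 2
  expect_equal(ms2$G, mid / sqrt(sum(sweep(mid, 2, colMeans(mid))^2)),
               tolerance = 1e-12)
  # unbalanced groups: mean of means differs from the grand mean
  mom <- Reduce(`+`, ms2) / 2
  grand <- (x + y + y) / 3
  expect_gt(max(abs(unit_shape(mom) - unit_shape(grand))), 1e-4)
})

test_that("shape PCA satisfies its spectral invariants", {
  ms <- make_means(n = 7)
  p <- shape_pca(ms)
  V <- p$eigenvectors
  expect_equal(V %*% t(V), diag(nrow(V)), tolerance = 1e-9)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-12)
  # reconstruction
  X <- do.call(rbind, lapply(ms, function(m) as.vector(t(m))))
  rec <- sweep(p$scores %*% V, 2, p$mean, `+`)
  expect_equal(unname(rec), unname(X), tolerance = 1e-9)
  # isometry: score distances equal shape distances
  expect_equal(dist(p$scores), dist(X), tolerance = 1e-9, ignore_attr = TRUE)
  # collinear shapes: one non-zero component
  base <- make_means(n = 1)[[1]]
  dirn <- rand_config(12, seed = 74, sd = 0.05)
  line <- lapply(1:4, function(i) base + i * dirn)
  names(line) <- paste0("t", 1:4)
  pl <- shape_pca(line)
  expect_equal(length(pl$eigenvalues), 1)
  expect_equal(pl$variance_fractions[1], 1)
  expect_error(shape_pca(line[1:2]), "at least 3")
})

test_that("vLCA on a star tree is the grand mean of the tip mean shapes", {
  ms <- make_means(n = 5)
  st <- star_tree(5)
  fit <- vlca(ms, st)
  gm <- unit_shape(Reduce(`+`, ms) / 5)
  expect_equal(fit$node_landmarks[[1]], gm, tolerance = 1e-9)
})

test_that("ancestral scores re-project exactly from back-rotated landmarks", {
  ms <- make_means(n = 6)
  tr <- tiny_tree("((t1:1,t2:1):1,((t3:1,t4:1):0.5,(t5:1.2,t6:0.8):0.3):0.7);")
  fit <- vlca(ms, tr)
  raw <- backrotate_scores(fit$pca, coef(fit))
  sc <- project_shapes(fit$pca, raw)
  expect_equal(unname(sc), unname(coef(fit)), tolerance = 1e-9)
  # unit size after post-normalization
  for (m in fit$node_landmarks)
    expect_lt(abs(sqrt(sum(sweep(m, 2, colMeans(m))^2)) - 1), 1e-9)
})

test_that("vLCA recovers the true root on synthetic data", {
  tm <- small_template()
  errs <- c()
  for (n_ind in c(2, 8)) {
    ds <- simulate_dataset(tree = "h1", template = tm, rate = 0.004,
                           within_sd = 1, individuals_per_taxon = n_ind,
                           seed = 75)
    g <- gpa(ds$individuals)
    fit <- vlca(population_mean_shapes(g), ds$tree)
    root_est <- fit$node_landmarks[[1]]
    root_true <- unit_shape(ds$base_shape)
    rmse <- ordinary_procrustes(root_true, root_est)$distance /
      sqrt(tm$scheme$n_landmarks)
    tips <- lapply(ds$true_tip_shapes, unit_shape)
    gm <- unit_shape(Reduce(`+`, tips) / length(tips))
    disp <- sqrt(mean(vapply(tips, function(t)
      ordinary_procrustes(gm, t)$distance^2, 1))) / sqrt(tm$scheme$n_landmarks)
    expect_lt(rmse, disp)
    errs <- c(errs, rmse)
  }
  expect_lt(errs[2], errs[1] * 1.5)   # more individuals does not hurt
})

test_that("tip/taxon mismatches are reported by name", {
  ms <- make_means(n = 5)
  names(ms)[5] <- "zz"
  expect_error(vlca(ms, star_tree(5)), "zz")
})

test_that("phylomorphospace places tips exactly and bounds nodes by ellipses", {
  ms <- make_means(n = 6)
  tr <- tiny_tree("((t1:1,t2:1):1,((t3:1,t4:1):0.5,(t5:1.2,t6:0.8):0.3):0.7);")
  fit <- vlca(ms, tr)
  pm <- phylomorphospace(fit, pcs = 1:2)
  tippts <- pm$points[pm$points$type == "tip", ]
  expect_equal(as.matrix(tippts[, c("PC1", "PC2")]),
               fit$pca$scores[tippts$label, 1:2], ignore_attr = TRUE)
  expect_equal(nrow(pm$edges), nrow(tr$phy$edge))
  # root ellipse has positive semi-axes (contains the root point)
  expect_true(all(pm$ellipses[1, -1] > 0))
  expect_error(phylomorphospace(fit, pcs = 99), "beyond")
  # plotting runs headless
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("warp_reference is exact for identity and affine targets", {
  tm <- small_template()
  mesh <- ellipsoid_mesh(n_lat = 8, n_lon = 12)
  lm <- tm$base_shape
  w1 <- warp_reference(mesh, lm, lm)
  expect_equal(w1$vertices, mesh$vertices, tolerance = 1e-9)
  w2 <- warp_reference(mesh, lm, lm * 1.5)
  expect_equal(w2$vertices, mesh$vertices * 1.5, tolerance = 1e-8)
  expect_error(warp_reference(mesh, lm, lm[-1, ]), "mismatch")
})
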