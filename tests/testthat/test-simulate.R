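test_that("the default template reproduces the cranial proportions", {
  tm <- make_template()
  expect_equal(tm$scheme$n_landmarks, 780)
  expect_equal(sum(tm$scheme$roles == "fixed"), 56)
  expect_equal(sum(tm$scheme$roles == "curve"), 116)
  expect_equal(sum(tm$scheme$roles == "surface"), 608)
  pr <- tm$scheme$symmetry_pairs
  expect_equal(tm$base_shape[pr[, 1], ],
               tm$base_shape[pr[, 2], ] %*% diag(c(-1, 1, 1)),
               tolerance = 1e-12)
  expect_true(all(abs(tm$base_shape[tm$scheme$midline, 1]) < 1e-12))
  tm2 <- make_template()
  expect_identical(tm, tm2)
  expect_false(identical(make_template(seed = 9)$base_shape, tm$base_shape))
})

test_that("BM simulation matches its marginal and shared variances", {
  tr <- tiny_tree("((A:1,B:1):1,C:2);")
  base <- matrix(0, 1, 3)
  expect_equal(simulate_bm_shapes(tr, base, rate = 0, seed = 1)$tip_shapes$A,
               base)
  n_rep <- 1000
  a1 <- b1 <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    s <- simulate_bm_shapes(tr, base, rate = 2, seed = i)
    a1[i] <- s$tip_shapes$A[1, 1]
    b1[i] <- s$tip_shapes$B[1, 1]
  }
  expect_equal(stats::var(a1), 2 * 2, tolerance = 0.1 * 4)  # rate x depth
  expect_equal(stats::cov(a1, b1), 2 * 1, tolerance = 0.1 * 4) # rate x shared
  expect_identical(simulate_bm_shapes(tr, base, rate = 2, seed = 5),
                   simulate_bm_shapes(tr, base, rate = 2, seed = 5))
})

test_that("population sampling concentrates at the CLT rate", {
  tm <- small_template()
  mean_shape <- tm$base_shape
  expect_equal(sample_population(mean_shape, 3, 0, seed = 1)[[2]]$coords,
               mean_shape)
  rmse_at <- function(n) {
    inds <- sample_population(mean_shape, n, within_sd = 2, seed = 11)
    m <- Reduce(`+`, lapply(inds, `[[`, "coords")) / n
    sqrt(mean((m - mean_shape)^2))
  }
  r10 <- rmse_at(10); r100 <- rmse_at(100); r1000 <- rmse_at(1000)
  expect_gt(r10, r100)
  expect_gt(r100, r1000)
  expect_equal(r10 / r1000, 10, tolerance = 5)  # ~ sqrt(1000/10)
})

test_that("fossil masks keep the analysis subset and are reproducible", {
  tm <- make_template()
  cfg <- landmark_config(tm$base_shape, "f")
  masked <- apply_fossil_mask(cfg, "A", tm$scheme)
  expect_equal(sum(!masked$missing), 255)
  m1 <- apply_fossil_mask(cfg, "D", tm$scheme, seed = 3, unilateral_frac = .2)
  m2 <- apply_fossil_mask(cfg, "D", tm$scheme, seed = 3, unilateral_frac = .2)
  expect_identical(m1$missing, m2$missing)
  m3 <- apply_fossil_mask(cfg, "D", tm$scheme, seed = 4, unilateral_frac = .2)
  expect_false(identical(m3$missing, m1$missing))
})

test_that("a unilateral mask on a symmetric shape is exactly recoverable", {
  tm <- small_template()
  cfg <- landmark_config(tm$base_shape, "f")
  pr <- tm$scheme$symmetry_pairs
  keep <- setdiff(seq_len(tm$scheme$n_landmarks), pr[1:5, 2])
  masked <- apply_fossil_mask(cfg, "custom", tm$scheme, keep_indices = keep)
  imp <- impute_missing(masked, tm$base_shape, tm$scheme)
  expect_equal(imp$coords, tm$base_shape, tolerance = 1e-8)
  expect_true(all(imp$provenance[pr[1:5, 2]] == "mirror"))
})

test_that("datasets regenerate bit-identically from their seed", {
  tm <- small_template()
  d1 <- simulate_dataset(tree = "h1b", template = tm, individuals_per_taxon = 2,
                         seed = 21)
  d2 <- simulate_dataset(tree = "h1b", template = tm, individuals_per_taxon = 2,
                         seed = 21)
  expect_identical(d1$individuals, d2$individuals)
  expect_identical(d1$true_node_shapes, d2$true_node_shapes)
  # root truth equals the base shape
  root_id <- as.character(length(d1$tree$phy$tip.label) + 1)
  expect_identical(d1$true_node_shapes[[root_id]], tm$base_shape)
  # fossil (non-contemporaneous) tips get exactly one individual
  grp <- vapply(d1$individuals, `[[`, "", "group")
  n_per <- table(grp)
  fossil_tips <- names(d1$tree$tip_ages[d1$tree$tip_ages > 1e-8])
  expect_true(all(n_per[fossil_tips] == 1))
  expect_true(all(n_per[setdiff(names(n_per), fossil_tips)] == 2))
})

test_that("dataset files round-trip through the standard formats", {
  tm <- small_template()
  ds <- simulate_dataset(tree = "h1b", template = tm, individuals_per_taxon = 1,
                         fossil_masks = c(fossil_syn_1 = "A"), seed = 22)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  tr <- read_newick(file.path(dir, "tree.nwk"))
  expect_equal(phylo_covariance(tr)[tr$phy$tip.label, tr$phy$tip.label],
               phylo_covariance(ds$tree)[tr$phy$tip.label, tr$phy$tip.label],
               tolerance = 1e-9)
  sch <- read_scheme(file.path(dir, "scheme.yaml"))
  expect_equal(sch$n_landmarks, tm$scheme$n_landmarks)
  expect_equal(sch$symmetry_pairs, tm$scheme$symmetry_pairs, ignore_attr = TRUE)
  cf <- read_landmarks_csv(file.path(dir, paste0(ds$individuals[[1]]$specimen_id, ".csv")))
  expect_equal(cf$coords, ds$individuals[[1]]$coords, tolerance = 1e-6,
               ignore_attr = TRUE)
  # masked fossil round-trips its missing mask
  ff <- read_landmarks_csv(file.path(dir, "fossil_syn_1.csv"))
  expect_identical(ff$missing, ds$fossils[[1]]$missing)
})

test_that("TPS-format landmark files round-trip with missing markers", {
  tm <- small_template()
  cfg <- apply_fossil_mask(landmark_config(tm$base_shape, "spec1"), "custom",
                           tm$scheme, keep_indices = 5:40)
  path <- withr::local_tempfile(fileext = ".tps")
  write_tps(list(cfg, landmark_config(tm$base_shape, "spec2")), path)
  back <- read_tps(path)
  expect_equal(length(back), 2)
  expect_identical(back[[1]]$missing, cfg$missing)
  expect_equal(back[[2]]$coords, tm$base_shape, tolerance = 1e-6)
  expect_equal(back[[1]]$specimen_id, "spec1")
})

test_that("end-to-end root recovery improves as the BM rate drops", {
  tm <- small_template()
  rates <- c(0.001, 0.004, 0.016)
  mean_rmse <- vapply(rates, function(r) {
    errs <- vapply(1:20, function(rep) {
      ds <- simulate_dataset(tree = "h1b", template = tm, rate = r,
                             within_sd = 0.5, individuals_per_taxon = 2,
                             seed = 3000 + rep)
      g <- gpa(ds$individuals)
      fit <- vlca(population_mean_shapes(g), ds$tree)
      ordinary_procrustes(unit_shape(ds$base_shape),
                          fit$node_landmarks[[1]])$distance
    }, 1)
    mean(errs)
  }, 1)
  expect_lt(mean_rmse[1], mean_rmse[2])
  expect_lt(mean_rmse[2], mean_rmse[3])
})
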