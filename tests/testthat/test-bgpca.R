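two_group_sample <- function(k = 10, n = 6, sep = 1, seed = 91) {
  set.seed(seed)
  base <- rand_config(k, seed = seed)
  offs <- matrix(rnorm(3 * k, sd = sep), k, 3)
  cfgs <- c(lapply(1:n, function(i)
    landmark_config(base + matrix(rnorm(3 * k, sd = .2), k, 3),
                    paste0("a", i), group = "G1")),
    lapply(1:n, function(i)
      landmark_config(base + offs + matrix(rnorm(3 * k, sd = .2), k, 3),
                      paste0("b", i), group = "G2")))
  cfgs
}

test_that("analysis specs reproduce the preservation counts", {
  tm <- make_template()   # full 780-landmark template
  expect_equal(length(make_analysis_spec("A", tm$scheme)$landmark_indices), 255)
  expect_equal(length(make_analysis_spec("B", tm$scheme)$landmark_indices), 148)
  expect_equal(length(make_analysis_spec("C", tm$scheme)$landmark_indices), 112)
  expect_equal(length(make_analysis_spec("D", tm$scheme)$landmark_indices), 181)
  expect_equal(make_analysis_spec("B", tm$scheme)$excluded_specimens, "Florisbad")
  expect_equal(make_analysis_spec("C", tm$scheme)$excluded_specimens,
               c("Omo II", "LH18"))
  sm <- small_template()
  sp <- make_analysis_spec("A", sm$scheme)
  expect_equal(length(sp$landmark_indices), round(255 / 780 * 40))
  expect_error(make_analysis_spec("E", tm$scheme), "unknown")
})

test_that("two groups give a single axis along the mean difference", {
  bg <- bgpca(two_group_sample())
  expect_equal(length(bg$eigenvalues), 1)
  expect_equal(bg$variance_fractions, 1)
  # group mean scores are symmetric about zero on the single axis
  expect_equal(sum(bg$group_mean_scores), 0, tolerance = 1e-9)
})

test_that("passive specimens project exactly; mean distances are preserved", {
  cfgs <- two_group_sample(n = 5)
  g3 <- lapply(1:4, function(i)
    landmark_config(rand_config(10, seed = 92) +
                      matrix(rnorm(30, sd = .2), 10, 3),
                    paste0("c", i), group = "G3"))
  all_cfg <- c(cfgs, g3)
  X <- do.call(rbind, lapply(all_cfg, function(cf) as.vector(t(cf$coords))))
  grp <- vapply(all_cfg, `[[`, "", "group")
  m1 <- colMeans(X[grp == "G1", ])
  bg <- bgpca(all_cfg, passive = list(ghost = matrix(m1, ncol = 3, byrow = TRUE)))
  # passive equal to a group mean projects onto that mean's score
  expect_equal(unname(bg$passive_scores["ghost", ]),
               unname(bg$group_mean_scores["G1", ]), tolerance = 1e-9)
  # full-space distances between group means equal score-space distances
  means <- bg$group_means
  expect_equal(dist(bg$group_mean_scores), dist(means),
               tolerance = 1e-9, ignore_attr = TRUE)
  # orthonormal axes, reproducible sign convention
  V <- bg$eigenvectors
  expect_equal(V %*% t(V), diag(nrow(V)), tolerance = 1e-9)
  bg2 <- bgpca(all_cfg, passive = list(ghost = matrix(m1, ncol = 3, byrow = TRUE)))
  expect_identical(bg$scores, bg2$scores)
  expect_error(bgpca(all_cfg[grp == "G1"]), "2 groups")
})

test_that("distance tables are symmetric with zero diagonal and name nearest groups", {
  cfgs <- two_group_sample(n = 4)
  pas <- list(p1 = cfgs[[1]]$coords)
  dt <- euclidean_distance_table(bgpca(cfgs, passive = pas))
  expect_equal(dt$matrix, t(dt$matrix))
  expect_true(all(diag(dt$matrix) == 0))
  expect_equal(dt$nearest$specimen, "p1")
  expect_equal(dt$nearest$nearest_group, "G1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_table(dt, path)
  expect_true(file.exists(path))
})

test_that("a planted nearest group is recovered almost always", {
  hits <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    k <- 8
    base <- matrix(rnorm(3 * k), k, 3)
    centers <- lapply(1:3, function(g) base + matrix(rnorm(3 * k, sd = 1), k, 3))
    cfgs <- unlist(lapply(1:3, function(g)
      lapply(1:4, function(i)
        landmark_config(centers[[g]] + matrix(rnorm(3 * k, sd = .3), k, 3),
                        paste0("g", g, "_", i), group = paste0("G", g)))),
      recursive = FALSE)
    probe <- centers[[2]] + matrix(rnorm(3 * k, sd = .3), k, 3)
    dt <- euclidean_distance_table(bgpca(cfgs, passive = list(p = probe)))
    if (dt$nearest$nearest_group == "G2") hits <- hits + 1
  }
  expect_gte(hits, 0.95 * n_rep)
})

test_that("Procrustes distance reports summarise per group", {
  cfgs <- two_group_sample(n = 3)
  g <- gpa(cfgs)
  ref <- list(solo = g$configs[[1]]$coords)
  rep_ <- procrustes_distance_report(g, ref)
  expect_setequal(unique(rep_$summary$group), c("G1", "G2"))
  d11 <- rep_$summary[rep_$summary$group == "G1", ]
  expect_equal(d11$min, 0, tolerance = 1e-12)   # reference is in G1
  expect_true(all(rep_$summary$q1 <= rep_$summary$median))
  expect_true(all(rep_$summary$median <= rep_$summary$q3))
  # reference equal to a group's sole individual gives the {0} distribution
  solo_g <- structure(list(configs = list(landmark_config(g$configs[[1]]$coords,
                                                          "only", group = "S")),
                           consensus = g$consensus, centroid_sizes = 1,
                           n_iterations = 1), class = "aligned_sample")
  r2 <- procrustes_distance_report(solo_g, ref)
  expect_equal(r2$summary$max, 0, tolerance = 1e-12)
})
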