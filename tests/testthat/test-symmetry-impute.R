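sym6 <- function() {
  coords <- rbind(c(1, 0, 0), c(-1, 0, 0),
                  c(0.8, 1, 0.3), c(-0.8, 1, 0.3),
                  c(0, -1, 0.5), c(0, 0.5, -1))
  scheme <- landmark_scheme(6, roles = rep("fixed", 6),
                            symmetry_pairs = rbind(c(2, 1), c(4, 3)),
                            midline = c(5, 6))
  list(coords = coords, scheme = scheme)
}

test_that("a perfectly symmetric configuration passes through unchanged", {
  tm <- small_template()
  x <- tm$base_shape
  b <- sweep(x %*% rand_rotation(41), 2, c(5, 1, 2), `+`)
  sc <- symmetric_component(list(x, b), tm$scheme)
  ua <- unit_shape(x)
  for (cf in sc$configs) {
    r <- svd(crossprod(ua, cf$coords))
    rot <- r$v %*% diag(c(1, 1, sign(det(r$u %*% t(r$v))))) %*% t(r$u)
    expect_equal(ua %*% rot, cf$coords, tolerance = 1e-9)
  }
})

test_that("symmetric components are exactly symmetric and idempotent", {
  tm <- small_template()
  set.seed(42)
  samp <- lapply(1:4, function(i)
    tm$base_shape + matrix(rnorm(3 * tm$scheme$n_landmarks), ncol = 3))
  sc <- symmetric_component(samp, tm$scheme)
  pr <- tm$scheme$symmetry_pairs
  for (cf in sc$configs) {
    expect_equal(cf$coords[pr[, 1], ],
                 cf$coords[pr[, 2], ] %*% diag(c(-1, 1, 1)), tolerance = 1e-9)
    expect_lt(max(abs(cf$coords[tm$scheme$midline, 1])), 1e-9)
  }
  sc2 <- symmetric_component(sc, tm$scheme)
  for (i in seq_along(sc$configs))
    expect_equal(sc2$configs[[i]]$coords, sc$configs[[i]]$coords,
                 tolerance = 1e-6)
})

test_that("a one-sided perturbation moves both sides by half, per hand computation", {
  f <- sym6()
  eps <- 1e-3
  pert <- f$coords; pert[3, 2] <- pert[3, 2] + eps
  sc <- symmetric_component(list(f$coords, pert), f$scheme)
  # hand-computed expectation: both members of the pair move by eps/2 along y
  expected <- f$coords
  expected[3, 2] <- expected[3, 2] + eps / 2
  expected[4, 2] <- expected[4, 2] + eps / 2
  expect_lt(ordinary_procrustes(sc$configs[[2]]$coords, expected)$distance,
            10 * eps^2)
  expect_lt(ordinary_procrustes(sc$configs[[1]]$coords, f$coords)$distance,
            1e-10)
})

test_that("mirror imputation reconstructs a deleted side exactly", {
  tm <- small_template()
  x <- tm$base_shape
  sch <- tm$scheme
  miss <- rep(FALSE, nrow(x)); miss[sch$symmetry_pairs[, 2]] <- TRUE
  cfg <- x; cfg[miss, ] <- NA
  imp <- impute_missing(landmark_config(cfg, "fossil"), x, sch)
  expect_equal(imp$coords, x, tolerance = 1e-8)
  expect_true(all(imp$provenance[sch$symmetry_pairs[, 2]] == "mirror"))
  expect_true(all(imp$provenance[!miss] == "observed"))
})

test_that("TPS imputation of a template-identical specimen is exact", {
  tm <- small_template()
  x <- tm$base_shape
  set.seed(43)
  miss <- rep(FALSE, nrow(x))
  miss[sample(nrow(x), round(0.1 * nrow(x)))] <- TRUE
  miss[tm$scheme$midline[1]] <- TRUE   # include a midline landmark
  cfg <- x; cfg[miss, ] <- NA
  imp <- impute_missing(landmark_config(cfg, "g"), x, tm$scheme)
  expect_equal(imp$coords, x, tolerance = 1e-8)
})

test_that("fossil-mask imputation recovers the population mean at the noise scale", {
  # With landmark-independent within-population noise, no imputation can
  # predict a specimen's own noise at unobserved landmarks, so the relevant
  # target is the population mean shape: imputed positions should deviate
  # from it on the order of the within-population standard deviation, far
  # below any between-population signal.
  tm <- make_template()
  within_sd <- 1
  rmse <- vapply(1:5, function(i) {
    fossil <- sample_population(tm$base_shape, 1, within_sd, seed = 100 + i)[[1]]
    masked <- apply_fossil_mask(fossil, "D", tm$scheme, seed = i,
                                unilateral_frac = 0.3)
    imp <- impute_missing(masked, tm$base_shape, tm$scheme)
    sqrt(mean((imp$coords[masked$missing, ] -
               tm$base_shape[masked$missing, ])^2))
  }, 1)
  expect_lt(mean(rmse), 1.5 * within_sd)
})

test_that("imputation errors name the unresolvable cases", {
  tm <- small_template()
  x <- tm$base_shape
  cfg <- x; cfg[5:nrow(x), ] <- NA
  expect_error(impute_missing(landmark_config(cfg, "f"), x, tm$scheme),
               "cannot impute|fewer than")
})
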