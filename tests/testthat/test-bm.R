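test_that("root estimates reduce to closed forms on simple trees", {
  st <- star_tree(3)
  y <- matrix(c(1, 2, 3), 3, 1, dimnames = list(st$phy$tip.label, NULL))
  a <- bm_ancestral_states(st, y)
  expect_equal(unname(a$estimates[1, 1]), 2)
  tt <- tiny_tree("(A:1,B:3);")
  a2 <- bm_ancestral_states(tt, matrix(c(0, 4), 2, 1,
                                       dimnames = list(c("A", "B"), NULL)))
  expect_equal(unname(a2$estimates[1, 1]), 1)   # (0/1 + 4/3)/(1 + 1/3)
  # two-tip root lies on the segment between tips with positive weights
  expect_gte(a2$estimates[1, 1], 0)
  expect_lte(a2$estimates[1, 1], 4)
})

test_that("node estimates match brute-force maximization of the BM likelihood", {
  tr <- tiny_tree("((A:1,B:2):1.5,(C:0.8,(D:1.2,E:0.7):0.9):1.1);")
  y <- c(A = 1.0, B = -0.5, C = 2.0, D = 0.3, E = 1.4)
  est <- bm_ancestral_states(tr, matrix(y, 5, 1, dimnames = list(names(y), NULL)))
  phy <- tr$phy
  nll <- function(states) {
    allv <- c(y[phy$tip.label], states)
    -sum(stats::dnorm(allv[phy$edge[, 2]], allv[phy$edge[, 1]],
                      sqrt(est$sigma2[1] * phy$edge.length), log = TRUE))
  }
  o <- stats::optim(rep(mean(y), phy$Nnode), nll, method = "BFGS",
                    control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(est$estimates[, 1]), o$par, tolerance = 1e-4)
})

test_that("estimates agree with an independent implementation (phytools)", {
  skip_if_not_installed("phytools")
  tr <- tiny_tree("((A:1,B:2):1.5,(C:0.8,(D:1.2,E:0.7):0.9):1.1);")
  y <- c(A = 1.0, B = -0.5, C = 2.0, D = 0.3, E = 1.4)
  est <- bm_ancestral_states(tr, matrix(y, 5, 1, dimnames = list(names(y), NULL)))
  fa <- phytools::fastAnc(tr$phy, y)
  expect_equal(unname(est$estimates[names(fa), 1]), unname(c(fa)),
               tolerance = 1e-8)
})

test_that("branch rescaling leaves estimates fixed and scales variances", {
  tr <- build_hypothesis("h1b")
  set.seed(51)
  y <- matrix(rnorm(25 * 2), 25, 2, dimnames = list(tr$phy$tip.label, NULL))
  a1 <- bm_ancestral_states(tr, y)
  phy2 <- tr$phy; phy2$edge.length <- phy2$edge.length * 7
  a2 <- bm_ancestral_states(chronogram(phy2), y)
  expect_equal(a1$estimates, a2$estimates, tolerance = 1e-9)
  expect_equal(a1$variances, a2$variances, tolerance = 1e-9)  # sigma2 absorbs it
  expect_equal(a1$sigma2 / 7, a2$sigma2, tolerance = 1e-9)
})

test_that("root estimates stay inside the convex hull of tip values", {
  for (s in 1:5) {
    tr <- build_hypothesis("h1")
    set.seed(s)
    y <- matrix(rnorm(29 * 3), 29, 3, dimnames = list(tr$phy$tip.label, NULL))
    a <- bm_ancestral_states(tr, y)
    for (j in 1:3) {
      expect_gte(a$estimates[1, j], min(y[, j]))
      expect_lte(a$estimates[1, j], max(y[, j]))
    }
  }
})

test_that("REML option divides the rate quadratic form by N - 1", {
  tt <- tiny_tree("((A:1,B:1):1,C:2);")
  y <- matrix(c(0, 1, 5), 3, 1, dimnames = list(c("A", "B", "C"), NULL))
  ml <- bm_ancestral_states(tt, y)
  reml <- bm_ancestral_states(tt, y, reml = TRUE)
  expect_equal(ml$sigma2 * 3 / 2, reml$sigma2, tolerance = 1e-12)
  expect_equal(ml$estimates, reml$estimates)
})

test_that("hypothesis choice inside the modern clade barely moves outgroup nodes", {
  h1 <- build_hypothesis("h1"); h2 <- build_hypothesis("h2")
  set.seed(52)
  y <- matrix(rnorm(29 * 2), 29, 2, dimnames = list(h1$phy$tip.label, NULL))
  a1 <- bm_ancestral_states(h1, y); a2 <- bm_ancestral_states(h2, y)
  key <- function(tr, n) paste(sort(ape::extract.clade(tr$phy, as.integer(n))$tip.label),
                               collapse = "|")
  k1 <- vapply(rownames(a1$estimates), function(n) key(h1, n), "")
  k2 <- vapply(rownames(a2$estimates), function(n) key(h2, n), "")
  common <- intersect(k1, k2)
  d <- vapply(common, function(l)
    max(abs(a1$estimates[names(k1)[k1 == l], ] -
            a2$estimates[names(k2)[k2 == l], ])), 1)
  outg <- common[grepl("H_habilis|Neandertal", common) & !grepl("San", common)]
  affected <- setdiff(common, outg)
  expect_lt(max(d[outg]), 0.01 * max(d[affected]))
})

test_that("degenerate inputs raise errors", {
  st <- star_tree(3)
  expect_error(bm_ancestral_states(st, matrix(numeric(0), 3, 0)), "p >= 1")
  y <- matrix(1:3, 3, 1, dimnames = list(c("A", "B", "X"), NULL))
  expect_error(bm_ancestral_states(st, y), "do not match")
})
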