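# Shared fixtures built in code (no stored data).

# Reduced skull-like template: 10 fixed, 2 curves x 5, 20 surface = 40 landmarks
small_template <- function(seed = 2)
  make_template(k_fixed = 10, n_curves = 2, curve_len = 5, n_surface = 20,
                seed = seed)

# Deterministic proper random rotation
rand_rotation <- function(seed) {
  set.seed(seed)
  r <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# Generic non-degenerate configuration
rand_config <- function(k = 10, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(3 * k, sd = sd), k, 3)
}

tiny_tree <- function(text) chronogram(ape::read.tree(text = text))

star_tree <- function(n = 4, bl = 1) {
  labs <- paste0("t", seq_len(n))
  tiny_tree(paste0("(", paste0(labs, ":", bl, collapse = ","), ");"))
}

# unit-scaled centered copy
unit_shape <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  x / sqrt(sum(x^2))
}
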