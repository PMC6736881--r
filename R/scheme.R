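#' Landmark scheme: roles, topology and bilateral symmetry of a template
#'
#' A `landmark_scheme` declares, for a template of `n_landmarks` points, which
#' landmarks are fixed anatomical points, which are curve semilandmarks
#' (ordered chains that may slide along their tangent) and which are surface
#' semilandmarks (sliding within a local tangent plane estimated from declared
#' neighbours), together with the bilateral pairing used for the symmetric
#' shape component and for mirror imputation of missing landmarks.
#'
#' @param n_landmarks total number of landmarks in the template.
#' @param roles character vector of length `n_landmarks`, each element one of
#'   `"fixed"`, `"curve"`, `"surface"`.
#' @param curves list of integer vectors; each an ordered chain of landmark
#'   indices (length >= 3) along an anatomical curve. Chain interiors must
#'   have role `"curve"`.
#' @param surfaces named list with elements `indices` (integer vector of
#'   surface-semilandmark indices) and `neighbors` (list, one integer vector
#'   of >= 3 neighbour indices per surface landmark, used for tangent-plane
#'   estimation).
#' @param symmetry_pairs two-column integer matrix of (left, right) index
#'   pairs.
#' @param midline integer vector of unpaired landmarks lying on the
#'   mid-sagittal plane.
#' @return an object of class `landmark_scheme`.
#' @export
landmark_scheme <- function(n_landmarks, roles, curves = list(),
                            surfaces = list(indices = integer(0), neighbors = list()),
                            symmetry_pairs = matrix(integer(0), ncol = 2),
                            midline = integer(0)) {
  n_landmarks <- as.integer(n_landmarks)
  stopifnot(n_landmarks >= 1, length(roles) == n_landmarks)
  if (!all(roles %in% c("fixed", "curve", "surface")))
    stop("roles must be 'fixed', 'curve' or 'surface'")
  symmetry_pairs <- matrix(as.integer(symmetry_pairs), ncol = 2)
  midline <- as.integer(midline)
  all_idx <- c(as.vector(symmetry_pairs), midline)
  if (length(all_idx) != n_landmarks || !setequal(all_idx, seq_len(n_landmarks)) ||
      anyDuplicated(all_idx))
    stop("symmetry_pairs and midline must cover every landmark exactly once")
  curve_idx <- unlist(lapply(curves, function(ch) ch[-c(1, length(ch))]))
  if (anyDuplicated(unlist(curves)))
    stop("no landmark may belong to two curves")
  for (ch in curves) {
    if (length(ch) < 3) stop("each curve chain needs >= 3 indices")
    if (any(ch < 1 | ch > n_landmarks)) stop("curve index out of range")
  }
  if (length(surfaces$indices)) {
    if (length(surfaces$neighbors) != length(surfaces$indices))
      stop("one neighbor list per surface landmark required")
    if (any(vapply(surfaces$neighbors, length, 1L) < 3))
      stop("each surface landmark needs >= 3 neighbors")
  }
  if (!all(roles[curve_idx] == "curve"))
    stop("curve-chain interior landmarks must have role 'curve'")
  if (length(surfaces$indices) && !all(roles[surfaces$indices] == "surface"))
    stop("surface indices must have role 'surface'")
  structure(list(n_landmarks = n_landmarks, roles = roles, curves = curves,
                 surfaces = surfaces, symmetry_pairs = symmetry_pairs,
                 midline = midline),
            class = "landmark_scheme")
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme:", x$n_landmarks, "landmarks\n")
  cat("  fixed:", sum(x$roles == "fixed"),
      " curve:", sum(x$roles == "curve"),
      "(", length(x$curves), "chains )",
      " surface:", sum(x$roles == "surface"), "\n")
  cat("  bilateral pairs:", nrow(x$symmetry_pairs),
      " midline:", length(x$midline), "\n")
  invisible(x)
}

#' Read or write a landmark scheme as a YAML file
#'
#' The file has top-level keys `n_landmarks`, `roles`, `curves` (list of index
#' vectors), `surfaces` (`indices`, `neighbors`), `symmetry_pairs` (list of
#' two-element vectors) and `midline`. Indices are 1-based.
#'
#' @param path file path.
#' @return `read_scheme` returns a [landmark_scheme].
#' @export
read_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  landmark_scheme(
    n_landmarks = y$n_landmarks,
    roles = unlist(y$roles),
    curves = lapply(y$curves, as.integer),
    surfaces = list(indices = as.integer(unlist(y$surfaces$indices)),
                    neighbors = lapply(y$surfaces$neighbors, as.integer)),
    symmetry_pairs = do.call(rbind, lapply(y$symmetry_pairs, as.integer)),
    midline = as.integer(unlist(y$midline)))
}

#' @rdname read_scheme
#' @param scheme a [landmark_scheme].
#' @export
write_scheme <- function(scheme, path) {
  y <- list(n_landmarks = scheme$n_landmarks,
            roles = scheme$roles,
            curves = lapply(scheme$curves, as.integer),
            surfaces = list(indices = as.integer(scheme$surfaces$indices),
                            neighbors = lapply(scheme$surfaces$neighbors, as.integer)),
            symmetry_pairs = lapply(seq_len(nrow(scheme$symmetry_pairs)),
                                    function(i) as.integer(scheme$symmetry_pairs[i, ])),
            midline = as.integer(scheme$midline))
  yaml::write_yaml(y, path)
  invisible(path)
}
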