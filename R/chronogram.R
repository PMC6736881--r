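#' Dated phylogeny (chronogram)
#'
#' Wraps an `ape::phylo` tree whose branch lengths are in thousands of years
#' (ka). The tree must be rooted, fully resolved (binary) and every edge must
#' carry a positive length. Tips need not be contemporaneous: a tip's age
#' before present is the root age (the longest root-to-tip path) minus its
#' own root-to-tip path, so fossil taxa sit above the present.
#'
#' @param phy an `ape::phylo` object.
#' @param require_binary reject polytomies? Default `FALSE` here (star
#'   trees are legitimate for the closed-form Brownian results); Newick
#'   input via [read_newick()] enforces fully resolved trees.
#' @return object of class `chronogram` with elements `phy`, `root_age`,
#'   `tip_ages` (named, ka) and `node_ages` (internal nodes, named by ape
#'   node number).
#' @export
chronogram <- function(phy, require_binary = FALSE) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape 'phylo' tree")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(is.na(phy$edge.length)) || any(phy$edge.length <= 0))
    stop("all branch lengths must be positive")
  if (require_binary && !ape::is.rooted(phy)) stop("tree must be rooted")
  if (require_binary && !ape::is.binary(phy))
    stop("tree must be fully resolved (no polytomies)")
  n <- length(phy$tip.label)
  depths <- ape::node.depth.edgelength(phy)
  root_age <- max(depths[seq_len(n)])
  tip_ages <- root_age - depths[seq_len(n)]
  names(tip_ages) <- phy$tip.label
  node_ages <- root_age - depths[(n + 1):(n + phy$Nnode)]
  names(node_ages) <- as.character((n + 1):(n + phy$Nnode))
  structure(list(phy = phy, root_age = root_age, tip_ages = tip_ages,
                 node_ages = node_ages),
            class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat("Chronogram:", length(x$phy$tip.label), "tips, root age",
      format(x$root_age), "ka\n")
  nz <- x$tip_ages[x$tip_ages > 1e-8]
  if (length(nz))
    cat("  non-contemporaneous tips:", paste(names(nz), collapse = ", "), "\n")
  invisible(x)
}

as_chronogram <- function(x) {
  if (inherits(x, "chronogram")) x
  else if (is.character(x) && length(x) == 1 && x %in% c("h1", "h2", "h1b", "h2b"))
    build_hypothesis(x)
  else chronogram(x)
}

#' Read or write a chronogram in Newick format
#'
#' Branch lengths are interpreted as ka. Reading rejects polytomies and
#' unlengthed edges; a write/read round trip preserves topology and branch
#' lengths to better than 1e-9.
#'
#' @param path file path.
#' @return `read_newick` returns a [chronogram].
#' @export
read_newick <- function(path) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file ", path)
  chronogram(phy, require_binary = TRUE)
}

#' @rdname read_newick
#' @param tree a [chronogram].
#' @param annotate_ages if `TRUE`, write internal node labels of the form
#'   `age=<ka>` so the chronology is visible in the serialized tree.
#' @export
write_newick <- function(tree, path, annotate_ages = FALSE) {
  tree <- as_chronogram(tree)
  phy <- tree$phy
  if (annotate_ages)
    phy$node.label <- sprintf("age=%.6g", unname(tree$node_ages))
  ape::write.tree(phy, file = path, digits = 12)
  invisible(path)
}

#' Phylogenetic covariance matrix under Brownian motion
#'
#' The N x N matrix whose entry (i, j) is the path length (ka) from the root
#' to the most recent common ancestor of tips i and j; the diagonal holds
#' each tip's root-to-tip path length. Under Brownian motion tip values are
#' jointly Gaussian with covariance proportional to this matrix.
#'
#' @param tree a [chronogram] or preset name.
#' @return symmetric positive definite matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  tree <- as_chronogram(tree)
  ape::vcv.phylo(tree$phy)
}

# ---- hypothesis presets ------------------------------------------------

# Nested (age, children | label) description -> Newick string.
node_to_newick <- function(node, parent_age) {
  if (!is.null(node$label)) {
    sprintf("%s:%.10g", node$label, parent_age - node$age)
  } else {
    inner <- paste(vapply(node$children, node_to_newick, "", parent_age = node$age),
                   collapse = ",")
    if (is.na(parent_age)) sprintf("(%s);", inner)
    else sprintf("(%s):%.10g", inner, parent_age - node$age)
  }
}

tipnode <- function(label, age = 0) list(label = label, age = age)
clade <- function(age, ...) list(age = age, children = list(...))

# Dated tree hypotheses for the genus Homo. Shared backbone: an early-Homo
# outgroup, a Neandertal clade rooted at 300 ka, and a modern human clade
# rooted at 305 ka whose early H. sapiens tip (~100 ka) is sister to 21
# extant populations. The modern-Neandertal split is at 600 ka. The two
# hypotheses differ in the out-of-Africa structure: in h1 the Oceanian
# branch splits from the African clade at 90 ka and the remaining
# non-Africans at 75 ka; in h2 all non-Africans (Oceanians included) split
# from the Africans at 75 ka. Fossil tip ages are chronology-range midpoints.
hypothesis_spec <- function(name) {
  oceania <- clade(40, tipnode("Papua"), tipnode("Australia"))
  america <- clade(25, tipnode("NorthAmerica"),
                   clade(10, tipnode("InuitGreenland"), tipnode("InuitAlaska")))
  east_asia <- clade(20, tipnode("EastAsiaJapan"), tipnode("EastAsiaChina"))
  europe <- clade(35, tipnode("SouthEurope"), tipnode("NorthEurope"))
  eurasia <- if (name %in% c("h1", "h1b")) {
    clade(60, europe,
          clade(50, tipnode("SouthAsia"),
                clade(45, tipnode("SouthEastAsia"),
                      clade(35, east_asia, america))))
  } else {
    clade(60, europe,
          clade(50, tipnode("SouthAsia"),
                clade(47, oceania,
                      clade(45, tipnode("SouthEastAsia"),
                            clade(35, east_asia, america)))))
  }
  ooa <- clade(75, tipnode("NorthAfrica"), eurasia)
  inner_africa <- if (name %in% c("h1", "h1b")) {
    clade(90, oceania, ooa)          # early out-of-Africa kept in Oceania
  } else ooa
  core <- clade(120, clade(70, tipnode("EastAfrica"), tipnode("Nilotic")),
                inner_africa)
  a4 <- clade(150, tipnode("SouthAfrica"), core)
  a2 <- clade(180, clade(100, tipnode("WestAfrica"), tipnode("CentralAfrica")), a4)
  extant <- if (name %in% c("h1", "h2")) {
    clade(280, clade(110, tipnode("San"), tipnode("Khoikhoi")),
          clade(220, clade(120, tipnode("Bayaka"), tipnode("Mbuti")), a2))
  } else a2                          # b variants drop Khoisans and Pygmies
  modern <- clade(305, tipnode("Early_H_sapiens", 100), extant)
  neand <- clade(300, tipnode("Neandertal_Early", 195),
                 clade(150, tipnode("Neandertal_NearEast", 50),
                       clade(100, tipnode("Neandertal_SEurope", 53),
                             tipnode("Neandertal_WEurope", 55))))
  clade(2000,
        clade(1900, tipnode("H_habilis", 1800),
              clade(1820, tipnode("H_ergaster", 1550),
                    tipnode("H_georgicus", 1770))),
        clade(600, neand, modern))
}

#' Built-in dated phylogeny hypotheses for the genus Homo
#'
#' Four preset chronograms: `h1` and `h2` (29 tips: a 3-tip early-Homo
#' outgroup, 4 Neandertal groups, early H. sapiens and 21 extant
#' populations) and the reduced variants `h1b`/`h2b` (25 tips) that drop the
#' San, Khoikhoi, Bayaka and Mbuti populations. The Neandertal-modern human
#' split sits at 600 ka, the Neandertal clade root at 300 ka and the modern
#' clade root at 305 ka; in `h1` the Australian/Papuan branch splits from
#' the African clade at 90 ka, while in `h2` all non-Africans split from the
#' Africans at 75 ka. Branch lengths in ka; fossil tips keep their
#' chronological ages.
#'
#' @param name one of `"h1"`, `"h2"`, `"h1b"`, `"h2b"`.
#' @return a [chronogram].
#' @export
build_hypothesis <- function(name) {
  if (!name %in% c("h1", "h2", "h1b", "h2b"))
    stop("unknown hypothesis '", name, "'; presets are h1, h2, h1b, h2b")
  nwk <- node_to_newick(hypothesis_spec(name), NA)
  chronogram(ape::read.tree(text = nwk))
}
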