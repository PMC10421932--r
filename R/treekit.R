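# Desk-scale tree construction and comparison: distance matrices,
# neighbor-joining, Robinson-Foulds, and monophyly testing.  Full Bayesian /
# maximum-likelihood inference is out of scope here; externally computed
# trees enter via Newick import and are compared quantitatively.

#' Pairwise distance matrix from alignments or feature vectors
#'
#' Modes: \code{p_distance_on_alignment} (mismatches over non-gap comparable
#' columns, per pair, on an aligned set of equal-length sequences);
#' \code{feature_euclidean}; \code{feature_cosine} (1 - cosine similarity).
#'
#' @param x named character vector of aligned sequences, or a numeric
#'   matrix with rownames (feature modes)
#' @param mode one of \code{"p_distance_on_alignment"},
#'   \code{"feature_euclidean"}, \code{"feature_cosine"}
#' @return symmetric numeric matrix with zero diagonal, labelled
#' @export
distance_matrix <- function(x, mode = c("p_distance_on_alignment",
                                        "feature_euclidean",
                                        "feature_cosine")) {
  mode <- match.arg(mode)
  if (mode == "p_distance_on_alignment") {
    stopifnot(is.character(x), !is.null(names(x)))
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      stop("ragged alignment: lengths ", paste(unique(lens), collapse = ", "))
    }
    chars <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    n <- length(x)
    D <- matrix(0, n, n, dimnames = list(names(x), names(x)))
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        ok <- chars[i, ] != "-" & chars[j, ] != "-"
        ncomp <- sum(ok)
        D[i, j] <- D[j, i] <-
          if (ncomp == 0L) 0 else sum(chars[i, ok] != chars[j, ok]) / ncomp
      }
    }
    return(D)
  }
  x <- as.matrix(x)
  stopifnot(!is.null(rownames(x)), all(is.finite(x)))
  if (mode == "feature_euclidean") {
    return(as.matrix(stats::dist(x)))
  }
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("zero vector has no cosine distance")
  S <- (x / nrm) %*% t(x / nrm)
  D <- 1 - S
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining (via \pkg{ape}); negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to 0
#' with a warning.
#'
#' @param D symmetric labelled distance matrix (n >= 3)
#' @return unrooted \code{ape::phylo} tree
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa, got ", n)
  if (is.null(rownames(D))) stop("distance matrix must be labelled")
  stopifnot(isSymmetric(unname(D)), all(diag(D) == 0), all(D >= 0),
            all(is.finite(D)))
  tree <- ape::nj(D)
  if (any(tree$edge.length < 0)) {
    warning("clamped ", sum(tree$edge.length < 0),
            " negative branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' Count of non-trivial bipartitions present in exactly one of the two
#' unrooted trees.
#'
#' @param t1,t2 \code{ape::phylo} trees over the same leaf set
#' @return integer
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  d1 <- setdiff(t1$tip.label, t2$tip.label)
  d2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(d1) || length(d2)) {
    stop("leaf sets differ; only in tree 1: ",
         paste(d1, collapse = ","), "; only in tree 2: ",
         paste(d2, collapse = ","))
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

#' Is a leaf subset monophyletic (unrooted sense)?
#'
#' TRUE iff removing some edge separates exactly the subset from the rest.
#' With an arbitrary rooting this holds iff the subset or its complement
#' forms a rooted clade, which is how it is tested.
#'
#' @param tree \code{ape::phylo}
#' @param leaf_subset character vector of tip labels
#' @return logical
#' @export
is_monophyletic <- function(tree, leaf_subset) {
  stopifnot(inherits(tree, "phylo"), length(leaf_subset) > 0)
  unknown <- setdiff(leaf_subset, tree$tip.label)
  if (length(unknown)) stop("unknown leaf: ", paste(unknown, collapse = ","))
  leaves <- tree$tip.label
  if (length(leaf_subset) %in% c(1L, length(leaves))) return(TRUE)
  rest <- setdiff(leaves, leaf_subset)
  ape::is.monophyletic(tree, leaf_subset) || ape::is.monophyletic(tree, rest)
}

#' Random additive distance matrix with its generating tree
#'
#' Draws a random unrooted topology with positive branch lengths and
#' returns the implied additive (path-length) distance matrix; used to
#' exercise topology recovery.
#'
#' @param n_leaves number of leaves
#' @param seed integer seed
#' @return list(tree, D)
#' @export
random_additive_matrix <- function(n_leaves, seed) {
  set.seed(as.integer(seed))
  tree <- ape::rtree(n_leaves, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.1, 2))
  tree$tip.label <- sprintf("t%02d", seq_len(n_leaves))
  D <- ape::cophenetic.phylo(tree)
  lab <- sort(rownames(D))
  list(tree = tree, D = D[lab, lab])
}
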