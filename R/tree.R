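#' Parse a Newick string into a rooted phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree must be
#' rooted, carry an explicit branch length on every edge, and have unique,
#' non-empty tip labels. Internal node labels are permitted and ignored.
#'
#' @param text A single Newick string (terminated by `;`), or the path of a
#'   file containing one if `file = TRUE`.
#' @param file Logical; treat `text` as a file path.
#' @return An object of class `"phylo"` (see [ape::read.tree()]).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text, file = FALSE) {
  if (file) {
    tr <- tryCatch(suppressWarnings(ape::read.tree(file = text)),
                   error = function(e) NULL)
  } else {
    stopifnot(is.character(text), length(text) == 1L)
    tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                   error = function(e) NULL)
  }
  if (is.null(tr)) stop("malformed Newick input")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree")
  validate_tree(tr)
  tr
}

#' Write a phylogeny as Newick
#'
#' @param tree A `"phylo"` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  validate_tree(tree)
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' Validate the tree invariants assumed throughout the package
#'
#' Checks that `tree` is a rooted `"phylo"` with explicit nonnegative branch
#' lengths (at least one positive) and unique non-empty tip labels.
#' Zero-length terminal branches are legal but warned about: they can make
#' the phylogenetic covariance singular.
#'
#' @param tree A `"phylo"` object.
#' @return `tree`, invisibly.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("every edge must carry an explicit branch length")
  if (anyNA(tree$edge.length)) stop("missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (all(tree$edge.length == 0)) stop("all branch lengths are zero")
  lab <- tree$tip.label
  if (any(!nzchar(lab))) stop("empty tip labels")
  if (anyDuplicated(lab)) stop("duplicate tip labels")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  term <- tree$edge[, 2] <= length(lab)
  if (any(tree$edge.length[term] == 0))
    warning("zero-length terminal branch(es); covariance matrix may be singular")
  invisible(tree)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' `C[i, j]` is the shared root-to-tip path length of tips `i` and `j`;
#' `C[i, i]` is the depth of tip `i`. This is the covariance (up to the rate
#' sigma^2) of trait values at the tips under Brownian motion, and the
#' lambda = 1 covariance used by the signal and regression machinery.
#'
#' @param tree A valid `"phylo"` object.
#' @return A symmetric numeric matrix with tip labels as dimnames, rows and
#'   columns in `tree$tip.label` order.
#' @examples
#' phylo_vcv(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Pagel's lambda transformation of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of `C` by `lambda`, leaving the
#' diagonal untouched. `lambda = 1` returns `C`; `lambda = 0` removes all
#' phylogenetic covariance (a diagonal matrix, i.e. no signal).
#'
#' @param C A phylogenetic covariance matrix (see [phylo_vcv()]).
#' @param lambda A number in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single number in [0, 1]")
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

#' Prune a tree to a set of tips
#'
#' Returns the induced subtree on `keep`: path lengths between retained tips
#' are preserved and internal nodes left with a single descendant are
#' collapsed, their branch lengths summed.
#'
#' @param tree A valid `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `"phylo"` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 retained tips")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Export a covariance matrix as CSV with taxa header row and column
#'
#' @param C Covariance matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcv_csv <- function(C, path) {
  utils::write.csv(C, path, row.names = TRUE)
  invisible(path)
}

# Cholesky factor of V with a logged 1e-10 diagonal ridge if V is
# numerically singular (e.g. zero-length terminal branches).
chol_safe <- function(V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    warning("covariance not positive definite; adding 1e-10 ridge to diagonal")
    ch <- chol(V + diag(1e-10 * mean(diag(V)), nrow(V)))
  }
  ch
}

# Gaussian log-likelihood machinery shared by the lambda and PGLS profiles:
# given cholesky factor of V, whitened residuals and log|V|.
gls_decompose <- function(V, y, X) {
  ch <- chol_safe(V)
  logdet <- 2 * sum(log(diag(ch)))
  yw <- backsolve(ch, y, transpose = TRUE)
  Xw <- backsolve(ch, X, transpose = TRUE)
  list(logdet = logdet, yw = yw, Xw = Xw)
}
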