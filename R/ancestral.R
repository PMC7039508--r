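#' Ancestral states of a continuous trait under Brownian motion
#'
#' Maximum-likelihood reconstruction: each internal node's estimate is the
#' generalized-least-squares prediction of the node value given the tip
#' values and the Brownian covariance structure (equivalently, the mode of
#' the joint likelihood over all internal states). The root estimate equals
#' the GLS mean `(1' C^-1 x) / (1' C^-1 1)`. Prediction variances use the
#' plug-in ML rate `sigma2_hat = (x - mu)' C^-1 (x - mu) / n` and account
#' for the estimation of the root mean.
#'
#' @param tree A valid `"phylo"` object with at least 2 tips.
#' @param x Numeric trait, named by tip label or in tip order.
#' @return An object of class `"ancestral_recon"` with fields
#'   `node_estimates` and `node_variances` (named by internal node number,
#'   as in `tree$edge`), `root_estimate`, `sigma2`, and the inputs.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ml_ancestral_continuous(tr, c(A = 1, B = 3, C = 8))
#' @export
ml_ancestral_continuous <- function(tree, x) {
  validate_tree(tree)
  x <- align_trait(tree, x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 taxa")
  if (any(!is.finite(x))) stop("non-finite trait values")

  C <- phylo_vcv(tree)
  nodes <- (n + 1L):(n + tree$Nnode)
  depths <- ape::node.depth.edgelength(tree)   # root-to-node path lengths
  mrca_all <- ape::mrca(tree, full = TRUE)     # node numbers for all pairs
  # cov(node u, tip i) under BM = depth of their most recent common ancestor
  Cnt <- matrix(depths[mrca_all[nodes, seq_len(n)]],
                nrow = length(nodes), ncol = n)

  ch <- chol_safe(C)
  one <- rep(1, n)
  Cinv_x <- backsolve(ch, backsolve(ch, x, transpose = TRUE))
  Cinv_1 <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
  s11 <- sum(Cinv_1)
  mu <- sum(Cinv_x) / s11
  sigma2 <- sum((x - mu) * (Cinv_x - mu * Cinv_1)) / n

  est <- drop(mu + Cnt %*% (Cinv_x - mu * Cinv_1))
  # prediction variance with plug-in sigma2, including mean-estimation term
  CinvCnt <- backsolve(ch, backsolve(ch, t(Cnt), transpose = TRUE))
  quad <- colSums(t(Cnt) * CinvCnt)
  mean_term <- (1 - drop(Cnt %*% Cinv_1))^2 / s11
  vars <- pmax(0, sigma2 * (depths[nodes] - quad + mean_term))

  names(est) <- names(vars) <- nodes
  structure(list(
    node_estimates = est,
    node_variances = vars,
    root_estimate = unname(est[as.character(n + 1L)]),
    sigma2 = sigma2,
    tree = tree,
    trait = x
  ), class = "ancestral_recon")
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat(sprintf("BM ancestral reconstruction: %d internal nodes, root = %.4f\n",
              length(x$node_estimates), x$root_estimate))
  invisible(x)
}

#' Per-branch linear interpolation of ancestral estimates
#'
#' Numeric export of the trait gradient along every branch: `n_points`
#' evenly spaced positions between the parent and child estimates (tips use
#' their observed values). This is the data behind continuous-trait
#' "painted branch" figures, without the rendering.
#'
#' @param tree The tree used for the reconstruction.
#' @param recon An `"ancestral_recon"` from [ml_ancestral_continuous()].
#' @param x The tip trait used for the reconstruction.
#' @param n_points Number of interpolation points per branch (>= 2).
#' @return A data.frame with one row per (branch, point): `parent`,
#'   `child`, `position` in `[0, 1]` along the branch, and `value`.
#' @export
branch_gradient <- function(tree, recon, x, n_points = 10) {
  stopifnot(inherits(recon, "ancestral_recon"), n_points >= 2)
  x <- align_trait(tree, x)
  n <- length(tree$tip.label)
  node_val <- function(v)
    if (v <= n) x[[v]] else unname(recon$node_estimates[[as.character(v)]])
  pos <- seq(0, 1, length.out = n_points)
  out <- lapply(seq_len(nrow(tree$edge)), function(e) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    vp <- node_val(p); vc <- node_val(ch)
    data.frame(parent = p, child = ch, position = pos,
               value = vp + pos * (vc - vp))
  })
  do.call(rbind, out)
}
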