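#' Phylogenetic signal statistics
#'
#' Two signal measures, matching the variable types of the analysis:
#' Pagel's lambda for continuous (and ordinal-as-continuous) traits and
#' Fritz and Purvis's D for binary traits. Both come with a significance
#' test against the "no phylogenetic structure" null.
#'
#' @name phylo_signal
NULL

# Align a (possibly named) trait vector to the tree's tip order.
align_trait <- function(tree, x) {
  n <- length(tree$tip.label)
  if (!is.null(names(x))) {
    if (!all(tree$tip.label %in% names(x)))
      stop("trait names do not cover all tree tips")
    x <- x[tree$tip.label]
  } else if (length(x) != n) {
    stop("unnamed trait vector must have one value per tip")
  }
  if (anyNA(x)) stop("trait contains missing values; drop those taxa first")
  x
}

# Profile log-likelihood of lambda for a mean-only Gaussian model:
# x ~ N(mu * 1, sigma2 * lambda_transform(C, lambda)), mu and sigma2
# profiled analytically.
lambda_profile_loglik <- function(C, x, lambda) {
  n <- length(x)
  V <- lambda_transform(C, lambda)
  d <- gls_decompose(V, x, matrix(1, n, 1))
  mu <- sum(d$Xw * d$yw) / sum(d$Xw^2)
  rss <- sum((d$yw - mu * d$Xw)^2)
  sigma2 <- rss / n
  -n / 2 * log(2 * pi) - n / 2 * log(sigma2) - d$logdet / 2 - n / 2
}

# Maximize a 1-D function on [0, 1] by bounded search from multiple starts,
# with explicit endpoint evaluation; ties broken toward smaller lambda.
maximize_unit_interval <- function(f, starts = c(0, 0.25, 0.5, 0.75, 1)) {
  cand <- data.frame(lambda = c(0, 1), value = c(f(0), f(1)))
  br <- sort(unique(starts))
  for (i in seq_len(length(br) - 1)) {
    o <- stats::optimize(f, lower = br[i], upper = br[i + 1], maximum = TRUE,
                         tol = 1e-8)
    cand <- rbind(cand, data.frame(lambda = o$maximum, value = o$objective))
  }
  cand <- cand[order(-cand$value, cand$lambda), ]
  best <- cand[1, ]
  # snap near-boundary optima produced by optimize()'s interior tolerance
  if (best$lambda < 1e-6 && f(0) >= best$value - 1e-10)
    best <- data.frame(lambda = 0, value = f(0))
  if (best$lambda > 1 - 1e-6 && f(1) >= best$value - 1e-10)
    best <- data.frame(lambda = 1, value = f(1))
  best
}

#' Pagel's lambda for a continuous trait
#'
#' Maximum-likelihood estimate of the lambda branch-length transformation
#' for a single trait: the trait is modelled as multivariate normal with a
#' common mean and covariance `sigma2 * lambda_transform(C, lambda)`, with
#' mean and sigma2 profiled analytically and lambda maximized over `[0, 1]`.
#' Significance is a likelihood-ratio test of `lambda_hat` against
#' `lambda = 0` (no signal) on a chi-square with 1 df.
#'
#' @param tree A valid `"phylo"` object with at least 4 tips.
#' @param x Numeric trait vector, named by tip label (or in tip order).
#' @return An object of class `"signal_result"` with fields `statistic`
#'   (`"lambda"`), `estimate`, `log_likelihood`, `log_likelihood_0`,
#'   `p_value` (vs. the lambda = 0 null) and `n_taxa`.
#' @examples
#' tr <- simulate_tree(50, seed = 1)
#' x <- simulate_bm(tr, sigma2 = 1, root_value = 0, lambda = 1, seed = 2)
#' pagel_lambda(tr, x)
#' @export
pagel_lambda <- function(tree, x) {
  validate_tree(tree)
  x <- align_trait(tree, x)
  n <- length(x)
  if (n < 4L) stop("lambda is not reliably identifiable with fewer than 4 taxa")
  if (stats::var(x) == 0) stop("trait is constant; lambda undefined")
  C <- phylo_vcv(tree)
  f <- function(l) lambda_profile_loglik(C, x, l)
  best <- maximize_unit_interval(f)
  ll0 <- f(0)
  lr <- max(0, 2 * (best$value - ll0))
  structure(list(
    statistic = "lambda",
    estimate = best$lambda,
    log_likelihood = best$value,
    log_likelihood_0 = ll0,
    p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    n_taxa = n
  ), class = "signal_result")
}

# Linear machinery for the D statistic. Nodal values are estimated by a
# single Felsenstein-style post-order pass: a node's value is the mean of
# its daughters' values weighted by inverse (contrast-extended) branch
# lengths. Because that estimator is linear in the tip values, each
# daughter-pair difference is a fixed row vector over tips; d(trait) for
# any number of trait vectors is then one matrix product.
d_contrast_matrix <- function(tree) {
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  eps <- 1e-8 * max(ape::node.depth.edgelength(tree))
  W <- matrix(0, n + nnode, n)          # node value as weights over tips
  W[cbind(1:n, 1:n)] <- 1
  ext <- numeric(n + nnode)             # contrast branch-length extension
  rows <- list()
  edges <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  for (node in unique(po$edge[, 1])) {  # postorder guarantees children done
    idx <- edges[[as.character(node)]]
    kids <- po$edge[idx, 2]
    bl <- pmax(po$edge.length[idx] + ext[kids], eps)
    w <- (1 / bl) / sum(1 / bl)
    W[node, ] <- colSums(W[kids, , drop = FALSE] * w)
    ext[node] <- 1 / sum(1 / bl)
    for (i in seq_along(kids)[-length(kids)])
      for (j in seq.int(i + 1, length(kids)))
        rows[[length(rows) + 1L]] <- W[kids[i], ] - W[kids[j], ]
  }
  do.call(rbind, rows)
}

# Sum of absolute sister-clade differences for each column of a trait matrix.
d_values <- function(Dm, traits) colSums(abs(Dm %*% traits))

#' Fritz and Purvis's D for a binary trait
#'
#' Measures phylogenetic signal of a binary trait as the sum of absolute
#' sister-clade differences in estimated nodal values (`d_obs`), scaled
#' between two null expectations: `D = (d_obs - mean(d_B)) /
#' (mean(d_R) - mean(d_B))`, where `d_R` comes from random permutations of
#' the tip states and `d_B` from Brownian simulations thresholded to the
#' observed prevalence. D centres at 1 under phylogenetic randomness and at
#' 0 under the Brownian threshold model; it is reported unclipped and can
#' legitimately fall outside `[0, 1]` (strong clumping gives D < 0,
#' overdispersion D > 1).
#'
#' P-values are one-sided towards clumping: `p_value` (vs. random) is the
#' fraction of permutation d values at or below `d_obs`; `p_brownian` is
#' the fraction of Brownian d values at or above `d_obs`.
#'
#' @param tree A valid `"phylo"` object.
#' @param x Binary trait (0/1, logical, or 2-level factor), named by tip
#'   label or in tip order; both states must be present.
#' @param n_permutations,n_simulations Number of permutation and Brownian
#'   null replicates (each at least 100; default 1000).
#' @param seed Integer seed making the null distributions reproducible.
#' @return An object of class `"signal_result"` with fields `statistic`
#'   (`"D"`), `estimate`, `p_value`, `p_brownian`, `n_taxa`, `components`
#'   (`d_obs`, `mean_d_random`, `mean_d_brownian`) and `null_settings`.
#' @export
fritz_purvis_d <- function(tree, x, n_permutations = 1000,
                           n_simulations = 1000, seed = 1) {
  validate_tree(tree)
  if (is.factor(x)) {
    stopifnot(nlevels(droplevels(x)) == 2L)
    x <- stats::setNames(as.integer(x == levels(x)[2L]), names(x))
  }
  x <- align_trait(tree, as.numeric(x))
  if (!all(x %in% c(0, 1))) stop("trait must be binary 0/1")
  if (length(unique(x)) < 2L) stop("trait must show both states")
  if (n_permutations < 100 || n_simulations < 100)
    stop("use at least 100 null replicates")
  n <- length(x)
  Dm <- d_contrast_matrix(tree)
  d_obs <- d_values(Dm, matrix(x, ncol = 1))
  C <- phylo_vcv(tree)
  ch <- chol_safe(C)
  k1 <- sum(x)
  withr::with_seed(seed, {
    perm <- matrix(0, n, n_permutations)
    for (b in seq_len(n_permutations)) perm[, b] <- sample(x)
    bm <- crossprod(ch, matrix(stats::rnorm(n * n_simulations), n))
    # threshold each simulation so the number of 1s matches the data
    thr <- apply(bm, 2, function(v) as.numeric(rank(v, ties.method = "first") > n - k1))
  })
  d_R <- d_values(Dm, perm)
  d_B <- d_values(Dm, thr)
  estimate <- (d_obs - mean(d_B)) / (mean(d_R) - mean(d_B))
  structure(list(
    statistic = "D",
    estimate = unname(estimate),
    p_value = mean(d_R <= d_obs),
    p_brownian = mean(d_B >= d_obs),
    n_taxa = n,
    components = list(d_obs = unname(d_obs),
                      mean_d_random = mean(d_R),
                      mean_d_brownian = mean(d_B)),
    null_settings = list(n_permutations = n_permutations,
                         n_simulations = n_simulations, seed = seed)
  ), class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  if (x$statistic == "lambda") {
    cat(sprintf("Pagel's lambda = %.3f (logL = %.3f, n = %d)\n",
                x$estimate, x$log_likelihood, x$n_taxa))
    cat(sprintf("LR test vs lambda = 0: p = %.4g\n", x$p_value))
  } else {
    cat(sprintf("Fritz-Purvis D = %.3f (n = %d)\n", x$estimate, x$n_taxa))
    cat(sprintf("p vs random = %.4g, p vs Brownian = %.4g\n",
                x$p_value, x$p_brownian))
  }
  invisible(x)
}
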