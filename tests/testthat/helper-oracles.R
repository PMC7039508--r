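# Independent oracle implementations used to verify the package's fast
# paths. These deliberately use naive algorithms (explicit inversion,
# enumeration, grid search) and independent libraries (Matrix::expm).

# Brute-force phylogenetic covariance: for every pair of tips, sum the
# branch lengths of the edges shared by their root-to-tip paths.
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  path_edges <- function(tip) {
    edges <- integer(0)
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  }
  paths <- lapply(seq_len(n), path_edges)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  }
  C
}

# GLS coefficients by explicit matrix inversion.
oracle_gls_beta <- function(V, X, y) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
}

# Dense grid search for the lambda maximizing the mean-only profile
# likelihood (profiled mu and sigma2 computed by explicit inversion).
oracle_lambda_grid <- function(tree, x, n_grid = 1001) {
  C <- phylo_vcv(tree)
  x <- x[tree$tip.label]
  n <- length(x)
  ll <- function(lam) {
    V <- lambda_transform(C, lam)
    Vi <- solve(V)
    one <- rep(1, n)
    mu <- drop(one %*% Vi %*% x) / drop(one %*% Vi %*% one)
    s2 <- drop(t(x - mu) %*% Vi %*% (x - mu)) / n
    -n / 2 * log(2 * pi) - n / 2 * log(s2) - determinant(V)$modulus / 2 - n / 2
  }
  grid <- seq(0, 1, length.out = n_grid)
  vals <- vapply(grid, ll, numeric(1))
  list(lambda = grid[which.max(vals)], loglik = max(vals))
}

# CTMC log-likelihood by explicit enumeration of all internal-node states,
# with transition probabilities from Matrix::expm (independent of the
# package's eigendecomposition pruning).
oracle_ctmc_enum <- function(tree, tip_states, q, prior) {
  k <- nrow(q)
  n <- length(tree$tip.label)
  n_int <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(q * tree$edge.length[e])))
  states <- as.integer(tip_states)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    all_states <- c(states, combos[r, ])
    lik <- prior[all_states[n + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      lik <- lik * P[[e]][all_states[tree$edge[e, 1]], all_states[tree$edge[e, 2]]]
    }
    total <- total + lik
  }
  log(total)
}

# Two-state Mk pruning log-likelihood in plain R with Matrix::expm,
# for the independent-model factorization identity.
oracle_mk2_loglik <- function(tree, tip01, gain, loss, prior = c(0.5, 0.5)) {
  q <- matrix(c(-gain, gain, loss, -loss), 2, 2, byrow = TRUE)
  po <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  L <- matrix(1, n + tree$Nnode, 2)
  L[cbind(seq_len(n), tip01[tree$tip.label] + 1L)] <- 1
  L[cbind(seq_len(n), 2L - tip01[tree$tip.label])] <- 0
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    P <- as.matrix(Matrix::expm(q * po$edge.length[e]))
    v <- P %*% L[po$edge[e, 2], ]
    L[po$edge[e, 1], ] <- L[po$edge[e, 1], ] * v
    m <- max(L[po$edge[e, 1], ])
    L[po$edge[e, 1], ] <- L[po$edge[e, 1], ] / m
    logscale <- logscale + log(m)
  }
  log(sum(L[n + 1L, ] * prior)) + logscale
}

# Full Brownian-motion simulation including internal-node values
# (preorder walk with independent normal increments).
oracle_bm_full <- function(tree, sigma2, root_value = 0) {
  n <- length(tree$tip.label)
  vals <- numeric(n + tree$Nnode)
  vals[n + 1L] <- root_value
  pr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pr$edge))) {
    vals[pr$edge[e, 2]] <- vals[pr$edge[e, 1]] +
      stats::rnorm(1, 0, sqrt(sigma2 * pr$edge.length[e]))
  }
  vals
}

# 4-state independent-model generator from per-trait gain/loss rates.
indep_q <- function(x_gain, x_loss, y_gain, y_loss) {
  make_rate_matrix(c(q12 = y_gain, q21 = y_loss, q13 = x_gain, q31 = x_loss,
                     q24 = x_gain, q42 = x_loss, q34 = y_gain, q43 = y_loss))
}

# Simulate a binary trait pair on a tree under a 4-state chain and return
# aligned 0/1 vectors (NULL if either trait comes out constant).
sim_binary_pair <- function(tree, q, seed) {
  s <- simulate_discrete(tree, q, root_state = 1, seed = seed)
  st <- c("00", "01", "10", "11")[s]
  xy <- split_states(st)
  x <- stats::setNames(xy$x, names(s))
  y <- stats::setNames(xy$y, names(s))
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NULL)
  list(x = x, y = y)
}
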