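test_that("constant traits reconstruct constant with nonnegative variances", {
  tr <- simulate_tree(15, seed = 81)
  rec <- ml_ancestral_continuous(tr, stats::setNames(rep(3.2, 15), tr$tip.label))
  expect_true(all(abs(rec$node_estimates - 3.2) < 1e-10))
  expect_true(all(rec$node_variances >= 0))
})

test_that("a two-tip symmetric tree puts the root at the tip mean", {
  tr <- parse_newick("(A:1,B:1);")
  rec <- ml_ancestral_continuous(tr, c(A = 2, B = 6))
  expect_equal(rec$root_estimate, 4)
})

test_that("estimates match a joint-likelihood numeric optimization oracle", {
  for (seed in 1:4) {
    tr <- simulate_tree(5, seed = 90 + seed)
    x <- simulate_bm(tr, 1, 2, lambda = 1, seed = 95 + seed)
    rec <- ml_ancestral_continuous(tr, x)
    # maximize the joint BM density over all internal states: equivalent to
    # minimizing the branch-weighted sum of squared changes
    obj <- function(a) {
      vals <- c(x[tr$tip.label], a)
      sum((vals[tr$edge[, 2]] - vals[tr$edge[, 1]])^2 / tr$edge.length)
    }
    o <- stats::optim(rep(mean(x), tr$Nnode), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 2000))
    expect_equal(unname(rec$node_estimates), o$par, tolerance = 1e-5)
  }
})

test_that("the root estimate is the GLS phylogenetic mean", {
  tr <- simulate_tree(30, seed = 101)
  x <- simulate_bm(tr, 1, -1, lambda = 1, seed = 102)
  rec <- ml_ancestral_continuous(tr, x)
  C <- phylo_vcv(tr)
  one <- rep(1, 30)
  mu <- drop(one %*% solve(C, x)) / drop(one %*% solve(C, one))
  expect_equal(rec$root_estimate, mu, tolerance = 1e-10)
})

test_that("reconstruction is shift- and scale-equivariant", {
  tr <- simulate_tree(12, seed = 103)
  x <- simulate_bm(tr, 1, 0, lambda = 1, seed = 104)
  r1 <- ml_ancestral_continuous(tr, x)
  r2 <- ml_ancestral_continuous(tr, 3 * x + 7)
  expect_equal(r2$node_estimates, 3 * r1$node_estimates + 7, tolerance = 1e-10)
})

test_that("estimates agree with an independent fast reconstruction", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(40, seed = 105)
  x <- simulate_bm(tr, 1, 5, lambda = 1, seed = 106)
  rec <- ml_ancestral_continuous(tr, x)
  fa <- phytools::fastAnc(tr, x)
  expect_equal(unname(rec$node_estimates),
               unname(fa[names(rec$node_estimates)]), tolerance = 1e-8)
})

test_that("reconstruction error shrinks towards the tips on simulated data", {
  tr <- simulate_tree(50, seed = 107)
  depths <- ape::node.depth.edgelength(tr)[51:(50 + tr$Nnode)]
  err <- matrix(0, 100, tr$Nnode)
  withr::with_seed(108, {
    for (i in 1:100) {
      vals <- oracle_bm_full(tr, 1)
      x <- stats::setNames(vals[1:50], tr$tip.label)
      rec <- ml_ancestral_continuous(tr, x)
      err[i, ] <- abs(rec$node_estimates - vals[51:(50 + tr$Nnode)])
    }
  })
  # deeper nodes (farther from the tips on a unit-depth tree) are harder
  ct <- stats::cor.test(depths, colMeans(err), method = "spearman")
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("branch gradients interpolate linearly between endpoint estimates", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  x <- c(A = 1, B = 3, C = 9)
  rec <- ml_ancestral_continuous(tr, x)
  g <- branch_gradient(tr, rec, x, n_points = 3)
  expect_equal(nrow(g), 4 * 3)
  # first/last points equal the endpoint values exactly
  for (e in seq_len(nrow(tr$edge))) {
    seg <- g[g$parent == tr$edge[e, 1] & g$child == tr$edge[e, 2], ]
    node_val <- function(v) if (v <= 3) x[[v]] else
      rec$node_estimates[[as.character(v)]]
    expect_equal(seg$value[1], node_val(tr$edge[e, 1]))
    expect_equal(seg$value[3], node_val(tr$edge[e, 2]))
    expect_equal(seg$value[2], mean(seg$value[c(1, 3)]))
  }
  # constant trait gives constant interpolation
  recc <- ml_ancestral_continuous(tr, c(A = 2, B = 2, C = 2))
  gc <- branch_gradient(tr, recc, c(A = 2, B = 2, C = 2), n_points = 5)
  expect_true(all(abs(gc$value - 2) < 1e-10))
  expect_error(branch_gradient(tr, rec, x, n_points = 1), "n_points")
})
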