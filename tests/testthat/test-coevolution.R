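test_that("combined states encode (x, y) pairs bijectively", {
  s <- combined_states(c(0, 1), c(1, 1))
  expect_equal(as.character(s), c("01", "11"))
  expect_equal(as.character(combined_states(c(0, 0), c(0, 0))), c("00", "00"))
  withr::with_seed(1, {
    x <- stats::rbinom(30, 1, 0.5)
    y <- stats::rbinom(30, 1, 0.5)
  })
  back <- split_states(combined_states(x, y))
  expect_equal(back$x, x)
  expect_equal(back$y, y)
  expect_error(combined_states(c(0, 2), c(0, 1)), "binary")
})

test_that("rate matrices forbid double transitions and have zero row sums", {
  q <- make_rate_matrix(c(q12 = 1, q21 = 2, q13 = 3, q31 = 4,
                          q24 = 5, q42 = 6, q34 = 7, q43 = 8))
  expect_equal(rowSums(q), rep(0, 4), ignore_attr = TRUE)
  expect_equal(q["00", "11"], 0)
  expect_equal(q["01", "10"], 0)
  expect_equal(q["00", "01"], 1)
  expect_equal(q["11", "01"], 6)
  bad <- q; bad["00", "11"] <- 0.5; bad["00", "00"] <- bad["00", "00"] - 0.5
  expect_error(phylodwell:::validate_rate_matrix(bad), "double")
})

test_that("a zero-rate chain gives log-prior for uniform data and -Inf otherwise", {
  tr <- simulate_tree(6, seed = 120)
  q0 <- make_rate_matrix(stats::setNames(rep(0, 8), phylodwell:::ctmc_rate_names))
  same <- factor(rep("10", 6), levels = c("00", "01", "10", "11"))
  names(same) <- tr$tip.label
  expect_equal(ctmc_loglik(tr, same, q0), log(1 / 4))
  mixed <- factor(c("10", "11", rep("10", 4)), levels = c("00", "01", "10", "11"))
  names(mixed) <- tr$tip.label
  expect_equal(ctmc_loglik(tr, mixed, q0), -Inf)
})

test_that("pruning likelihood matches brute-force enumeration on 3-tip trees", {
  for (seed in 1:5) {
    tr <- simulate_tree(3, seed = 130 + seed)
    withr::with_seed(140 + seed, {
      rates <- stats::setNames(stats::runif(8, 0.1, 2),
                               phylodwell:::ctmc_rate_names)
      tip <- factor(sample(c("00", "01", "10", "11"), 3, replace = TRUE),
                    levels = c("00", "01", "10", "11"))
    })
    names(tip) <- tr$tip.label
    q <- make_rate_matrix(rates)
    expect_equal(ctmc_loglik(tr, tip, q),
                 oracle_ctmc_enum(tr, tip, q, rep(0.25, 4)),
                 tolerance = 1e-10)
  }
})

test_that("transition probabilities are stochastic: tip-state likelihoods sum to 1", {
  # summing the likelihood over every possible 2-tip state assignment must
  # give exactly 1 if each exp(Q t) has unit row sums and the prior sums to 1
  tr <- parse_newick("(A:0.7,B:1.3);")
  q <- make_rate_matrix(c(q12 = 0.5, q21 = 1.5, q13 = 0.2, q31 = 0.9,
                          q24 = 2, q42 = 0.1, q34 = 0.8, q43 = 0.4))
  states <- c("00", "01", "10", "11")
  total <- 0
  for (a in states) for (b in states) {
    tip <- factor(c(a, b), levels = states)
    names(tip) <- c("A", "B")
    total <- total + exp(ctmc_loglik(tr, tip, q))
  }
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("the independent-model likelihood factorizes into two Mk chains", {
  tr <- simulate_tree(40, seed = 150)
  q <- indep_q(x_gain = 0.8, x_loss = 0.3, y_gain = 1.2, y_loss = 0.6)
  pair <- sim_binary_pair(tr, q, seed = 151)
  st <- combined_states(pair$x, pair$y)
  names(st) <- names(pair$x)
  ll4 <- ctmc_loglik(tr, st, q)
  llx <- oracle_mk2_loglik(tr, pair$x, gain = 0.8, loss = 0.3)
  lly <- oracle_mk2_loglik(tr, pair$y, gain = 1.2, loss = 0.6)
  expect_equal(ll4, llx + lly, tolerance = 1e-8)
})

test_that("model likelihoods respect nesting and LR is symmetric in trait labels", {
  tr <- simulate_tree(60, seed = 160)
  q <- make_rate_matrix(c(q12 = 0.5, q21 = 0.5, q13 = 0.4, q31 = 0.6,
                          q24 = 3, q42 = 0.2, q34 = 0.9, q43 = 0.5))
  pair <- sim_binary_pair(tr, q, seed = 161)
  pt <- pagel_test(tr, pair$x, pair$y, n_restarts = 5, seed = 1)
  ll <- vapply(pt$fits, `[[`, numeric(1), "log_likelihood")
  expect_gte(ll["dependent"], max(ll["dep_x"], ll["dep_y"]) - 1e-4)
  expect_gte(min(ll["dep_x"], ll["dep_y"]), ll["independent"] - 1e-4)
  expect_equal(pt$lr_statistic,
               2 * (ll["dependent"] - ll["independent"]),
               ignore_attr = TRUE)
  # swapping which trait is x and which is y leaves the headline LR alone
  pt2 <- pagel_test(tr, pair$y, pair$x, n_restarts = 5, seed = 1)
  expect_equal(pt$lr_statistic, pt2$lr_statistic, tolerance = 1e-3)
})

test_that("perfectly coupled traits favour the dependent model strictly", {
  tr <- simulate_tree(50, seed = 162)
  q2 <- indep_q(1, 1, 1, 1)
  repeat {
    pair <- sim_binary_pair(tr, q2, seed = 163)
    if (!is.null(pair)) break
  }
  x <- pair$x
  f_ind <- fit_pagel_model(tr, x, x, "independent", n_restarts = 4, seed = 2)
  f_dep <- fit_pagel_model(tr, x, x, "dependent", n_restarts = 4, seed = 2,
                           extra_starts = list(f_ind$rates))
  expect_gt(f_dep$log_likelihood, f_ind$log_likelihood + 1)
})

test_that("fitted likelihoods agree with an independent reference implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(50, seed = 170)
  q <- make_rate_matrix(c(q12 = 0.5, q21 = 0.5, q13 = 0.4, q31 = 0.6,
                          q24 = 2.5, q42 = 0.2, q34 = 0.9, q43 = 0.5))
  pair <- sim_binary_pair(tr, q, seed = 171)
  pt <- pagel_test(tr, pair$x, pair$y, n_restarts = 6, seed = 3)
  xf <- stats::setNames(factor(pair$x), names(pair$x))
  yf <- stats::setNames(factor(pair$y), names(pair$y))
  fp <- suppressWarnings(
    phytools::fitPagel(tr, xf, yf, method = "fitMk", pi = "equal"))
  expect_equal(pt$fits$independent$log_likelihood, fp$independent.logL,
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(pt$fits$dependent$log_likelihood, fp$dependent.logL,
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("monomorphic traits are rejected", {
  tr <- simulate_tree(10, seed = 180)
  x <- stats::setNames(rep(1, 10), tr$tip.label)
  y <- stats::setNames(rep(c(0, 1), 5), tr$tip.label)
  expect_error(fit_pagel_model(tr, x, y, "independent"), "both states")
})
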