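sim_reg_data <- function(tree, beta = c(1, 0.5, 0.8), lambda = 0.6,
                         sigma2 = 0.5, seed = 1) {
  n <- length(tree$tip.label)
  gen <- function() {
    d <- data.frame(society_id = tree$tip.label,
                    x = stats::rnorm(n),
                    z = stats::rbinom(n, 1, 0.5))
    d$y <- beta[1] + beta[2] * d$x + beta[3] * d$z +
      simulate_bm(tree, sigma2, 0, lambda = lambda)
    d
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

test_that("PGLS at fixed lambda = 0 equals heteroscedastic weighted OLS", {
  tr <- simulate_tree(40, seed = 31)
  d <- sim_reg_data(tr, seed = 32)
  f0 <- pgls_fit(tr, d, y ~ x + z, lambda = 0)
  w <- stats::lm(y ~ x + z, data = d, weights = 1 / diag(phylo_vcv(tr)))
  expect_equal(unname(f0$coefficients), unname(stats::coef(w)),
               tolerance = 1e-10)
  fs <- summary(w)$fstatistic
  expect_equal(f0$f_p_value,
               stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a zero-residual linear relation is fit exactly", {
  tr <- simulate_tree(20, seed = 33)
  d <- data.frame(society_id = tr$tip.label, x = seq_len(20) / 5)
  d$y <- 2 + 0.5 * d$x
  f <- pgls_fit(tr, d, y ~ x, lambda = 0.5)
  expect_equal(unname(f$coefficients), c(2, 0.5), tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-8)
})

test_that("coefficients match an explicit-inverse GLS oracle on small trees", {
  for (seed in 1:5) {
    tr <- simulate_tree(10, seed = 40 + seed)
    d <- sim_reg_data(tr, seed = 50 + seed)
    lam <- c(0, 0.3, 0.6, 0.9, 1)[seed]
    f <- pgls_fit(tr, d, y ~ x + z, lambda = lam)
    X <- cbind(1, d$x, d$z)
    V <- lambda_transform(phylo_vcv(tr), lam)
    expect_equal(unname(f$coefficients),
                 drop(oracle_gls_beta(V, X, d$y)), tolerance = 1e-8)
  }
})

test_that("profile-ML lambda in regression matches a dense grid search", {
  tr <- simulate_tree(50, seed = 61)
  d <- sim_reg_data(tr, lambda = 0.5, seed = 62)
  f <- pgls_fit(tr, d, y ~ x + z)
  X <- stats::model.matrix(~ x + z, d)
  C <- phylo_vcv(tr)
  grid <- seq(0, 1, length.out = 1001)
  ll <- vapply(grid, function(l)
    phylodwell:::pgls_profile_loglik(C, d$y, X, l)$loglik, numeric(1))
  expect_lt(abs(f$lambda - grid[which.max(ll)]), 0.01)
})

test_that("under lambda = 0 on an equal-depth tree the F-test matches plain OLS", {
  # lambda = 0 reduces the covariance of any unit-depth ultrametric tree to
  # the identity, i.e. the star-phylogeny (no shared ancestry) model
  star <- simulate_tree(30, seed = 68)
  d <- sim_reg_data(star, lambda = 0, seed = 63)
  f <- pgls_fit(star, d, y ~ x + z, lambda = 0)
  ols <- stats::lm(y ~ x + z, data = d)
  fs <- summary(ols)$fstatistic
  expect_equal(f$f_p_value,
               stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(f$coefficients), unname(stats::coef(ols)),
               tolerance = 1e-8)
})

test_that("log-likelihood is invariant to joint permutation of data rows", {
  tr <- simulate_tree(25, seed = 64)
  d <- sim_reg_data(tr, seed = 65)
  f1 <- pgls_fit(tr, d, y ~ x + z)
  d2 <- d[sample(nrow(d)), ]
  f2 <- pgls_fit(tr, d2, y ~ x + z)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-10)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("a pure-noise predictor cannot decrease raw R2 and tends to raise AIC", {
  tr <- simulate_tree(50, seed = 66)
  worse_aic <- 0L
  withr::with_seed(67, {
    for (i in 1:100) {
      d <- sim_reg_data(tr, seed = NULL)
      d$junk <- stats::rnorm(nrow(d))
      fa <- pgls_fit(tr, d, y ~ x, lambda = 0.5)
      fb <- pgls_fit(tr, d, y ~ x + junk, lambda = 0.5)
      expect_gte(fb$r2, fa$r2 - 1e-10)
      worse_aic <- worse_aic + (fb$aic > fa$aic)
    }
  })
  # under the null the noise term raises AIC unless its LR exceeds 2
  # (about 84% of the time); one-sided binomial bound at 0.99 confidence
  expect_gte(worse_aic, stats::qbinom(0.99, 100, 0.5))
})

test_that("model_table ranks models, reports per-row n, and survives failures", {
  study <- simulate_study(study_config(n_taxa = 60, seed = 71))
  cd <- build_dataset(study$records, study$tree)
  tab <- model_table(cd$tree, cd$data,
                     list(ahfa_log ~ pmr_ord,
                          ahfa_log ~ pmr_ord + settlement,
                          ahfa_log ~ pmr_ord,
                          ahfa_log ~ not_a_column))
  expect_equal(nrow(tab), 4L)
  expect_equal(sum(tab$best), 1L)
  expect_false(is.na(tab$error[4]))
  expect_true(is.na(tab$aic[4]))
  # duplicate specs give identical rows
  expect_equal(tab$aic[1], tab$aic[3])
  expect_equal(tab$n[1], 60L)
})

test_that("intercept-only models get adjusted R2 of 0 by convention", {
  tr <- simulate_tree(20, seed = 72)
  d <- sim_reg_data(tr, seed = 73)
  f <- pgls_fit(tr, d, y ~ 1)
  expect_equal(f$r2_adjusted, 0)
  expect_true(is.na(f$f_p_value))
})

test_that("rank-deficient designs and bad inputs are rejected", {
  tr <- simulate_tree(20, seed = 74)
  d <- sim_reg_data(tr, seed = 75)
  d$x2 <- d$x
  expect_error(pgls_fit(tr, d, y ~ x + x2), "rank-deficient")
  expect_error(pgls_fit(tr, d, y ~ missing_var), "not in data")
})
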