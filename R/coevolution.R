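#' Pagel's test for correlated evolution of two binary traits
#'
#' Two binary traits are combined into a 4-state character
#' ((0,0), (0,1), (1,0), (1,1)) evolving under a continuous-time Markov
#' chain in which simultaneous change of both traits is forbidden. The
#' independent model (4 free rates) constrains each trait's gain and loss
#' rates to be the same regardless of the other trait's state; the
#' dependent model frees all 8 permitted rates; `dep_x` / `dep_y` free one
#' trait's rates only (6 parameters each). Correlated evolution is assessed
#' by a likelihood-ratio test of dependent vs. independent on a chi-square
#' with 4 df, plus an AIC ranking over all four models.
#'
#' @name discrete_coevolution
NULL

ctmc_states <- c("00", "01", "10", "11")

# the 8 permitted transitions (no simultaneous double changes)
ctmc_transitions <- matrix(c(
  "00", "01",   # y gain, x = 0   q12
  "01", "00",   # y loss, x = 0   q21
  "00", "10",   # x gain, y = 0   q13
  "10", "00",   # x loss, y = 0   q31
  "01", "11",   # x gain, y = 1   q24
  "11", "01",   # x loss, y = 1   q42
  "10", "11",   # y gain, x = 1   q34
  "11", "10"    # y loss, x = 1   q43
), ncol = 2, byrow = TRUE)

ctmc_rate_names <- c("q12", "q21", "q13", "q31", "q24", "q42", "q34", "q43")

as_binary01 <- function(v, name) {
  if (is.factor(v)) {
    if (nlevels(droplevels(v)) > 2L) stop(name, " is not binary")
    v <- stats::setNames(as.integer(v == levels(v)[2L]), names(v))
  }
  v <- stats::setNames(as.numeric(v), names(v))
  if (!all(v %in% c(0, 1))) stop(name, " must be binary 0/1")
  v
}

#' Combine two binary traits into a 4-state character
#'
#' @param x,y Binary traits (0/1, logical or 2-level factors) over the same
#'   taxa, in the same order (names preserved from `x`).
#' @return Factor with levels `"00", "01", "10", "11"`, encoding
#'   `(x, y)` pairs.
#' @examples
#' combined_states(c(0, 1), c(1, 1))
#' @export
combined_states <- function(x, y) {
  x <- as_binary01(x, "x"); y <- as_binary01(y, "y")
  if (length(x) != length(y)) stop("x and y lengths differ")
  factor(paste0(x, y), levels = ctmc_states)
}

#' Split a combined 4-state character back into its two binary traits
#'
#' @param s Factor or character vector of combined states.
#' @return List with numeric 0/1 components `x` and `y`.
#' @export
split_states <- function(s) {
  s <- as.character(s)
  stopifnot(all(s %in% ctmc_states))
  list(x = as.numeric(substr(s, 1, 1)), y = as.numeric(substr(s, 2, 2)))
}

#' Build a 4-state rate matrix from its 8 permitted transition rates
#'
#' @param rates Named vector with entries `q12, q21, q13, q31, q24, q42,
#'   q34, q43` (state order 1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1));
#'   all nonnegative. Entries between states differing in both traits are
#'   structurally zero and rows sum to zero.
#' @return A 4x4 matrix with state dimnames.
#' @export
make_rate_matrix <- function(rates) {
  stopifnot(all(ctmc_rate_names %in% names(rates)), all(rates >= 0))
  q <- matrix(0, 4, 4, dimnames = list(ctmc_states, ctmc_states))
  for (i in seq_len(nrow(ctmc_transitions))) {
    q[ctmc_transitions[i, 1], ctmc_transitions[i, 2]] <-
      rates[[ctmc_rate_names[i]]]
  }
  diag(q) <- -rowSums(q)
  q
}

validate_rate_matrix <- function(q) {
  stopifnot(is.matrix(q), all(dim(q) == 4))
  off <- q; diag(off) <- 0
  if (any(off < 0)) stop("negative off-diagonal rate")
  if (any(abs(rowSums(q)) > 1e-8)) stop("rate matrix rows must sum to 0")
  if (abs(q[1, 4]) > 0 || abs(q[4, 1]) > 0 ||
      abs(q[2, 3]) > 0 || abs(q[3, 2]) > 0)
    stop("simultaneous double transitions must have rate 0")
  if (any(!is.finite(q))) stop("non-finite rates")
  invisible(q)
}

stationary_distribution <- function(q) {
  A <- rbind(t(q), rep(1, 4))
  pi <- qr.solve(A, c(0, 0, 0, 0, 1))
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

# postorder edge structure reused across likelihood evaluations
ctmc_tree_data <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, edge_length = po$edge.length,
       n_tip = length(tree$tip.label), n_node = tree$Nnode)
}

#' Pruning log-likelihood of a 4-state CTMC on a tree
#'
#' Felsenstein's pruning algorithm with per-branch transition probabilities
#' `P(t) = exp(Q t)`, root state integrated against the prior. Data that a
#' zero-rate chain cannot produce yield `-Inf`.
#'
#' @param tree A valid `"phylo"` object.
#' @param tip_states Combined states from [combined_states()], named by tip
#'   label or in tip order.
#' @param q A 4x4 rate matrix (see [make_rate_matrix()]).
#' @param root_prior `"flat"` (1/4 each, the default) or `"stationary"`.
#' @return The log-likelihood (a scalar; may be `-Inf`).
#' @export
ctmc_loglik <- function(tree, tip_states, q,
                        root_prior = c("flat", "stationary")) {
  validate_tree(tree)
  validate_rate_matrix(q)
  root_prior <- match.arg(root_prior)
  if (is.null(names(tip_states)) || is.factor(tip_states)) {
    st <- tip_states
  }
  if (!is.null(names(tip_states))) {
    st <- tip_states[tree$tip.label]
  } else {
    stopifnot(length(tip_states) == length(tree$tip.label))
    st <- tip_states
  }
  st_int <- as.integer(factor(as.character(st), levels = ctmc_states))
  if (anyNA(st_int)) stop("tip states must be in {00, 01, 10, 11}")
  prior <- if (root_prior == "flat") rep(0.25, 4) else stationary_distribution(q)
  td <- ctmc_tree_data(tree)
  ctmc_loglik_cpp(td$edge, td$edge_length, st_int, td$n_tip, td$n_node,
                  q, prior)
}

# free-parameter template for each model: maps a log-rate vector to the
# full 8 named rates
ctmc_model_template <- function(model) {
  switch(model,
    independent = list(
      n_free = 4L,
      par_names = c("x_gain", "x_loss", "y_gain", "y_loss"),
      expand = function(p) c(q12 = p[["y_gain"]], q21 = p[["y_loss"]],
                             q13 = p[["x_gain"]], q31 = p[["x_loss"]],
                             q24 = p[["x_gain"]], q42 = p[["x_loss"]],
                             q34 = p[["y_gain"]], q43 = p[["y_loss"]]),
      collapse = function(r) c(x_gain = mean(r[c("q13", "q24")]),
                               x_loss = mean(r[c("q31", "q42")]),
                               y_gain = mean(r[c("q12", "q34")]),
                               y_loss = mean(r[c("q21", "q43")]))),
    dependent = list(
      n_free = 8L,
      par_names = ctmc_rate_names,
      expand = function(p) p[ctmc_rate_names],
      collapse = function(r) r[ctmc_rate_names]),
    dep_x = list(  # x's rates depend on y's state; y's rates do not
      n_free = 6L,
      par_names = c("q13", "q24", "q31", "q42", "y_gain", "y_loss"),
      expand = function(p) c(q12 = p[["y_gain"]], q21 = p[["y_loss"]],
                             q13 = p[["q13"]], q31 = p[["q31"]],
                             q24 = p[["q24"]], q42 = p[["q42"]],
                             q34 = p[["y_gain"]], q43 = p[["y_loss"]]),
      collapse = function(r) c(r[c("q13", "q24", "q31", "q42")],
                               y_gain = mean(r[c("q12", "q34")]),
                               y_loss = mean(r[c("q21", "q43")]))),
    dep_y = list(  # y's rates depend on x's state; x's rates do not
      n_free = 6L,
      par_names = c("q12", "q34", "q21", "q43", "x_gain", "x_loss"),
      expand = function(p) c(q12 = p[["q12"]], q21 = p[["q21"]],
                             q13 = p[["x_gain"]], q31 = p[["x_loss"]],
                             q24 = p[["x_gain"]], q42 = p[["x_loss"]],
                             q34 = p[["q34"]], q43 = p[["q43"]]),
      collapse = function(r) c(r[c("q12", "q34", "q21", "q43")],
                               x_gain = mean(r[c("q13", "q24")]),
                               x_loss = mean(r[c("q31", "q42")]))),
    stop("unknown model: ", model)
  )
}

#' Fit one correlated-evolution model by maximum likelihood
#'
#' Rates are optimized on the log scale within `rate_bounds` (per unit
#' branch length) by bounded quasi-Newton search from one deterministic
#' start plus random restarts; the best solution across restarts is kept.
#'
#' @param tree A valid `"phylo"` object.
#' @param x,y Binary traits over the tips (0/1 or 2-level factors), named
#'   by tip label or in tip order.
#' @param model `"independent"`, `"dependent"`, `"dep_x"` (x's rates depend
#'   on y's state) or `"dep_y"`.
#' @param root_prior `"flat"` or `"stationary"`.
#' @param n_restarts Number of optimization starts (default 10).
#' @param seed Seed for the random restart points.
#' @param rate_bounds Lower/upper bounds on each rate.
#' @param extra_starts Optional list of named full-rate vectors used as
#'   additional warm starts (e.g. a nested model's solution).
#' @return An object of class `"coevol_fit"`: model name, fitted `rates`,
#'   `q` matrix, `n_free_params`, `log_likelihood`, `aic`, `convergence`.
#' @export
fit_pagel_model <- function(tree, x, y,
                            model = c("independent", "dependent",
                                      "dep_x", "dep_y"),
                            root_prior = c("flat", "stationary"),
                            n_restarts = 10, seed = 1,
                            rate_bounds = c(1e-6, 100),
                            extra_starts = NULL) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  validate_tree(tree)
  x <- align_trait(tree, as_binary01(x, "x"))
  y <- align_trait(tree, as_binary01(y, "y"))
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("both traits must show both states")
  st_int <- as.integer(combined_states(x, y))
  td <- ctmc_tree_data(tree)
  tmpl <- ctmc_model_template(model)
  flat_prior <- rep(0.25, 4)

  negll <- function(logp) {
    p <- stats::setNames(exp(logp), tmpl$par_names)
    q <- make_rate_matrix(tmpl$expand(p))
    prior <- if (root_prior == "flat") flat_prior else stationary_distribution(q)
    ll <- ctmc_loglik_cpp(td$edge, td$edge_length, st_int, td$n_tip,
                          td$n_node, q, prior)
    if (!is.finite(ll)) 1e10 else -ll
  }

  lb <- rep(log(rate_bounds[1]), tmpl$n_free)
  ub <- rep(log(rate_bounds[2]), tmpl$n_free)
  # deterministic start: one expected change per total tree length
  base_rate <- max(rate_bounds[1] * 10,
                   min(rate_bounds[2] / 10, 2 / max(ape::node.depth.edgelength(tree))))
  starts <- list(rep(log(base_rate), tmpl$n_free))
  if (!is.null(extra_starts)) {
    for (r in extra_starts) {
      p <- pmin(pmax(tmpl$collapse(r[ctmc_rate_names]), rate_bounds[1]),
                rate_bounds[2])
      starts[[length(starts) + 1L]] <- log(unname(p[tmpl$par_names]))
    }
  }
  n_random <- max(0L, n_restarts - length(starts))
  if (n_random > 0) {
    rnd <- withr::with_seed(seed, matrix(stats::runif(n_random * tmpl$n_free,
                                                      log(0.1), log(10)),
                                         nrow = n_random))
    for (i in seq_len(n_random)) starts[[length(starts) + 1L]] <- rnd[i, ]
  }

  best <- NULL
  conv <- FALSE
  for (s in starts) {
    o <- tryCatch(
      stats::nlminb(s, negll, lower = lb, upper = ub,
                    control = list(rel.tol = 1e-10, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$objective < best$objective) best <- o
    if (o$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("all optimization restarts failed for model ", model)

  p <- stats::setNames(exp(best$par), tmpl$par_names)
  rates <- tmpl$expand(p)[ctmc_rate_names]
  ll <- -best$objective
  structure(list(
    model = model,
    rates = rates,
    q = make_rate_matrix(rates),
    n_free_params = tmpl$n_free,
    log_likelihood = ll,
    aic = -2 * ll + 2 * tmpl$n_free,
    root_prior = root_prior,
    convergence = conv
  ), class = "coevol_fit")
}

#' @export
print.coevol_fit <- function(x, ...) {
  cat(sprintf("Pagel %s model: logL = %.4f, AIC = %.4f (%d free rates)\n",
              x$model, x$log_likelihood, x$aic, x$n_free_params))
  print(round(x$q, 4))
  invisible(x)
}

#' Pagel's correlated-evolution test
#'
#' Fits the independent, dependent and both one-way-dependent models,
#' reusing nested solutions as warm starts so the likelihood nesting
#' `logL(dependent) >= logL(dep_x), logL(dep_y) >= logL(independent)`
#' holds up to optimizer tolerance. The headline test is the likelihood
#' ratio of dependent vs. independent on chi-square with 4 df; the AIC
#' ranking over all four models addresses the direction of dependence.
#'
#' @inheritParams fit_pagel_model
#' @return An object of class `"pagel_test"` with fields `fits` (named list
#'   of the four `coevol_fit`s), `lr_statistic`, `lr_p_value`,
#'   `best_model_by_aic`, and an `aic_table`.
#' @examples
#' tr <- simulate_tree(60, seed = 1)
#' q <- make_rate_matrix(c(q12 = 1, q21 = 1, q13 = 1, q31 = 1,
#'                         q24 = 1, q42 = 1, q34 = 1, q43 = 1))
#' s <- split_states(ctmc_states[simulate_discrete(tr, q, root_state = 1,
#'                                                 seed = 2)])
#' pagel_test(tr, s$x, s$y, n_restarts = 4)
#' @export
pagel_test <- function(tree, x, y, root_prior = c("flat", "stationary"),
                       n_restarts = 10, seed = 1) {
  root_prior <- match.arg(root_prior)
  indep <- fit_pagel_model(tree, x, y, "independent", root_prior,
                           n_restarts, seed)
  depx <- fit_pagel_model(tree, x, y, "dep_x", root_prior, n_restarts,
                          seed + 1L, extra_starts = list(indep$rates))
  depy <- fit_pagel_model(tree, x, y, "dep_y", root_prior, n_restarts,
                          seed + 2L, extra_starts = list(indep$rates))
  dep <- fit_pagel_model(tree, x, y, "dependent", root_prior, n_restarts,
                         seed + 3L,
                         extra_starts = list(indep$rates, depx$rates,
                                             depy$rates))
  fits <- list(independent = indep, dep_x = depx, dep_y = depy,
               dependent = dep)
  lr <- max(0, 2 * (dep$log_likelihood - indep$log_likelihood))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  structure(list(
    fits = fits,
    lr_statistic = lr,
    lr_df = 4L,
    lr_p_value = stats::pchisq(lr, df = 4, lower.tail = FALSE),
    best_model_by_aic = names(aic)[which.min(aic)],
    aic_table = data.frame(
      model = names(fits),
      n_free_params = vapply(fits, `[[`, integer(1), "n_free_params"),
      log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
      aic = aic, row.names = NULL)
  ), class = "pagel_test")
}

#' @export
print.pagel_test <- function(x, ...) {
  cat("Pagel's test for correlated evolution\n")
  print(transform(x$aic_table,
                  log_likelihood = round(log_likelihood, 4),
                  aic = round(aic, 4)))
  cat(sprintf("LR (dependent vs independent) = %.4f, chi-sq df = %d, p = %.4g\n",
              x$lr_statistic, x$lr_df, x$lr_p_value))
  cat("Best model by AIC:", x$best_model_by_aic, "\n")
  invisible(x)
}
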