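#' Phylogenetic generalized least squares with residual lambda
#'
#' Linear regression whose residual covariance follows the phylogeny scaled
#' by Pagel's lambda: `V = lambda_transform(C, lambda)`, with lambda either
#' fixed or estimated by profile maximum likelihood jointly with the
#' regression. This is the model-comparison engine behind the
#' dwelling-size analysis.
#'
#' @name pgls
NULL

# GLS fit at fixed V-cholesky pieces; returns beta, RSS (Mahalanobis), etc.
gls_fit_at <- function(d) {
  qrX <- qr(d$Xw)
  beta <- qr.coef(qrX, d$yw)
  resid <- d$yw - d$Xw %*% beta
  list(beta = beta, rss = sum(resid^2), qrX = qrX)
}

pgls_profile_loglik <- function(C, y, X, lambda) {
  n <- length(y)
  d <- gls_decompose(lambda_transform(C, lambda), y, X)
  f <- gls_fit_at(d)
  sigma2 <- f$rss / n
  ll <- -n / 2 * log(2 * pi) - n / 2 * log(sigma2) - d$logdet / 2 - n / 2
  list(loglik = ll, fit = f, decomp = d, sigma2 = sigma2)
}

#' Fit a PGLS regression
#'
#' Estimates `beta_hat = (X' V^-1 X)^-1 X' V^-1 y` with
#' `V = lambda_transform(C, lambda)`; when `lambda = "ML"` the profile
#' likelihood over lambda in `[0, 1]` is maximized (sigma^2 profiled
#' analytically, ties broken toward smaller lambda). The overall F-test
#' compares the regression against the intercept-only model under the same
#' `V(lambda_hat)`; R^2 is defined from the Mahalanobis deviances of the
#' two models under that same V, and
#' `R2_adj = 1 - (1 - R2) (n - 1) / (n - k_slopes - 1)`.
#' `AIC = -2 logL + 2 p` where p counts the regression coefficients,
#' sigma^2, and lambda when it was estimated.
#'
#' @param tree A valid `"phylo"` object.
#' @param data A data.frame with a `society_id` column (or row names)
#'   matching tip labels — e.g. the `$data` of [build_dataset()] — or a
#'   `"coded_dataset"`. Rows with missing model variables are dropped
#'   (complete-case analysis) and the tree pruned to match.
#' @param formula Model formula, e.g. `ahfa_log ~ pmr_ord + settlement`.
#'   Binary factors enter as 0/1 indicators of their second level
#'   (matrilocal / important / sedentary / durable / large = 1).
#' @param lambda `"ML"` (default) or a fixed number in `[0, 1]`.
#' @return An object of class `"pgls_fit"`.
#' @examples
#' study <- simulate_study(study_config(seed = 1))
#' cd <- build_dataset(study$records, study$tree)
#' pgls_fit(cd$tree, cd$data, ahfa_log ~ pmr_ord + settlement)
#' @export
pgls_fit <- function(tree, data, formula, lambda = "ML") {
  if (inherits(data, "coded_dataset")) {
    tree <- data$tree
    data <- data$data
  }
  validate_tree(tree)
  stopifnot(inherits(formula, "formula"))
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("variable(s) not in data: ", paste(miss, collapse = ", "))
  ids <- if ("society_id" %in% names(data)) as.character(data$society_id)
         else rownames(data)
  if (is.null(ids) || anyDuplicated(ids))
    stop("data must carry unique taxon ids (society_id column or row names)")

  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  keep <- intersect(tree$tip.label, ids[cc])
  if (length(keep) < 3L) stop("fewer than 3 complete-case taxa overlap the tree")
  tree <- prune_to_taxa(tree, keep)
  data <- data[match(tree$tip.label, ids), , drop = FALSE]

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  k <- ncol(X)
  if (qr(X)$rank < k) stop("rank-deficient design matrix")
  if (n <= k + 2L) stop("too few complete cases for the requested model")

  C <- phylo_vcv(tree)
  lambda_mode <- if (identical(lambda, "ML")) "ml" else "fixed"
  if (lambda_mode == "ml") {
    best <- maximize_unit_interval(function(l) pgls_profile_loglik(C, y, X, l)$loglik)
    lam_hat <- best$lambda
  } else {
    stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0, lambda <= 1)
    lam_hat <- lambda
  }
  pf <- pgls_profile_loglik(C, y, X, lam_hat)
  beta <- drop(pf$fit$beta)
  names(beta) <- colnames(X)

  # intercept-only deviance under the same V(lambda_hat) for F, R^2
  p0 <- pgls_profile_loglik(C, y, matrix(1, n, 1), lam_hat)
  rss <- pf$fit$rss
  rss0 <- p0$fit$rss
  k_slopes <- k - as.integer("(Intercept)" %in% colnames(X))
  if (k_slopes > 0) {
    fstat <- ((rss0 - rss) / k_slopes) / (rss / (n - k))
    f_p <- stats::pf(fstat, k_slopes, n - k, lower.tail = FALSE)
    r2 <- 1 - rss / rss0
    r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k_slopes - 1)
  } else {
    fstat <- NA_real_; f_p <- NA_real_; r2 <- 0; r2_adj <- 0
  }

  # coefficient table with unbiased residual variance, as in OLS practice
  XtVinvX_inv <- chol2inv(qr.R(pf$fit$qrX))
  se <- sqrt(diag(XtVinvX_inv) * rss / (n - k))
  tval <- beta / se
  coef_table <- data.frame(
    estimate = beta, std_error = se, t_value = tval,
    p_value = 2 * stats::pt(abs(tval), n - k, lower.tail = FALSE),
    row.names = names(beta)
  )

  n_par <- k + 1L + as.integer(lambda_mode == "ml")
  structure(list(
    formula = formula,
    coefficients = beta,
    coef_table = coef_table,
    lambda = lam_hat,
    lambda_mode = lambda_mode,
    sigma2 = pf$sigma2,
    log_likelihood = pf$loglik,
    aic = -2 * pf$loglik + 2 * n_par,
    n_par = n_par,
    r2 = r2,
    r2_adjusted = r2_adj,
    f_statistic = fstat,
    f_df = c(k_slopes, n - k),
    f_p_value = f_p,
    n = n,
    k = k
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, lambda = %.3f (%s), logL = %.3f, AIC = %.3f\n",
              x$n, x$lambda, x$lambda_mode, x$log_likelihood, x$aic))
  cat(sprintf("R2_adj = %.3f, F(%d, %d) p = %.4g\n",
              x$r2_adjusted, x$f_df[1], x$f_df[2], x$f_p_value))
  print(round(x$coef_table, 4))
  invisible(x)
}

#' Compare a set of PGLS models
#'
#' Fits each formula with residual lambda estimated by ML and tabulates
#' F-test p-value, adjusted R^2 and AIC, flagging the lowest-AIC model as
#' best. A formula whose fit fails yields a row with the error message;
#' the table is still returned. Complete-case n can differ between rows.
#'
#' @param tree A valid `"phylo"` object.
#' @param data As for [pgls_fit()].
#' @param formulas List of formulas (or character strings coercible to
#'   formulas).
#' @return A data.frame of class `"pgls_model_table"`, one row per model,
#'   ordered as given, with a `fits` attribute holding the `pgls_fit`
#'   objects.
#' @export
model_table <- function(tree, data, formulas) {
  stopifnot(length(formulas) >= 1)
  formulas <- lapply(formulas, stats::as.formula)
  fits <- lapply(formulas, function(f)
    tryCatch(pgls_fit(tree, data, f), error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  tab <- data.frame(
    model = vapply(formulas, function(f) paste(deparse(f), collapse = " "),
                   character(1)),
    n = NA_integer_, lambda = NA_real_, f_p_value = NA_real_,
    r2_adjusted = NA_real_, aic = NA_real_, best = FALSE,
    error = NA_character_, stringsAsFactors = FALSE
  )
  for (i in seq_along(fits)) {
    if (ok[i]) {
      f <- fits[[i]]
      tab$n[i] <- f$n; tab$lambda[i] <- f$lambda
      tab$f_p_value[i] <- f$f_p_value
      tab$r2_adjusted[i] <- f$r2_adjusted; tab$aic[i] <- f$aic
    } else {
      tab$error[i] <- conditionMessage(fits[[i]])
    }
  }
  if (any(ok)) tab$best[which.min(replace(tab$aic, !ok, Inf))] <- TRUE
  structure(tab, fits = fits, class = c("pgls_model_table", "data.frame"))
}
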