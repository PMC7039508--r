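#' Default model-comparison formulas
#'
#' The ten regressions of the dwelling-size model table: single predictors
#' in ordinal and binary codings, then settlement-anchored combinations.
#'
#' @return List of formulas.
#' @export
default_model_formulas <- function() {
  list(
    ahfa_log ~ pmr_ord,
    ahfa_log ~ pmr_bin,
    ahfa_log ~ agriculture,
    ahfa_log ~ agriculture_ord,
    ahfa_log ~ settlement,
    ahfa_log ~ material,
    ahfa_log ~ pmr_ord + settlement,
    ahfa_log ~ pmr_ord + settlement + agriculture,
    ahfa_log ~ pmr_ord + settlement + material,
    ahfa_log ~ pmr_ord + agriculture + settlement + material
  )
}

run_stage <- function(name, expr, errors) {
  r <- tryCatch(expr, error = function(e) e)
  if (inherits(r, "error")) {
    errors[[name]] <- conditionMessage(r)
    list(value = NULL, errors = errors)
  } else list(value = r, errors = errors)
}

# signal table rows: lambda for the two multistate traits, D for the three
# binaries, each on that variable's complete cases
signal_table <- function(tree, data, seed, n_null = 1000) {
  rows <- list(
    list(var = "ahfa_log", stat = "lambda"),
    list(var = "pmr_ord", stat = "lambda"),
    list(var = "agriculture", stat = "D"),
    list(var = "settlement", stat = "D"),
    list(var = "material", stat = "D")
  )
  out <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    v <- data[[r$var]]
    names(v) <- data$society_id
    v <- v[!is.na(v)]
    res <- tryCatch({
      tr <- if (length(v) < nrow(data)) prune_to_taxa(tree, names(v)) else tree
      if (r$stat == "lambda") {
        s <- pagel_lambda(tr, as.numeric(v))
        data.frame(variable = r$var, statistic = "lambda",
                   estimate = s$estimate, p_value = s$p_value,
                   p_brownian = NA_real_, n = s$n_taxa,
                   error = NA_character_)
      } else {
        s <- fritz_purvis_d(tr, binary_as_01(v), n_permutations = n_null,
                            n_simulations = n_null, seed = seed + i)
        data.frame(variable = r$var, statistic = "D",
                   estimate = s$estimate, p_value = s$p_value,
                   p_brownian = s$p_brownian, n = s$n_taxa,
                   error = NA_character_)
      }
    }, error = function(e)
      data.frame(variable = r$var, statistic = r$stat, estimate = NA_real_,
                 p_value = NA_real_, p_brownian = NA_real_, n = length(v),
                 error = conditionMessage(e)))
    res
  })
  do.call(rbind, out)
}

asr_export <- function(tree, data, trait, n_points = 10) {
  v <- stats::setNames(as.numeric(data[[trait]]), data$society_id)
  v <- v[!is.na(v)]
  tr <- if (length(v) < nrow(data)) prune_to_taxa(tree, names(v)) else tree
  rec <- ml_ancestral_continuous(tr, v)
  nodes <- data.frame(node = as.integer(names(rec$node_estimates)),
                      estimate = unname(rec$node_estimates),
                      variance = unname(rec$node_variances))
  out <- list(trait = trait, n = length(v),
              root_estimate = rec$root_estimate,
              sigma2 = rec$sigma2, nodes = nodes,
              gradient = branch_gradient(tr, rec, v, n_points))
  if (trait == "ahfa_log") out$root_estimate_m2 <- exp(rec$root_estimate)
  out
}

#' Run the full comparative analysis
#'
#' End-to-end pipeline: recode the raw society table against the tree,
#' compute the phylogenetic-signal table (lambda for log house area and
#' the residence ordinal; D for agriculture, settlement and material), fit
#' the PGLS model-comparison table, reconstruct ancestral states of log
#' house area (reported on both log and m^2 scales) and of the residence
#' ordinal, and run Pagel's correlated-evolution test on the binary house
#' size x residence pair. A failing stage is recorded in `$errors` and the
#' remaining stages still run. The run is deterministic given `seed`.
#'
#' @param tree A rooted `"phylo"` (or path to a Newick file).
#' @param records Raw society data.frame (or path to its CSV); columns as
#'   in [build_dataset()].
#' @param seed Integer seed for all stochastic components.
#' @param formulas Model formulas (default [default_model_formulas()]).
#' @param n_null Null replicates for each D statistic.
#' @param n_restarts Optimization restarts for the coevolution fits.
#' @param out_dir Optional directory; when given, the bundle is written as
#'   `bundle.json` plus CSV sidecars for the tables.
#' @return A list of class `"analysis_bundle"`: `coded`, `signal_table`,
#'   `model_table`, `asr` (per trait), `coevolution`, `errors`,
#'   `provenance`.
#' @export
run_all <- function(tree, records, seed = 1,
                    formulas = default_model_formulas(),
                    n_null = 1000, n_restarts = 10, out_dir = NULL) {
  if (is.character(tree)) tree <- parse_newick(tree, file = TRUE)
  if (is.character(records))
    records <- utils::read.csv(records, stringsAsFactors = FALSE)
  errors <- list()
  cd <- build_dataset(records, tree)
  data <- cd$data
  tr <- cd$tree

  s <- run_stage("signal", signal_table(tr, data, seed, n_null), errors)
  errors <- s$errors
  m <- run_stage("models", model_table(tr, data, formulas), errors)
  errors <- m$errors
  a1 <- run_stage("asr_ahfa", asr_export(tr, data, "ahfa_log"), errors)
  errors <- a1$errors
  a2 <- run_stage("asr_pmr", asr_export(tr, data, "pmr_ord"), errors)
  errors <- a2$errors
  co <- run_stage("coevolution", {
    x <- binary_as_01(data$ahfa_bin)
    y <- binary_as_01(data$pmr_bin)
    names(x) <- names(y) <- data$society_id
    pagel_test(tr, x, y, n_restarts = n_restarts, seed = seed + 100L)
  }, errors)
  errors <- co$errors

  bundle <- structure(list(
    coded = cd,
    signal_table = s$value,
    model_table = m$value,
    asr = list(ahfa_log = a1$value, pmr_ord = a2$value),
    coevolution = co$value,
    errors = errors,
    provenance = list(
      package_version = as.character(utils::packageVersion("phylodwell")),
      seed = seed,
      n_taxa = nrow(data),
      tree_md5 = input_md5(write_newick(tr)),
      data_md5 = input_md5(paste(utils::capture.output(
        utils::write.csv(records, stdout(), row.names = FALSE)),
        collapse = "\n")),
      conventions = list(
        log_base = "natural",
        ahfa_cutoff_m2 = 65,
        aic_parameters = "slopes + intercept + sigma2 + lambda (when ML)",
        coevolution_root_prior = "flat",
        d_nulls = n_null
      )
    )
  ), class = "analysis_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

input_md5 <- function(text) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(text, f)
  unname(tools::md5sum(f))
}

#' Write an analysis bundle to disk
#'
#' `bundle.json` carries everything except the coded dataset's tree;
#' `signal.csv`, `models.csv`, `coded.csv` and per-trait `asr_*.csv` files
#' are flat sidecars. Output is deterministic (no timestamps).
#'
#' @param bundle An `"analysis_bundle"`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  co <- bundle$coevolution
  j <- list(
    provenance = bundle$provenance,
    signal = bundle$signal_table,
    models = as.data.frame(bundle$model_table),
    asr = lapply(bundle$asr, function(a)
      a[c("trait", "n", "root_estimate", "sigma2",
          intersect("root_estimate_m2", names(a)))]),
    coevolution = if (!is.null(co)) list(
      lr_statistic = co$lr_statistic, lr_df = co$lr_df,
      lr_p_value = co$lr_p_value, best_model_by_aic = co$best_model_by_aic,
      aic_table = co$aic_table,
      rate_matrices = lapply(co$fits, function(f) unclass(f$q))),
    errors = bundle$errors
  )
  jsonlite::write_json(j, file.path(out_dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(bundle$signal_table, file.path(out_dir, "signal.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$model_table),
                   file.path(out_dir, "models.csv"), row.names = FALSE)
  utils::write.csv(bundle$coded$data, file.path(out_dir, "coded.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$asr)) {
    a <- bundle$asr[[nm]]
    if (!is.null(a))
      utils::write.csv(a$nodes, file.path(out_dir, paste0("asr_", nm, ".csv")),
                       row.names = FALSE)
  }
  writeLines(bundle$coded$log, file.path(out_dir, "reconciliation.log"))
  invisible(out_dir)
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("Dwelling-size comparative analysis:", x$provenance$n_taxa, "societies\n\n")
  cat("Phylogenetic signal:\n")
  print(transform(x$signal_table, estimate = round(estimate, 3),
                  p_value = round(p_value, 4))[, 1:5])
  cat("\nModel comparison (best by AIC flagged):\n")
  print(as.data.frame(x$model_table)[, c("model", "n", "f_p_value",
                                         "r2_adjusted", "aic", "best")])
  if (!is.null(x$asr$ahfa_log))
    cat(sprintf("\nRoot house area: %.2f log-m2 = %.1f m2\n",
                x$asr$ahfa_log$root_estimate, x$asr$ahfa_log$root_estimate_m2))
  if (!is.null(x$asr$pmr_ord))
    cat(sprintf("Root residence ordinal: %.2f (0 = patrilocal, 4 = matrilocal)\n",
                x$asr$pmr_ord$root_estimate))
  if (!is.null(x$coevolution))
    cat(sprintf("\nCorrelated evolution: LR = %.3f, p = %.4g, best model: %s\n",
                x$coevolution$lr_statistic, x$coevolution$lr_p_value,
                x$coevolution$best_model_by_aic))
  if (length(x$errors)) {
    cat("\nStage errors:\n")
    for (nm in names(x$errors)) cat(" -", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}
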