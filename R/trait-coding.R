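#' Trait recoding for the dwelling-size analysis
#'
#' The analysis variables are derived from average house floor area (AHFA,
#' in m^2) and five Ethnographic-Atlas-style categorical codes:
#' EA012 (marital residence with kin), EA028 (agriculture intensity),
#' EA030 (settlement pattern), EA081 (wall material) and EA083 (roofing
#' material, used only when walls are indistinguishable from the roof).
#' Every map is total on its documented range and errors on anything else;
#' there is no silent coercion.
#'
#' @name trait_coding
NULL

.check_codes <- function(x, range, name, allow_na = FALSE) {
  if (allow_na && all(is.na(x))) return(invisible(x))
  bad <- !is.na(x) & (!is.finite(x) | x != round(x) | x < range[1] | x > range[2])
  if (any(bad))
    stop(sprintf("%s code(s) out of range %d..%d: %s", name,
                 range[1], range[2], paste(unique(x[bad]), collapse = ", ")))
  if (!allow_na && anyNA(x)) stop(sprintf("missing %s code(s)", name))
  invisible(x)
}

#' Code average house floor area
#'
#' Natural-log transform plus dichotomization at 65 m^2: areas below 65 m^2
#' are "small", areas of 65 m^2 and above are "large".
#'
#' @param ahfa_m2 Positive numeric vector of house floor areas in m^2.
#' @return A data.frame with columns `ahfa_log` (natural log of the area)
#'   and `ahfa_bin` (factor, levels `small` < `large`).
#' @examples
#' code_ahfa(c(12, 64, 65, 200))
#' @export
code_ahfa <- function(ahfa_m2) {
  if (any(!is.finite(ahfa_m2) | ahfa_m2 <= 0))
    stop("ahfa_m2 must be positive and finite")
  data.frame(
    ahfa_log = log(ahfa_m2),
    ahfa_bin = factor(ifelse(ahfa_m2 < 65, "small", "large"),
                      levels = c("small", "large"))
  )
}

#' Code post-marital residence (EA012)
#'
#' Reduces the 12-category residence code to a five-state ordinal scale of
#' tendency towards matrilocality (0 = patri/virilocal ... 4 = matri/
#' uxorilocal) and a binary matrilocal / non-matrilocal trait (matrilocal
#' when the original code is 5, 9 or 11).
#'
#' @param ea012 Integer vector of codes 1..12.
#' @return A data.frame with columns `pmr_ord` (integer 0..4) and `pmr_bin`
#'   (factor, levels `non-matrilocal`, `matrilocal`).
#' @examples
#' code_pmr(c(5, 8, 11))
#' @export
code_pmr <- function(ea012) {
  .check_codes(ea012, c(1L, 12L), "EA012")
  ord_map <- c(`1` = 0L, `2` = 2L, `3` = 2L, `4` = 0L, `5` = 4L, `6` = 2L,
               `7` = 2L, `8` = 0L, `9` = 4L, `10` = 0L, `11` = 3L, `12` = 1L)
  pmr_ord <- unname(ord_map[as.character(ea012)])
  pmr_bin <- factor(ifelse(ea012 %in% c(5L, 9L, 11L),
                           "matrilocal", "non-matrilocal"),
                    levels = c("non-matrilocal", "matrilocal"))
  data.frame(pmr_ord = pmr_ord, pmr_bin = pmr_bin)
}

#' Code agriculture intensity (EA028)
#'
#' Codes 1-2 (no or casual agriculture) become "not_important"; 3-6
#' (extensive/shifting through intensive irrigated) become "important".
#'
#' @param ea028 Integer vector of codes 1..6.
#' @return Factor with levels `not_important`, `important`.
#' @export
code_agriculture <- function(ea028) {
  .check_codes(ea028, c(1L, 6L), "EA028")
  factor(ifelse(ea028 <= 2L, "not_important", "important"),
         levels = c("not_important", "important"))
}

#' Code settlement pattern (EA030)
#'
#' Codes 1-2 (nomadic or seminomadic) become "mobile"; 3-8 (semisedentary
#' communities through complex settlements) become "sedentary".
#'
#' @param ea030 Integer vector of codes 1..8.
#' @return Factor with levels `mobile`, `sedentary`.
#' @export
code_settlement <- function(ea030) {
  .check_codes(ea030, c(1L, 8L), "EA030")
  factor(ifelse(ea030 <= 2L, "mobile", "sedentary"),
         levels = c("mobile", "sedentary"))
}

#' Code house construction material (EA081, with EA083 fallback)
#'
#' Wall materials 1 (stone/stucco/brick), 3 (wood/bamboo) and 9 (adobe/clay/
#' brick) are "durable"; 2, 4, 5, 6, 7, 8 and 10 are "impermanent". When
#' EA081 is 11 (walls indistinguishable from the roof) the roofing material
#' decides: EA083 code 9 (earth or turf) is durable, 10 (ice or snow) is
#' impermanent. Anything unresolvable is an error.
#'
#' @param ea081 Integer vector of codes 1..11, `NA` allowed only when the
#'   row is dropped upstream.
#' @param ea083 Integer vector of roofing codes; consulted only where
#'   `ea081 == 11`, and then required to be 9 or 10.
#' @return Factor with levels `impermanent`, `durable`.
#' @examples
#' code_material(c(1, 5, 11), c(NA, NA, 9))
#' @export
code_material <- function(ea081, ea083 = rep(NA_integer_, length(ea081))) {
  if (length(ea083) != length(ea081)) stop("ea081 and ea083 lengths differ")
  if (anyNA(ea081)) stop("missing EA081 code(s)")
  .check_codes(ea081, c(1L, 11L), "EA081")
  out <- character(length(ea081))
  durable81 <- c(1L, 3L, 9L)
  imperm81 <- c(2L, 4L, 5L, 6L, 7L, 8L, 10L)
  out[ea081 %in% durable81] <- "durable"
  out[ea081 %in% imperm81] <- "impermanent"
  fb <- which(ea081 == 11L)
  if (length(fb)) {
    e83 <- ea083[fb]
    if (anyNA(e83) || any(!e83 %in% c(9L, 10L)))
      stop("EA081 = 11 requires EA083 in {9, 10} to score material")
    out[fb] <- ifelse(e83 == 9L, "durable", "impermanent")
  }
  factor(out, levels = c("impermanent", "durable"))
}

#' Build the coded analysis dataset aligned to a phylogeny
#'
#' Inner-joins raw society records to the tree tips, recodes every analysis
#' variable, prunes the tree to the matched taxa, orders dataset rows as the
#' pruned tree's tips, and reports unmatched records/tips in a
#' reconciliation log.
#'
#' @param records A data.frame with columns `society_id`, `ahfa_m2`,
#'   `ea012`, `ea028`, `ea030`, `ea081`, `ea083` (the last two may contain
#'   `NA`; such rows are kept, with `material = NA`, and dropped from
#'   analyses that use material).
#' @param tree A valid `"phylo"` whose tip labels are society ids.
#' @return A list of class `"coded_dataset"` with elements `data` (the
#'   coded data.frame, one row per matched taxon, in tip order), `tree`
#'   (pruned tree) and `log` (character vector describing the
#'   reconciliation).
#' @export
build_dataset <- function(records, tree) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  need <- c("society_id", "ahfa_m2", "ea012", "ea028", "ea030")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (!"ea081" %in% names(records)) records$ea081 <- NA_integer_
  if (!"ea083" %in% names(records)) records$ea083 <- NA_integer_
  if (anyDuplicated(records$society_id)) stop("duplicate society_id values")
  validate_tree(tree)

  matched <- intersect(tree$tip.label, records$society_id)
  if (length(matched) < 3L) stop("fewer than 3 taxa match between records and tree")
  drop_rec <- setdiff(records$society_id, matched)
  drop_tip <- setdiff(tree$tip.label, matched)
  log <- c(
    sprintf("%d records, %d tree tips, %d matched taxa",
            nrow(records), length(tree$tip.label), length(matched)),
    if (length(drop_rec))
      sprintf("records without tree tip (excluded): %s",
              paste(sort(drop_rec), collapse = ", ")),
    if (length(drop_tip))
      sprintf("tree tips without record (pruned): %s",
              paste(sort(drop_tip), collapse = ", "))
  )

  tree2 <- if (length(drop_tip)) prune_to_taxa(tree, matched) else tree
  rec <- records[match(tree2$tip.label, records$society_id), , drop = FALSE]

  ahfa <- code_ahfa(rec$ahfa_m2)
  pmr <- code_pmr(rec$ea012)
  material <- rep(factor(NA, levels = c("impermanent", "durable")), nrow(rec))
  scorable <- !is.na(rec$ea081)
  if (any(scorable))
    material[scorable] <- code_material(rec$ea081[scorable], rec$ea083[scorable])
  if (any(!scorable))
    log <- c(log, sprintf("material unscorable (EA081 missing) for: %s",
                          paste(rec$society_id[!scorable], collapse = ", ")))

  data <- data.frame(
    society_id = rec$society_id,
    ahfa_m2 = rec$ahfa_m2,
    ahfa_log = ahfa$ahfa_log,
    ahfa_bin = ahfa$ahfa_bin,
    pmr_ord = pmr$pmr_ord,
    pmr_bin = pmr$pmr_bin,
    agriculture = code_agriculture(rec$ea028),
    agriculture_ord = as.integer(rec$ea028),
    settlement = code_settlement(rec$ea030),
    material = material,
    row.names = NULL
  )
  structure(list(data = data, tree = tree2, log = log),
            class = "coded_dataset")
}

#' @export
print.coded_dataset <- function(x, ...) {
  cat("Coded dataset:", nrow(x$data), "societies aligned to a",
      length(x$tree$tip.label), "tip tree\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

# 0/1 numeric view of the binary analysis variables, coded so that
# large / matrilocal / important / sedentary / durable = 1.
binary_as_01 <- function(f) {
  stopifnot(is.factor(f), nlevels(f) == 2L)
  as.integer(f) - 1L
}
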