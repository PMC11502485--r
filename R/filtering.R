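#' Variance explained by a single variant
#'
#' Standard summary-statistic approximation for the phenotypic variance a
#' variant explains: `r2 = z^2 / (z^2 + n - 2)` with `z = beta/se`.
#' Strictly increasing in `|z|` at fixed `n` and always in `[0, 1)`.
#'
#' @param beta,se Association effect and standard error (`se > 0`).
#' @param n Study sample size (`> 2`).
#' @return The variance explained, vectorized over the inputs.
#' @export
variance_explained <- function(beta, se, n) {
  if (any(!is.na(n) & n <= 2)) stopf("variance_explained requires n > 2")
  if (any(!is.na(se) & se <= 0)) stopf("variance_explained requires se > 0")
  z2 <- (beta / se)^2
  z2 / (z2 + n - 2)
}

#' Steiger directionality filter
#'
#' Guards against reverse causation: an instrument that explains more
#' variance in the outcome than in the exposure is more plausibly a
#' primary outcome variant, and is removed. The default rule compares the
#' point estimates `r2_exposure > r2_outcome` directly (no significance
#' gate), giving a deterministic keep/remove decision per variant.
#'
#' @param set A `harmonized_set` or records tibble with `beta_x`, `se_x`,
#'   `n_x`, `beta_y`, `se_y`, `n_y`.
#' @param on_missing_n `"drop"` (default) removes records lacking a sample
#'   size with reason `"steiger-no-n"`; `"keep"` retains them unfiltered.
#' @return List with `kept` (a `harmonized_set`) and `results` (tibble of
#'   per-variant `r2_exposure`, `r2_outcome`, `kept`, `reason`).
#' @export
steiger_filter <- function(set, on_missing_n = c("drop", "keep")) {
  on_missing_n <- match.arg(on_missing_n)
  records <- as_harmonized_records(set)
  no_n <- is.na(records$n_x) | is.na(records$n_y)
  r2x <- rep(NA_real_, nrow(records))
  r2y <- rep(NA_real_, nrow(records))
  ok <- !no_n
  r2x[ok] <- variance_explained(records$beta_x[ok], records$se_x[ok],
                                records$n_x[ok])
  r2y[ok] <- variance_explained(records$beta_y[ok], records$se_y[ok],
                                records$n_y[ok])
  kept <- ifelse(no_n, on_missing_n == "keep", r2x > r2y)
  reason <- rep(NA_character_, nrow(records))
  reason[!kept & no_n] <- "steiger-no-n"
  reason[!kept & !no_n] <- "steiger-reverse"
  results <- tibble::tibble(
    variant_id = records$variant_id,
    r2_exposure = r2x, r2_outcome = r2y,
    kept = kept, reason = reason
  )
  prov <- if (inherits(set, "harmonized_set")) set$provenance else NULL
  list(
    kept = new_harmonized_set(records[kept, , drop = FALSE], prov),
    results = results
  )
}

#' Stratify instruments by the sign of the indicator-trait effect
#'
#' The biological-effect filter: exposure-increasing alleles are split by
#' the direction of their effect on a downstream indicator trait that
#' indexes the biomarker's established action (e.g. glucose for insulin:
#' an insulin-raising allele that also raises glucose marks insulin
#' *resistance*, one that lowers glucose marks insulin *bioaction*).
#' Records must already be oriented to the exposure-increasing allele.
#' Variants with a missing indicator association or an exactly zero
#' `beta_z` carry no direction and fall in the unclassified stratum; the
#' three strata always partition the input.
#'
#' @param set A `harmonized_set` or records tibble (oriented).
#' @param labels Named character vector giving biological names to the
#'   sign strata, e.g. `c(positive = "resistance", negative = "bioaction")`
#'   for insulin/glucose.
#' @return A `stratified_groups` list: `positive`, `negative`,
#'   `unclassified` record tibbles, `sizes`, and `labels`.
#' @export
stratify_by_indicator <- function(set,
                                  labels = c(positive = "indicator-positive",
                                             negative = "indicator-negative")) {
  records <- as_harmonized_records(set)
  stopifnot(all(c("positive", "negative") %in% names(labels)))
  sign_z <- ifelse(is.na(records$beta_z), 0, sign(records$beta_z))
  groups <- structure(
    list(
      positive = records[sign_z > 0, , drop = FALSE],
      negative = records[sign_z < 0, , drop = FALSE],
      unclassified = records[sign_z == 0, , drop = FALSE],
      sizes = c(positive = sum(sign_z > 0), negative = sum(sign_z < 0),
                unclassified = sum(sign_z == 0)),
      labels = labels
    ),
    class = "stratified_groups"
  )
  stopifnot(sum(groups$sizes) == nrow(records))
  groups
}

#' @export
print.stratified_groups <- function(x, ...) {
  cat(sprintf(
    "<stratified_groups> %d %s (+), %d %s (-), %d unclassified\n",
    x$sizes[["positive"]], x$labels[["positive"]],
    x$sizes[["negative"]], x$labels[["negative"]],
    x$sizes[["unclassified"]]))
  invisible(x)
}
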