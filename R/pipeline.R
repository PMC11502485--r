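#' Family-wise significance threshold
#'
#' Bonferroni threshold over the exposure-outcome family:
#' `alpha / (n_exposures * n_outcomes)`. With `alpha = 0.05` and two
#' exposures against two outcomes this gives 0.0125.
#'
#' @param alpha Nominal level in (0,1) (default 0.05).
#' @param n_exposures,n_outcomes Family dimensions (each `>= 1`).
#' @return The corrected threshold.
#' @export
multiple_testing_threshold <- function(alpha = 0.05, n_exposures = 1L,
                                       n_outcomes = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stopf("alpha must be in (0,1)")
  }
  if (n_exposures < 1 || n_outcomes < 1) {
    stopf("n_exposures and n_outcomes must be >= 1")
  }
  alpha / (n_exposures * n_outcomes)
}

#' Egger-intercept validity rule for the IVW model
#'
#' A significant MR-Egger intercept (two-sided p strictly below
#' `alpha`) indicates directional pleiotropy, under which the IVW
#' estimate is considered invalid. When Egger itself was refused (fewer
#' than 3 instruments) the flag is `"egger-unavailable"` and IVW is not
#' auto-invalidated.
#'
#' @param estimates A per-method estimate tibble (as from [mr_all()]).
#' @param alpha Intercept significance level (default 0.05, strict `<`).
#' @return List with `ivw_invalid` (logical) and `flag`
#'   (`"ok"`, `"egger-intercept"` or `"egger-unavailable"`).
#' @export
apply_validity_rule <- function(estimates, alpha = 0.05) {
  egger <- estimates[estimates$method == "Egger", , drop = FALSE]
  if (nrow(egger) == 0 || is.na(egger$intercept_pval[1])) {
    return(list(ivw_invalid = FALSE, flag = "egger-unavailable"))
  }
  invalid <- egger$intercept_pval[1] < alpha
  list(ivw_invalid = invalid,
       flag = if (invalid) "egger-intercept" else "ok")
}

#' Plot-ready pleiotropy diagnostics
#'
#' Computes the two diagnostic datasets without rendering anything. The
#' funnel dataset has one row per kept instrument (`ratio`,
#' `precision = 1/ratio_se`) with vertical reference lines at each
#' method's estimate — asymmetry suggests directional pleiotropy. The
#' dosage dataset is the per-variant SNP-exposure versus SNP-outcome
#' scatter (`beta_x`, `beta_y`, `se_y`) with each method's fitted line
#' (through the origin except Egger).
#'
#' @param set A `harmonized_set` or records tibble (post-filtering).
#' @param estimates Per-method estimate tibble for the same set.
#' @return List with `funnel`, `funnel_refs`, `dosage`, `dosage_lines`,
#'   and `empty` flag.
#' @export
diagnostic_plot_data <- function(set, estimates) {
  records <- as_harmonized_records(set)
  est <- estimates[!is.na(estimates$beta), , drop = FALSE]
  if (nrow(records) == 0) {
    return(list(
      funnel = tibble::tibble(variant_id = character(), ratio = numeric(),
                              precision = numeric()),
      funnel_refs = tibble::tibble(method = character(), beta = numeric()),
      dosage = tibble::tibble(variant_id = character(), beta_x = numeric(),
                              beta_y = numeric(), se_y = numeric()),
      dosage_lines = tibble::tibble(method = character(), slope = numeric(),
                                    intercept = numeric()),
      empty = TRUE
    ))
  }
  rat <- ratio_estimates(records)
  list(
    funnel = tibble::tibble(variant_id = rat$variant_id, ratio = rat$ratio,
                            precision = 1 / rat$ratio_se),
    funnel_refs = tibble::tibble(method = est$method, beta = est$beta),
    dosage = tibble::tibble(variant_id = records$variant_id,
                            beta_x = records$beta_x, beta_y = records$beta_y,
                            se_y = records$se_y),
    dosage_lines = tibble::tibble(
      method = est$method, slope = est$beta,
      intercept = ifelse(is.na(est$intercept), 0, est$intercept)
    ),
    empty = FALSE
  )
}

#' Configuration for a full stratified MR analysis
#'
#' @param exposure,indicator,outcome [sumstats] tables or TSV paths.
#' @param ld An `ld_reference`, a length-2 character vector
#'   `c(pairs, positions)` of TSV paths, or `NULL` (no proxying).
#' @param p_threshold Instrument p-value threshold (default 5e-8, strict).
#' @param r2_min,max_dist LD-proxy rule (defaults 0.7 and 1e6 bp).
#' @param palindrome_window See [align_alleles()].
#' @param steiger Apply Steiger filtering before stratification
#'   (default `TRUE`).
#' @param random_effects Random-effects IVW (default `TRUE`).
#' @param n_boot,penalty_k Weighted-median settings.
#' @param alpha Nominal level; also the Egger-intercept validity level.
#' @param n_exposures,n_outcomes Family size for the Bonferroni threshold.
#' @param labels Stratum labels, e.g.
#'   `c(positive = "resistance", negative = "bioaction")`.
#' @param seed Seed for estimator bootstraps.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(exposure, indicator, outcome, ld = NULL,
                            p_threshold = 5e-8, r2_min = 0.7,
                            max_dist = 1e6, palindrome_window = 0.08,
                            steiger = TRUE, random_effects = TRUE,
                            n_boot = 1000, penalty_k = 20, alpha = 0.05,
                            n_exposures = 1L, n_outcomes = 1L,
                            labels = c(positive = "indicator-positive",
                                       negative = "indicator-negative"),
                            seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold < 1, r2_min >= 0, r2_min <= 1,
            max_dist > 0, alpha > 0, alpha < 1, n_boot >= 100)
  structure(list(
    exposure = exposure, indicator = indicator, outcome = outcome, ld = ld,
    p_threshold = p_threshold, r2_min = r2_min, max_dist = max_dist,
    palindrome_window = palindrome_window, steiger = steiger,
    random_effects = random_effects, n_boot = n_boot,
    penalty_k = penalty_k, alpha = alpha,
    n_exposures = as.integer(n_exposures),
    n_outcomes = as.integer(n_outcomes),
    labels = labels, seed = as.integer(seed)
  ), class = "analysis_config")
}

load_input <- function(x, what) {
  if (inherits(x, "sumstats") || is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    return(read_sumstats(x, trait_name = what))
  }
  stopf("%s must be a sumstats table or a TSV path", what)
}

load_ld <- function(x) {
  if (is.null(x) || inherits(x, "ld_reference")) return(x)
  if (is.character(x) && length(x) == 2) {
    return(read_ld_reference(x[1], x[2]))
  }
  stopf("ld must be NULL, an ld_reference, or c(pairs_path, positions_path)")
}

#' Run the full stratified two-sample MR analysis
#'
#' Executes the end-to-end chain: instrument selection, LD-proxy
#' substitution, allele alignment and orientation, Steiger filtering,
#' sign stratification on the indicator trait, and all four causal
#' estimators with heterogeneity and Egger-intercept diagnostics, for the
#' unstratified instrument set and each stratum. Deterministic given the
#' config (including its seed); empty instrument sets produce structured
#' `"no-instruments"` rows, never an error.
#'
#' @param config An [analysis_config()].
#' @return An `mr_report` list: `estimates` (stratum x method tibble with
#'   validity and significance flags), `counts`, `strata_sizes`,
#'   `steiger`, `provenance`, `plots` (per-stratum diagnostic datasets),
#'   `threshold`, `labels`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  exposure <- load_input(config$exposure, "exposure")
  indicator <- load_input(config$indicator, "indicator")
  outcome <- load_input(config$outcome, "outcome")
  ld <- load_ld(config$ld)

  set <- build_instrument_set(
    exposure, indicator, outcome, ld = ld,
    p_threshold = config$p_threshold, r2_min = config$r2_min,
    max_dist = config$max_dist,
    palindrome_window = config$palindrome_window
  )
  n_selected <- nrow(set$provenance)
  n_harmonized <- nrow(set$records)

  if (config$steiger) {
    st <- steiger_filter(set)
    steiger_results <- st$results
    kept <- st$kept
  } else {
    steiger_results <- tibble::tibble()
    kept <- set
  }
  n_post_steiger <- nrow(kept$records)

  strata <- stratify_by_indicator(kept, labels = config$labels)
  threshold <- multiple_testing_threshold(config$alpha, config$n_exposures,
                                          config$n_outcomes)

  sets <- list(
    all = kept$records,
    positive = strata$positive,
    negative = strata$negative,
    unclassified = strata$unclassified
  )
  stratum_label <- c(
    all = "all", positive = unname(config$labels[["positive"]]),
    negative = unname(config$labels[["negative"]]),
    unclassified = "unclassified"
  )

  estimates <- list()
  plots <- list()
  for (i in seq_along(sets)) {
    name <- names(sets)[i]
    est <- mr_all(sets[[i]], random_effects = config$random_effects,
                  n_boot = config$n_boot,
                  seed = config$seed + 101L * i, penalty_k = config$penalty_k)
    validity <- apply_validity_rule(est, alpha = config$alpha)
    est$stratum <- name
    est$stratum_label <- stratum_label[[name]]
    est$ivw_invalid <- validity$ivw_invalid & est$method == "IVW"
    est$validity_flag <- validity$flag
    est$significant <- !is.na(est$pval) & est$pval < threshold &
      !est$ivw_invalid
    estimates[[name]] <- est
    plots[[name]] <- diagnostic_plot_data(sets[[i]], est)
  }
  estimates <- dplyr::bind_rows(estimates)
  estimates <- estimates[, c("stratum", "stratum_label", "method", "n_snps",
                             "beta", "se", "pval", "Q", "Q_pval", "I2",
                             "intercept", "intercept_se", "intercept_pval",
                             "ivw_invalid", "validity_flag", "significant",
                             "note")]

  structure(list(
    estimates = estimates,
    counts = c(
      selected = n_selected,
      kept = n_harmonized,
      dropped = n_selected - n_harmonized,
      steiger_removed = n_harmonized - n_post_steiger,
      post_steiger = n_post_steiger
    ),
    strata_sizes = strata$sizes,
    steiger = steiger_results,
    provenance = set$provenance,
    plots = plots,
    threshold = threshold,
    labels = config$labels,
    config = config
  ), class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("<mr_report>\n")
  cat(sprintf(
    "  instruments: %d selected, %d harmonized, %d after Steiger\n",
    x$counts[["selected"]], x$counts[["kept"]], x$counts[["post_steiger"]]))
  cat(sprintf(
    "  strata: %d %s (+), %d %s (-), %d unclassified\n",
    x$strata_sizes[["positive"]], x$labels[["positive"]],
    x$strata_sizes[["negative"]], x$labels[["negative"]],
    x$strata_sizes[["unclassified"]]))
  cat(sprintf("  significance threshold: %g\n", x$threshold))
  ivw <- x$estimates[x$estimates$method == "IVW" &
                       !is.na(x$estimates$beta), , drop = FALSE]
  for (i in seq_len(nrow(ivw))) {
    cat(sprintf("  IVW [%s]: beta = %.4f (se %.4f), p = %.3g%s\n",
                ivw$stratum_label[i], ivw$beta[i], ivw$se[i], ivw$pval[i],
                if (ivw$ivw_invalid[i]) " [invalid: Egger intercept]" else ""))
  }
  invisible(x)
}

#' Write an analysis report to TSV files
#'
#' Serializes the estimate table, provenance, Steiger decisions, stratum
#' sizes and the funnel/dosage diagnostic datasets as plain TSV, giving a
#' byte-stable on-disk report for a deterministic config.
#'
#' @param report An `mr_report`.
#' @param dir Output directory (created if absent).
#' @return Named vector of file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) {
    utils::write.table(as.data.frame(df), file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    file.path(dir, file)
  }
  paths <- c(
    estimates = wt(report$estimates, "estimates.tsv"),
    provenance = wt(report$provenance, "provenance.tsv"),
    strata = wt(
      tibble::tibble(stratum = names(report$strata_sizes),
                     n = as.integer(report$strata_sizes)),
      "strata.tsv")
  )
  if (nrow(report$steiger) > 0) {
    paths["steiger"] <- wt(report$steiger, "steiger.tsv")
  }
  funnels <- lapply(names(report$plots), function(nm) {
    f <- report$plots[[nm]]$funnel
    if (nrow(f) > 0) f$stratum <- nm
    f
  })
  dosages <- lapply(names(report$plots), function(nm) {
    d <- report$plots[[nm]]$dosage
    if (nrow(d) > 0) d$stratum <- nm
    d
  })
  paths["funnel"] <- wt(dplyr::bind_rows(funnels), "funnel.tsv")
  paths["dosage"] <- wt(dplyr::bind_rows(dosages), "dosage.tsv")
  invisible(paths)
}

#' Funnel plot of per-variant ratios against precision
#'
#' @param report An `mr_report`.
#' @param stratum Which instrument set to plot (default `"all"`).
#' @return A ggplot object.
#' @export
plot_funnel <- function(report, stratum = "all") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_funnel requires ggplot2")
  }
  pd <- report$plots[[stratum]]
  if (is.null(pd) || pd$empty) stopf("no instruments in stratum '%s'", stratum)
  ggplot2::ggplot(pd$funnel, ggplot2::aes(x = ratio,
                                          y = precision)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(data = pd$funnel_refs,
                        ggplot2::aes(xintercept = beta,
                                     colour = method),
                        linetype = "dashed") +
    ggplot2::labs(x = "Wald ratio", y = "1 / SE(ratio)", colour = "Method")
}

#' Dosage plot of SNP-outcome against SNP-exposure effects
#'
#' @inheritParams plot_funnel
#' @return A ggplot object.
#' @export
plot_dosage <- function(report, stratum = "all") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_dosage requires ggplot2")
  }
  pd <- report$plots[[stratum]]
  if (is.null(pd) || pd$empty) stopf("no instruments in stratum '%s'", stratum)
  ggplot2::ggplot(pd$dosage, ggplot2::aes(x = beta_x,
                                          y = beta_y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = beta_y - 1.96 * se_y,
                                        ymax = beta_y + 1.96 * se_y),
                           width = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = pd$dosage_lines,
                         ggplot2::aes(slope = slope,
                                      intercept = intercept,
                                      colour = method)) +
    ggplot2::labs(x = "SNP-exposure effect", y = "SNP-outcome effect",
                  colour = "Method")
}
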