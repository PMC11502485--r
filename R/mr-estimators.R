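#' Per-variant Wald ratio estimates
#'
#' The building block of all the estimators: `ratio = beta_y / beta_x`
#' with first-order delta-method standard error `se_y / |beta_x|` and
#' inverse-variance weight `1 / ratio_se^2`. Records with `beta_x = 0`
#' are excluded (the ratio is undefined) and reported via the
#' `"excluded"` attribute.
#'
#' @param set A `harmonized_set` or records tibble.
#' @return Tibble with `variant_id`, `ratio`, `ratio_se`, `weight`.
#' @export
ratio_estimates <- function(set) {
  r <- as_harmonized_records(set)
  zero <- !is.na(r$beta_x) & r$beta_x == 0
  r <- r[!zero, , drop = FALSE]
  out <- tibble::tibble(
    variant_id = r$variant_id,
    ratio = r$beta_y / r$beta_x,
    ratio_se = r$se_y / abs(r$beta_x)
  )
  out$weight <- 1 / out$ratio_se^2
  attr(out, "excluded") <- sum(zero)
  out
}

mr_result_row <- function(method, beta = NA_real_, se = NA_real_,
                          pval = NA_real_, n_snps = 0L, Q = NA_real_,
                          Q_pval = NA_real_, I2 = NA_real_,
                          intercept = NA_real_, intercept_se = NA_real_,
                          intercept_pval = NA_real_, note = NA_character_) {
  tibble::tibble(
    method = method, beta = beta, se = se, pval = pval,
    n_snps = as.integer(n_snps), Q = Q, Q_pval = Q_pval, I2 = I2,
    intercept = intercept, intercept_se = intercept_se,
    intercept_pval = intercept_pval, note = note
  )
}

i2_from_q <- function(Q, df) {
  if (is.na(Q) || Q <= 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' Inverse-variance weighted causal estimate
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure
#' effects through the origin, weights `1/se_y^2`:
#' `beta = sum(beta_x beta_y / se_y^2) / sum(beta_x^2 / se_y^2)`.
#' Under the random-effects model the fixed-effect standard error is
#' scaled by `max(1, sqrt(Q/(L-1)))` — multiplicative over-dispersion
#' floored at 1, so reported uncertainty is never smaller than the
#' fixed-effect one. A single instrument degenerates to its Wald ratio.
#' Two-sided p-values come from the normal distribution.
#'
#' @param set A `harmonized_set` or records tibble.
#' @param random_effects Apply the multiplicative over-dispersion scale
#'   (default `TRUE`).
#' @return One-row tibble: `method`, `beta`, `se`, `pval`, `n_snps`, `Q`,
#'   `Q_pval`, `I2` (Egger-only columns `NA`).
#' @export
mr_ivw <- function(set, random_effects = TRUE) {
  r <- as_harmonized_records(set)
  r <- r[!is.na(r$beta_x) & r$beta_x != 0, , drop = FALSE]
  L <- nrow(r)
  if (L == 0) return(mr_result_row("IVW", note = "no-instruments"))
  if (L == 1) {
    beta <- r$beta_y / r$beta_x
    se <- r$se_y / abs(r$beta_x)
    return(mr_result_row("IVW", beta = beta, se = se,
                         pval = clamp_pval(2 * stats::pnorm(-abs(beta / se))),
                         n_snps = 1L, note = "wald-ratio"))
  }
  w <- 1 / r$se_y^2
  beta <- sum(w * r$beta_x * r$beta_y) / sum(w * r$beta_x^2)
  se_fixed <- 1 / sqrt(sum(w * r$beta_x^2))
  Q <- sum(w * (r$beta_y - beta * r$beta_x)^2)
  df <- L - 1
  scale <- if (random_effects) max(1, sqrt(Q / df)) else 1
  se <- se_fixed * scale
  mr_result_row(
    "IVW", beta = beta, se = se,
    pval = clamp_pval(2 * stats::pnorm(-abs(beta / se))),
    n_snps = L, Q = Q,
    Q_pval = stats::pchisq(Q, df, lower.tail = FALSE),
    I2 = i2_from_q(Q, df)
  )
}

#' MR-Egger regression estimate
#'
#' Weighted linear regression of SNP-outcome on SNP-exposure effects with
#' a free intercept, weights `1/se_y^2`, on records oriented to the
#' exposure-increasing allele. The slope estimates the causal effect; the
#' intercept estimates the average directional pleiotropy, and a nonzero
#' intercept signals that the exclusion-restriction assumption fails on
#' average. Standard errors are scaled by `max(1, sqrt(Q_E/(L-2)))`;
#' two-sided p-values use the t distribution with `L-2` degrees of
#' freedom. Requires at least 3 instruments.
#'
#' @inheritParams mr_ivw
#' @return One-row tibble including `intercept`, `intercept_se`,
#'   `intercept_pval`.
#' @export
mr_egger <- function(set) {
  r <- as_harmonized_records(set)
  r <- r[!is.na(r$beta_x) & r$beta_x != 0, , drop = FALSE]
  L <- nrow(r)
  if (L == 0) return(mr_result_row("Egger", note = "no-instruments"))
  if (L < 3) return(mr_result_row("Egger", n_snps = L,
                                  note = "insufficient-instruments"))
  w <- 1 / r$se_y^2
  sw <- sum(w); swx <- sum(w * r$beta_x); swx2 <- sum(w * r$beta_x^2)
  swy <- sum(w * r$beta_y); swxy <- sum(w * r$beta_x * r$beta_y)
  D <- sw * swx2 - swx^2
  slope <- (sw * swxy - swx * swy) / D
  intercept <- (swx2 * swy - swx * swxy) / D
  fitted <- intercept + slope * r$beta_x
  Q <- sum(w * (r$beta_y - fitted)^2)
  df <- L - 2
  scale <- max(1, sqrt(Q / df))
  se_slope <- sqrt(sw / D) * scale
  se_int <- sqrt(swx2 / D) * scale
  mr_result_row(
    "Egger", beta = slope, se = se_slope,
    pval = clamp_pval(2 * stats::pt(-abs(slope / se_slope), df)),
    n_snps = L, Q = Q,
    Q_pval = stats::pchisq(Q, df, lower.tail = FALSE),
    I2 = i2_from_q(Q, df),
    intercept = intercept, intercept_se = se_int,
    intercept_pval = clamp_pval(2 * stats::pt(-abs(intercept / se_int), df))
  )
}

# weighted median by interpolation of standardized cumulative weights
weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]; w <- weight[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (length(r) == 1 || s[1] >= 0.5) return(r[1])
  L <- length(r)
  if (s[L] <= 0.5) return(r[L])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

pwm_point <- function(ratio, weight, penalty_k) {
  b <- weighted_median_point(ratio, weight)
  q <- weight * (ratio - b)^2
  # clamp the tail away from numerical zero so penalized weights stay
  # positive even for gross outliers (the true tail is always > 0)
  pj <- clamp_pval(stats::pchisq(q, df = 1, lower.tail = FALSE))
  wstar <- weight * pmin(1, penalty_k * pj)
  weighted_median_point(ratio, wstar)
}

wm_bootstrap_se <- function(ratio, ratio_se, weight, n_boot, seed,
                            penalized, penalty_k) {
  L <- length(ratio)
  with_seed(seed, {
    draws <- vapply(seq_len(n_boot), function(i) {
      ri <- stats::rnorm(L, ratio, ratio_se)
      if (penalized) pwm_point(ri, weight, penalty_k)
      else weighted_median_point(ri, weight)
    }, numeric(1))
    stats::sd(draws)
  })
}

#' Weighted-median causal estimate
#'
#' The median of the per-variant Wald ratios under standardized
#' inverse-variance weights: order the ratios, form cumulative weights
#' `s_j = (sum_{k<=j} w_k - w_j/2) / sum w_k`, and linearly interpolate
#' the ordered ratios at `s = 0.5`. Consistent when at least half the
#' weight comes from valid instruments. The standard error is a seeded
#' parametric bootstrap: each ratio is resampled from
#' `Normal(ratio_j, ratio_se_j)` and the median recomputed.
#'
#' @inheritParams mr_ivw
#' @param n_boot Number of bootstrap draws (default 1000; minimum 100).
#' @param seed Seed for the bootstrap stream (`NULL` uses the current RNG
#'   state).
#' @return One-row tibble as in [mr_ivw()].
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = NULL) {
  wm_engine(set, n_boot, seed, penalized = FALSE, penalty_k = 20,
            method = "WM")
}

#' Penalized weighted-median causal estimate
#'
#' Weighted median with outlier down-weighting: after a first weighted
#' median `b`, each variant's heterogeneity contribution
#' `q_j = w_j (ratio_j - b)^2` is scored against the chi-square(1) upper
#' tail and the weight is rescaled to `w_j * min(1, penalty_k * p_j)`, so
#' variants in close agreement keep their full weight (penalty factor 1)
#' while gross outliers are penalized towards zero. The weighted median is
#' then recomputed with the penalized weights.
#'
#' @inheritParams mr_weighted_median
#' @param penalty_k Penalty constant (default 20).
#' @return One-row tibble as in [mr_ivw()].
#' @export
mr_penalized_weighted_median <- function(set, n_boot = 1000, seed = NULL,
                                         penalty_k = 20) {
  wm_engine(set, n_boot, seed, penalized = TRUE, penalty_k = penalty_k,
            method = "PWM")
}

wm_engine <- function(set, n_boot, seed, penalized, penalty_k, method) {
  if (n_boot < 100) stopf("n_boot must be >= 100")
  rat <- ratio_estimates(set)
  L <- nrow(rat)
  if (L == 0) return(mr_result_row(method, note = "no-instruments"))
  beta <- if (penalized) pwm_point(rat$ratio, rat$weight, penalty_k)
          else weighted_median_point(rat$ratio, rat$weight)
  se <- wm_bootstrap_se(rat$ratio, rat$ratio_se, rat$weight, n_boot, seed,
                        penalized, penalty_k)
  pval <- if (is.na(se) || se == 0) NA_real_ else
    clamp_pval(2 * stats::pnorm(-abs(beta / se)))
  mr_result_row(method, beta = beta, se = se, pval = pval, n_snps = L)
}

#' Cochran's Q heterogeneity statistics
#'
#' `Q = sum w_j (beta_y_j - fitted_j)^2` with `w_j = 1/se_y_j^2` and
#' fitted values from the named model (IVW: through-origin fit; Egger:
#' with intercept). The p-value uses the chi-square distribution with
#' `L-1` (IVW) or `L-2` (Egger) degrees of freedom, and
#' `I2 = max(0, (Q - df)/Q) * 100` (Higgins heterogeneity form, floored
#' at 0).
#'
#' @inheritParams mr_ivw
#' @param model `"IVW"` or `"Egger"`.
#' @return List with `Q`, `Q_pval`, `I2`.
#' @export
mr_heterogeneity <- function(set, model = c("IVW", "Egger")) {
  model <- match.arg(model)
  est <- if (model == "IVW") mr_ivw(set) else mr_egger(set)
  if (is.na(est$Q)) stopf("heterogeneity undefined: %s", est$note)
  list(Q = est$Q, Q_pval = est$Q_pval, I2 = est$I2)
}

#' Run all four MR estimators on one instrument set
#'
#' @inheritParams mr_ivw
#' @inheritParams mr_penalized_weighted_median
#' @return Four-row tibble (IVW, Egger, WM, PWM).
#' @export
mr_all <- function(set, random_effects = TRUE, n_boot = 1000, seed = NULL,
                   penalty_k = 20) {
  dplyr::bind_rows(
    mr_ivw(set, random_effects = random_effects),
    mr_egger(set),
    mr_weighted_median(set, n_boot = n_boot, seed = seed),
    mr_penalized_weighted_median(set, n_boot = n_boot,
                                 seed = if (is.null(seed)) NULL else seed + 1L,
                                 penalty_k = penalty_k)
  )
}
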