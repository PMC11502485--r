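#' Theoretical standard error of a per-allele effect estimate
#'
#' For a standardized trait, the sampling standard error of a per-allele
#' regression coefficient is approximately
#' `1 / sqrt(2 * eaf * (1 - eaf) * n)` — the inverse square root of the
#' genotype variance times the sample size. Symmetric in `eaf` about 0.5;
#' quadrupling `n` halves the standard error.
#'
#' @param eaf Effect-allele frequency strictly inside (0,1).
#' @param n Sample size (`> 2`).
#' @return The standard error, vectorized.
#' @export
theoretical_se <- function(eaf, n) {
  if (any(is.na(eaf) | eaf <= 0 | eaf >= 1)) {
    stopf("eaf must be strictly inside (0,1)")
  }
  if (any(is.na(n) | n <= 2)) stopf("n must be > 2")
  1 / sqrt(2 * eaf * (1 - eaf) * n)
}

#' Configuration for the linked summary-statistics simulator
#'
#' Defines the generative model behind [simulate_two_sample_study()]:
#' `n_variants` independent pre-resolved signals with minor-allele
#' frequencies `maf_range`; forward variants split into two latent classes
#' A and B with class-specific causal effects on the outcome (`theta_A`,
#' `theta_B`) and class-specific indicator coefficients
#' (`indicator_gamma_A`, `indicator_gamma_B` — opposite signs encode the
#' resistance-versus-bioaction structure); an optional fraction of
#' reverse-causal variants acting on the outcome first; and optional
#' directional pleiotropy. Traits are simulated on the standardized scale
#' so [theoretical_se()] applies exactly.
#'
#' @param n_variants Number of independent variants (default 50).
#' @param n_exposure,n_indicator,n_outcome Per-study sample sizes
#'   (default 100000 each; the three studies are non-overlapping).
#' @param maf_range Uniform range for minor-allele frequencies (default
#'   `c(0.05, 0.5)`).
#' @param exposure_effect_sd SD of the true per-allele exposure effects
#'   (default 0.05 standardized units).
#' @param class_probs Named probabilities for classes `A` and `B` among
#'   forward variants (default 0.5 each).
#' @param theta_A,theta_B True causal effect of the exposure on the
#'   outcome per class (default 0.2 both — a single homogeneous effect).
#' @param indicator_gamma_A,indicator_gamma_B Indicator effect per unit of
#'   exposure effect (defaults +1 and -1).
#' @param pleiotropy_frac Fraction of forward variants with a direct
#'   (horizontal-pleiotropy) outcome effect (default 0).
#' @param pleiotropy_mean,pleiotropy_sd Normal parameters of the
#'   pleiotropic effect, expressed in the exposure-increasing-allele frame
#'   (defaults 0 and 0.02).
#' @param correlated_pleiotropy If `TRUE`, pleiotropic effects are made
#'   proportional to instrument strength, deliberately violating the
#'   InSIDE assumption (default `FALSE`).
#' @param reverse_frac Fraction of variants that are reverse-causal:
#'   primary outcome variants with an induced, attenuated exposure effect
#'   (default 0).
#' @param reverse_effect_sd SD of the reverse variants' direct outcome
#'   effects (default 0.15 — the scale of strong primary outcome loci).
#' @param reverse_attenuation Induced exposure effect as a fraction of the
#'   outcome effect (default 1/3, i.e. a 3-fold effect ratio, a 9-fold
#'   variance-explained ratio).
#' @param allele_swap_frac Fraction of indicator/outcome rows whose allele
#'   labels are stored swapped (beta negated, eaf complemented), to
#'   exercise harmonization (default 0.25).
#' @param noise If `FALSE`, sampling noise is disabled and observed betas
#'   equal the true effects (default `TRUE`).
#' @param seed Integer seed; the three studies use distinct sub-streams.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_variants = 50L,
                       n_exposure = 100000L, n_indicator = 100000L,
                       n_outcome = 100000L,
                       maf_range = c(0.05, 0.5),
                       exposure_effect_sd = 0.05,
                       class_probs = c(A = 0.5, B = 0.5),
                       theta_A = 0.2, theta_B = 0.2,
                       indicator_gamma_A = 1, indicator_gamma_B = -1,
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0.02,
                       correlated_pleiotropy = FALSE,
                       reverse_frac = 0, reverse_effect_sd = 0.15,
                       reverse_attenuation = 1 / 3,
                       allele_swap_frac = 0.25,
                       noise = TRUE, seed = 1L) {
  cfg <- list(
    n_variants = as.integer(n_variants), n_exposure = as.integer(n_exposure),
    n_indicator = as.integer(n_indicator), n_outcome = as.integer(n_outcome),
    maf_range = as.numeric(maf_range),
    exposure_effect_sd = exposure_effect_sd, class_probs = class_probs,
    theta_A = theta_A, theta_B = theta_B,
    indicator_gamma_A = indicator_gamma_A,
    indicator_gamma_B = indicator_gamma_B,
    pleiotropy_frac = pleiotropy_frac, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd,
    correlated_pleiotropy = isTRUE(correlated_pleiotropy),
    reverse_frac = reverse_frac, reverse_effect_sd = reverse_effect_sd,
    reverse_attenuation = reverse_attenuation,
    allele_swap_frac = allele_swap_frac,
    noise = isTRUE(noise), seed = as.integer(seed)
  )
  with(cfg, {
    if (n_variants < 1) stopf("n_variants must be >= 1")
    if (any(c(n_exposure, n_indicator, n_outcome) <= 2)) {
      stopf("per-study sample sizes must be > 2")
    }
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2]) {
      stopf("maf_range must be (low, high) within (0, 0.5]")
    }
    if (exposure_effect_sd <= 0) stopf("exposure_effect_sd must be > 0")
    if (!all(c("A", "B") %in% names(class_probs)) ||
        any(class_probs < 0) || sum(class_probs) > 1 + 1e-12 ||
        sum(class_probs) <= 0) {
      stopf("class_probs must give non-negative A/B probabilities summing in (0,1]")
    }
    for (f in c("pleiotropy_frac", "reverse_frac", "allele_swap_frac")) {
      v <- cfg[[f]]
      if (v < 0 || v > 1) stopf("%s must be in [0,1]", f)
    }
    if (pleiotropy_sd < 0) stopf("pleiotropy_sd must be >= 0")
    if (reverse_effect_sd <= 0) stopf("reverse_effect_sd must be > 0")
    if (reverse_attenuation <= 0) stopf("reverse_attenuation must be > 0")
  })
  structure(cfg, class = "sim_config")
}

# deterministic genomic layout: one chromosome, 200 kb spacing, so a
# variant's neighbours within +/-4 positions fall inside a 1 Mb window
variant_layout <- function(n_variants) {
  tibble::tibble(
    variant_id = sprintf("rs%05d", seq_len(n_variants)),
    chrom = "1",
    pos = 1L + (seq_len(n_variants) - 1L) * 200000L
  )
}

NONPALINDROMIC_PAIRS <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

#' Simulate linked exposure/indicator/outcome summary statistics
#'
#' Generates three GWAS summary-statistics tables over a shared variant
#' panel, plus a ground-truth table, under the model described in
#' [sim_config()]. Forward variants draw a true exposure effect
#' `gamma_j ~ Normal(0, exposure_effect_sd^2)`; the indicator effect is
#' `indicator_gamma_class * gamma_j` and the outcome effect is
#' `theta_class * gamma_j` plus, for pleiotropic variants, a directional
#' term expressed in the exposure-increasing-allele frame. Reverse-causal
#' variants draw a direct outcome effect and an induced exposure effect
#' attenuated by `reverse_attenuation`, so their variance explained in the
#' outcome exceeds that in the exposure by construction. Observed betas
#' add independent noise with the [theoretical_se()] of each study; the
#' three studies use independent sub-seeds (two-sample design). Output is
#' fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `exposure`, `indicator`, `outcome` ([sumstats]
#'   tables), `truth` (per-variant class, true effects, pleiotropy draw)
#'   and `config`.
#' @export
simulate_two_sample_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  L <- cfg$n_variants
  layout <- variant_layout(L)

  with_seed(cfg$seed, {
    maf <- stats::runif(L, cfg$maf_range[1], cfg$maf_range[2])
    pair <- NONPALINDROMIC_PAIRS[
      sample.int(nrow(NONPALINDROMIC_PAIRS), L, replace = TRUE), ,
      drop = FALSE]

    u <- stats::runif(L)
    pA <- cfg$class_probs[["A"]] / sum(cfg$class_probs)
    class <- ifelse(u < cfg$reverse_frac, "reverse",
                    ifelse(stats::runif(L) < pA, "A", "B"))

    gamma <- stats::rnorm(L, 0, cfg$exposure_effect_sd)
    delta <- stats::rnorm(L, 0, cfg$reverse_effect_sd)
    is_pleio <- class != "reverse" & stats::runif(L) < cfg$pleiotropy_frac
    alpha <- ifelse(is_pleio,
                    stats::rnorm(L, cfg$pleiotropy_mean, cfg$pleiotropy_sd), 0)
    if (cfg$correlated_pleiotropy) {
      alpha <- alpha * abs(gamma) / cfg$exposure_effect_sd
    }

    theta <- ifelse(class == "A", cfg$theta_A,
                    ifelse(class == "B", cfg$theta_B, 0))
    ind_gamma <- ifelse(class == "A", cfg$indicator_gamma_A,
                        ifelse(class == "B", cfg$indicator_gamma_B, 0))

    fwd <- class != "reverse"
    beta_x_true <- ifelse(fwd, gamma, cfg$reverse_attenuation * delta)
    beta_z_true <- ifelse(fwd, ind_gamma * gamma, 0)
    # pleiotropy is directional in the exposure-increasing-allele frame:
    # flipping the stored allele must flip it with the exposure effect
    orient_sign <- ifelse(beta_x_true >= 0, 1, -1)
    beta_y_true <- ifelse(fwd, theta * gamma + orient_sign * alpha, delta)

    se_x <- theoretical_se(maf, cfg$n_exposure)
    se_z <- theoretical_se(maf, cfg$n_indicator)
    se_y <- theoretical_se(maf, cfg$n_outcome)
    noise <- as.numeric(cfg$noise)
    beta_x <- beta_x_true + noise * stats::rnorm(L) * se_x
    beta_z <- beta_z_true + noise * stats::rnorm(L) * se_z
    beta_y <- beta_y_true + noise * stats::rnorm(L) * se_y

    make_table <- function(beta, se, n, trait, swap) {
      df <- tibble::tibble(
        variant_id = layout$variant_id, chrom = layout$chrom,
        pos = layout$pos,
        effect_allele = pair[, 1], other_allele = pair[, 2],
        eaf = maf, beta = beta, se = se,
        pval = clamp_pval(2 * stats::pnorm(-abs(beta / se))),
        n = rep(n, L)
      )
      if (any(swap)) {
        ea <- df$effect_allele
        df$effect_allele[swap] <- df$other_allele[swap]
        df$other_allele[swap] <- ea[swap]
        df$beta[swap] <- -df$beta[swap]
        df$eaf[swap] <- 1 - df$eaf[swap]
      }
      sumstats(df, trait_name = trait, trait_units = "SD")
    }

    no_swap <- rep(FALSE, L)
    swap_z <- stats::runif(L) < cfg$allele_swap_frac
    swap_y <- stats::runif(L) < cfg$allele_swap_frac

    list(
      exposure = make_table(beta_x, se_x, cfg$n_exposure, "exposure", no_swap),
      indicator = make_table(beta_z, se_z, cfg$n_indicator, "indicator",
                             swap_z),
      outcome = make_table(beta_y, se_y, cfg$n_outcome, "outcome", swap_y),
      truth = tibble::tibble(
        variant_id = layout$variant_id, class = class, maf = maf,
        beta_x_true = beta_x_true, beta_z_true = beta_z_true,
        beta_y_true = beta_y_true,
        theta = theta, alpha = alpha, is_pleiotropic = is_pleio
      ),
      config = cfg
    )
  })
}

#' Simulate a block-structured LD reference
#'
#' Places the simulated variant panel on the deterministic layout used by
#' [simulate_two_sample_study()] and declares every pair of variants
#' within the same consecutive block of `block_size` variants to have
#' r-squared `within_block_r2`; cross-block pairs are absent (unknown LD).
#'
#' @param config A [sim_config()] (supplies the variant panel).
#' @param block_size Number of consecutive variants per block (default 1:
#'   no off-diagonal pairs).
#' @param within_block_r2 The r-squared shared by within-block pairs
#'   (default 0.9).
#' @return An `ld_reference`.
#' @export
simulate_ld_blocks <- function(config, block_size = 1L,
                               within_block_r2 = 0.9) {
  stopifnot(inherits(config, "sim_config"))
  if (block_size < 1) stopf("block_size must be >= 1")
  if (within_block_r2 < 0 || within_block_r2 > 1) {
    stopf("within_block_r2 must be in [0,1]")
  }
  layout <- variant_layout(config$n_variants)
  block <- (seq_len(config$n_variants) - 1L) %/% as.integer(block_size)
  pairs <- do.call(rbind, lapply(split(layout$variant_id, block), function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    data.frame(variant_id_a = cmb[1, ], variant_id_b = cmb[2, ],
               r2 = within_block_r2, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) {
    pairs <- data.frame(variant_id_a = character(),
                        variant_id_b = character(), r2 = numeric())
  }
  ld_reference(pairs, layout)
}

#' Write a simulated study to TSV files
#'
#' Serializes the three summary-statistics tables and the ground truth so
#' a simulated study can be re-read through the standard IO path.
#'
#' @param sim Output of [simulate_two_sample_study()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulated_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    exposure = file.path(dir, "exposure.tsv"),
    indicator = file.path(dir, "indicator.tsv"),
    outcome = file.path(dir, "outcome.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_sumstats(sim$exposure, paths[["exposure"]])
  write_sumstats(sim$indicator, paths[["indicator"]])
  write_sumstats(sim$outcome, paths[["outcome"]])
  truth <- sim$truth
  for (col in c("maf", "beta_x_true", "beta_z_true", "beta_y_true",
                "theta", "alpha")) {
    truth[[col]] <- num_full(truth[[col]])
  }
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(paths)
}
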