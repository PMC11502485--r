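# shared fixture builders; everything is generated in code, no stored data

# a minimal valid summary-statistics data frame
make_sumstats_df <- function(n = 10, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    pairs <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
    idx <- sample(4, n, replace = TRUE)
    data.frame(
      variant_id = sprintf("rs%04d", seq_len(n)),
      chrom = sample(c("1", "2"), n, replace = TRUE),
      pos = sort(sample.int(1e6, n)),
      effect_allele = pairs[idx, 1],
      other_allele = pairs[idx, 2],
      eaf = round(runif(n, 0.05, 0.95), 6),
      beta = rnorm(n, 0, 0.1),
      se = runif(n, 0.001, 0.05),
      pval = runif(n, 1e-12, 1),
      n = sample(1e4:1e5, n),
      stringsAsFactors = FALSE
    )
  })
}

# harmonized records tibble built directly (post-orientation frame)
make_records <- function(beta_x, beta_y, se_y, se_x = 0.01,
                         beta_z = rep(1, length(beta_x)),
                         n_x = 1e5L, n_y = 1e5L) {
  L <- length(beta_x)
  tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(L)),
    chrom = "1", pos = seq_len(L),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    proxy_of = NA_character_, proxy_r2 = NA_real_,
    beta_x = beta_x, se_x = se_x, p_x = 1e-10, n_x = n_x,
    beta_z = beta_z, se_z = 0.01, n_z = 1e5L,
    beta_y = beta_y, se_y = se_y, n_y = n_y,
    orientable = TRUE
  )
}

# run the harmonization chain over a simulated study (no selection filter:
# the generator emits pre-resolved instruments)
harmonize_sim <- function(sim, ld = NULL, p_threshold = 1 - 1e-12) {
  build_instrument_set(sim$exposure, sim$indicator, sim$outcome, ld = ld,
                       p_threshold = p_threshold)
}

# independent weighted-median oracle: explicit prefix-sum walk plus linear
# interpolation, written long-hand (kept separate from the implementation)
oracle_weighted_median <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]; w <- w[o]
  total <- sum(w)
  s <- numeric(length(r))
  acc <- 0
  for (j in seq_along(r)) {
    s[j] <- (acc + w[j] / 2) / total
    acc <- acc + w[j]
  }
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  j <- max(which(s < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}
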