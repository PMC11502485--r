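test_that("variance explained follows the z-based closed form", {
  expect_equal(variance_explained(0, 0.01, 100), 0)
  expect_equal(variance_explained(0.1, 0.01, 1000), 100 / 1098)
  # strictly increasing in |z| at fixed n
  r2 <- variance_explained(seq(0, 0.5, by = 0.05), 0.01, 500)
  expect_true(all(diff(r2) > 0))
  expect_true(all(r2 >= 0 & r2 < 1))
  expect_error(variance_explained(0.1, 0.01, 2), "n > 2")
  expect_error(variance_explained(0.1, 0, 100), "se > 0")
})

test_that("Steiger keeps exposure-first and removes outcome-first variants", {
  # equal n: decided by |z| alone
  rec <- make_records(beta_x = c(0.10, 0.02), beta_y = c(0.02, 0.10),
                      se_y = 0.01, se_x = 0.01)
  st <- steiger_filter(rec)
  expect_equal(st$results$kept, c(TRUE, FALSE))

  # unequal n: the closed forms cross even though |z_x| > |z_y|
  rec2 <- make_records(beta_x = 0.05, beta_y = 0.04, se_y = 0.01,
                       se_x = 0.01, n_x = 10000L, n_y = 500L)
  r2x <- variance_explained(0.05, 0.01, 10000)  # 25/10023
  r2y <- variance_explained(0.04, 0.01, 500)    # 16/514
  expect_lt(r2x, r2y)
  st2 <- steiger_filter(rec2)
  expect_false(st2$results$kept)
  expect_equal(st2$results$reason, "steiger-reverse")
})

test_that("Steiger decisions are deterministic and handle missing n", {
  rec <- make_records(beta_x = runif(20, 0.01, 0.1),
                      beta_y = runif(20, 0.01, 0.1), se_y = 0.01)
  expect_identical(steiger_filter(rec)$results, steiger_filter(rec)$results)

  rec$n_y[3] <- NA
  expect_equal(steiger_filter(rec)$results$reason[3], "steiger-no-n")
  expect_true(steiger_filter(rec, on_missing_n = "keep")$results$kept[3])
})

test_that("Steiger removes simulated reverse-causal variants, spares forward ones", {
  cfg <- sim_config(n_variants = 600, reverse_frac = 0.4,
                    n_exposure = 200000L, n_indicator = 200000L,
                    n_outcome = 200000L, seed = 101)
  sim <- simulate_two_sample_study(cfg)
  # in truth, reverse variants explain more outcome than exposure variance
  rev <- sim$truth$class == "reverse"
  expect_true(all(
    abs(sim$truth$beta_y_true[rev]) > abs(sim$truth$beta_x_true[rev])))

  set <- harmonize_sim(sim)
  st <- steiger_filter(set)
  cls <- sim$truth$class[match(st$results$variant_id,
                               sim$truth$variant_id)]
  removed <- !st$results$kept
  expect_gte(mean(removed[cls == "reverse"]), 0.95)
  expect_lte(mean(removed[cls != "reverse"]), 0.10)
})

test_that("stratification partitions by indicator sign with zero unclassified", {
  rec <- make_records(beta_x = rep(0.1, 6), beta_y = 0.02, se_y = 0.01,
                      beta_z = c(0.3, -0.2, 0, 0.1, -0.4, NA))
  g <- stratify_by_indicator(rec, labels = c(positive = "resistance",
                                             negative = "bioaction"))
  expect_equal(unname(g$sizes), c(2L, 2L, 2L))
  expect_setequal(g$positive$variant_id, c("v001", "v004"))
  expect_setequal(g$unclassified$variant_id, c("v003", "v006"))
  expect_equal(sum(g$sizes), nrow(rec))
})

test_that("stratum sizes reproduce the 43 -> 35/7/1 accounting contract", {
  rec <- make_records(
    beta_x = rep(0.1, 43), beta_y = 0.02, se_y = 0.01,
    beta_z = c(runif(35, 0.01, 0.5), runif(7, -0.5, -0.01), NA)
  )
  g <- stratify_by_indicator(rec, labels = c(positive = "resistance",
                                             negative = "bioaction"))
  expect_equal(g$sizes, c(positive = 35L, negative = 7L, unclassified = 1L))
  expect_equal(g$labels[["positive"]], "resistance")
})

test_that("stratification is a partition for arbitrary sets and is invariant to storage strand", {
  for (seed in c(2, 5)) {
    sim <- simulate_two_sample_study(
      sim_config(n_variants = 80, reverse_frac = 0.15, seed = seed))
    set <- harmonize_sim(sim)
    g <- stratify_by_indicator(set)
    expect_equal(sum(g$sizes), nrow(set$records))

    # flip the stored alleles of every exposure record: same strata
    flipped <- as.data.frame(sim$exposure)
    ea <- flipped$effect_allele
    flipped$effect_allele <- flipped$other_allele
    flipped$other_allele <- ea
    flipped$beta <- -flipped$beta
    flipped$eaf <- 1 - flipped$eaf
    set2 <- build_instrument_set(sumstats(flipped), sim$indicator,
                                 sim$outcome, p_threshold = 1 - 1e-12)
    g2 <- stratify_by_indicator(set2)
    expect_setequal(g$positive$variant_id, g2$positive$variant_id)
    expect_setequal(g$negative$variant_id, g2$negative$variant_id)
  }
})
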