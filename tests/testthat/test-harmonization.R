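test_that("instrument selection is strict at the threshold", {
  df <- make_sumstats_df(3)
  df$pval <- c(5e-8, 4.9e-8, 1)
  tab <- sumstats(df)
  sel <- select_instruments(tab, 5e-8)
  expect_equal(sel$variant_id, "rs0002")  # boundary equality excluded

  df$pval <- rep(1, 3)
  expect_equal(nrow(select_instruments(sumstats(df), 5e-8)), 0)
})

test_that("selection count matches a direct scan on simulated tables", {
  sim <- simulate_two_sample_study(sim_config(n_variants = 100, seed = 7))
  thr <- 5e-8
  sel <- select_instruments(sim$exposure, thr)
  expect_equal(nrow(sel), sum(sim$exposure$pval < thr))
  expect_gt(nrow(sel), 0)
})

one_rec <- function(ea, oa, eaf, beta, se = 0.01) {
  tibble::tibble(effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = beta, se = se)
}

test_that("allele alignment handles identity, swap, strand flip, mismatch", {
  ref <- one_rec("A", "G", 0.3, 0.5)

  same <- align_alleles(ref, one_rec("A", "G", 0.3, 0.2))
  expect_equal(same$beta, 0.2)
  expect_equal(same$status, "ok")

  swapped <- align_alleles(ref, one_rec("G", "A", 0.7, 0.2))
  expect_equal(swapped$beta, -0.2)
  expect_equal(swapped$eaf, 0.3)

  flipped <- align_alleles(ref, one_rec("T", "C", 0.3, 0.2))
  expect_equal(flipped$beta, 0.2)  # strand relabel, no sign change
  expect_equal(flipped$effect_allele, "A")

  # complement-then-swap: other file reports T/C as C/T
  both <- align_alleles(ref, one_rec("C", "T", 0.7, 0.2))
  expect_equal(both$beta, -0.2)

  bad <- align_alleles(ref, one_rec("C", "G", 0.3, 0.2))
  expect_equal(bad$status, "dropped")
  expect_equal(bad$reason, "allele-mismatch")
})

test_that("palindromic variants drop when frequencies cannot resolve strand", {
  ref <- one_rec("A", "T", 0.5, 0.5)
  amb <- align_alleles(ref, one_rec("A", "T", 0.5, 0.2))
  expect_equal(amb$reason, "palindromic-ambiguous")

  ref2 <- one_rec("A", "T", 0.2, 0.5)
  na_eaf <- align_alleles(ref2, one_rec("A", "T", NA_real_, 0.2))
  expect_equal(na_eaf$reason, "palindromic-ambiguous")

  # informative frequencies: concordant side keeps the sign...
  ok <- align_alleles(ref2, one_rec("A", "T", 0.22, 0.2))
  expect_equal(ok$status, "ok")
  expect_equal(ok$beta, 0.2)
  # ...discordant side implies the opposite strand orientation
  flip <- align_alleles(ref2, one_rec("A", "T", 0.78, 0.2))
  expect_equal(flip$beta, -0.2)
  expect_equal(flip$eaf, 0.22)
})

test_that("orientation flips all betas together and is idempotent", {
  rec <- make_records(beta_x = c(0.1, -0.1), beta_y = c(-0.02, -0.02),
                      se_y = 0.01, beta_z = c(0.05, 0.05))
  out <- orient_to_exposure_increasing(rec)
  expect_equal(out$beta_x, c(0.1, 0.1))
  expect_equal(out$beta_z, c(0.05, -0.05))
  expect_equal(out$beta_y, c(-0.02, 0.02))
  expect_equal(out$effect_allele, c("A", "G"))
  expect_identical(orient_to_exposure_increasing(out), out)

  zero <- orient_to_exposure_increasing(
    make_records(beta_x = 0, beta_y = 0.1, se_y = 0.01))
  expect_false(zero$orientable)
})

proxy_fixture <- function() {
  target <- sumstats(data.frame(
    variant_id = c("p1", "p2", "p3"), chrom = "1",
    pos = c(500000L, 100000L, 2000000L),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.1, se = 0.01, pval = 1e-10, n = 1e5L
  ))
  ld <- ld_reference(
    data.frame(variant_id_a = "idx", variant_id_b = c("p1", "p2", "p3"),
               r2 = c(0.9, 0.9, 0.95)),
    data.frame(variant_id = c("idx", "p1", "p2", "p3"), chrom = "1",
               pos = c(1L, 500000L, 100000L, 2000000L))
  )
  list(target = target, ld = ld)
}

test_that("proxy search respects the strict r2 rule and tie-breaks by distance", {
  fx <- proxy_fixture()
  # best r2 (0.95) is beyond 1 Mb; the two r2 = 0.9 candidates tie, the
  # nearer one wins
  pr <- find_proxy("idx", fx$target, fx$ld)
  expect_equal(pr$proxy_id, "p2")
  expect_equal(pr$r2, 0.9)

  # sole candidate below the strict threshold is refused
  ld_low <- ld_reference(
    data.frame(variant_id_a = "idx", variant_id_b = "p1", r2 = 0.69),
    fx$ld$positions)
  expect_true(is.na(find_proxy("idx", fx$target, ld_low)$proxy_id))
  # ... and r2 exactly 0.7 is also refused (strict >)
  ld_eq <- ld_reference(
    data.frame(variant_id_a = "idx", variant_id_b = "p1", r2 = 0.7),
    fx$ld$positions)
  expect_true(is.na(find_proxy("idx", fx$target, ld_eq)$proxy_id))

  # a variant present in the target is its own proxy
  self <- find_proxy("p1", fx$target, fx$ld)
  expect_equal(self$proxy_id, "p1")
  expect_equal(self$r2, 1)

  # index unknown to the LD panel
  expect_equal(find_proxy("nowhere", fx$target, fx$ld)$reason, "no-position")
})

test_that("instrument-set bookkeeping: 50 instruments, 5 deleted, 3 proxied", {
  cfg <- sim_config(n_variants = 50, allele_swap_frac = 0.3, seed = 11)
  sim <- simulate_two_sample_study(cfg)
  ld <- simulate_ld_blocks(cfg, block_size = 2, within_block_r2 = 0.9)
  # delete 5 outcome variants; rs3/rs4 share a block so neither has a proxy
  deleted <- c("rs00001", "rs00003", "rs00004", "rs00005", "rs00007")
  outcome <- sim$outcome[!sim$outcome$variant_id %in% deleted, ]
  set <- build_instrument_set(sim$exposure, sim$indicator, outcome, ld = ld,
                              p_threshold = 1 - 1e-12)
  expect_equal(nrow(set$records), 48)
  expect_equal(sum(set$provenance$status == "dropped"), 2)
  expect_setequal(
    set$provenance$variant_id[set$provenance$status == "dropped"],
    c("rs00003", "rs00004"))
  expect_equal(unique(set$provenance$reason[set$provenance$status == "dropped"]),
               "no-proxy")
  proxied <- set$records[!is.na(set$records$proxy_of), ]
  expect_equal(proxied$variant_id, c("rs00001", "rs00005", "rs00007"))
  expect_equal(proxied$proxy_of, c("rs00002", "rs00006", "rs00008"))
})

test_that("harmonized sets conserve counts and are fully oriented", {
  for (seed in c(3, 9, 21)) {
    cfg <- sim_config(n_variants = 40, reverse_frac = 0.1,
                      allele_swap_frac = 0.4, seed = seed)
    sim <- simulate_two_sample_study(cfg)
    set <- harmonize_sim(sim)
    expect_equal(nrow(set$records) +
                   sum(set$provenance$status == "dropped"),
                 nrow(set$provenance))
    expect_true(all(set$records$beta_x >= 0))
    # alignment recovers the true effect frame: oriented outcome betas
    # correlate with oriented truth despite label swaps in the stored files
    truth <- sim$truth[match(set$records$variant_id, sim$truth$variant_id), ]
    flip <- sign(truth$beta_x_true)
    expect_gt(stats::cor(set$records$beta_y, truth$beta_y_true * flip), 0.8)
  }
})
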