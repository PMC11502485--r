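test_that("Wald ratios follow the delta method and its invariances", {
  rec <- make_records(beta_x = 0.2, beta_y = 0.1, se_y = 0.02)
  rat <- ratio_estimates(rec)
  expect_equal(rat$ratio, 0.5)
  expect_equal(rat$ratio_se, 0.1)
  expect_equal(rat$weight, 100)

  zero_y <- ratio_estimates(make_records(beta_x = 0.2, beta_y = 0,
                                         se_y = 0.02))
  expect_equal(zero_y$ratio, 0)

  # common rescaling of both betas leaves the ratio unchanged
  a <- ratio_estimates(make_records(beta_x = 0.1, beta_y = 0.03, se_y = 0.01))
  b <- ratio_estimates(make_records(beta_x = 0.4, beta_y = 0.12, se_y = 0.01))
  expect_equal(a$ratio, b$ratio)

  excl <- ratio_estimates(make_records(beta_x = c(0.2, 0), beta_y = 0.1,
                                       se_y = 0.02))
  expect_equal(nrow(excl), 1)
  expect_equal(attr(excl, "excluded"), 1)
})

test_that("IVW matches its closed form, degenerating to the Wald ratio", {
  one <- mr_ivw(make_records(beta_x = 0.2, beta_y = 0.1, se_y = 0.02))
  expect_equal(one$beta, 0.5)
  expect_equal(one$se, 0.1)

  # all ratios equal r: estimate r, zero heterogeneity, fixed = random se
  exact <- make_records(beta_x = c(0.1, 0.2, 0.3),
                        beta_y = 0.4 * c(0.1, 0.2, 0.3), se_y = 0.01)
  fe <- mr_ivw(exact, random_effects = FALSE)
  re <- mr_ivw(exact, random_effects = TRUE)
  expect_equal(fe$beta, 0.4)
  expect_equal(fe$Q, 0)
  expect_equal(fe$I2, 0)
  expect_equal(fe$se, re$se)

  # fixed three-row table against the hand-evaluated weighted sum
  rec <- make_records(beta_x = c(0.1, 0.2, 0.15),
                      beta_y = c(0.02, 0.05, 0.03),
                      se_y = c(0.01, 0.01, 0.02))
  est <- mr_ivw(rec)
  expect_equal(est$beta, 131.25 / 556.25, tolerance = 1e-12)

  empty <- mr_ivw(make_records(numeric(0), numeric(0), numeric(0)))
  expect_equal(empty$note, "no-instruments")
  expect_true(is.na(empty$beta))
})

test_that("IVW and Egger agree with a generic weighted-least-squares oracle", {
  set.seed(2024)
  for (i in 1:40) {
    L <- sample(3:50, 1)
    rec <- make_records(beta_x = runif(L, 0.02, 0.3),
                        beta_y = rnorm(L, 0.05, 0.05),
                        se_y = runif(L, 0.005, 0.05))
    w <- 1 / rec$se_y^2
    ivw_fit <- stats::lm(beta_y ~ beta_x - 1, data = rec, weights = w)
    egger_fit <- stats::lm(beta_y ~ beta_x, data = rec, weights = w)
    expect_equal(mr_ivw(rec)$beta, unname(coef(ivw_fit)[1]),
                 tolerance = 1e-10)
    eg <- mr_egger(rec)
    expect_equal(eg$beta, unname(coef(egger_fit)["beta_x"]),
                 tolerance = 1e-10)
    expect_equal(eg$intercept, unname(coef(egger_fit)["(Intercept)"]),
                 tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact affine law and refuses < 3 instruments", {
  bx <- c(0.05, 0.1, 0.2, 0.3)
  rec <- make_records(beta_x = bx, beta_y = 0.05 + 0.3 * bx, se_y = 0.01)
  eg <- mr_egger(rec)
  expect_equal(eg$intercept, 0.05, tolerance = 1e-12)
  expect_equal(eg$beta, 0.3, tolerance = 1e-12)
  expect_equal(eg$Q, 0)

  two <- mr_egger(make_records(beta_x = c(0.1, 0.2), beta_y = c(0.02, 0.04),
                               se_y = 0.01))
  expect_equal(two$note, "insufficient-instruments")
  expect_true(is.na(two$beta))
})

test_that("weighted median interpolates standardized cumulative weights", {
  sym <- make_records(beta_x = rep(1, 3), beta_y = c(0.1, 0.5, 0.9),
                      se_y = 1)
  expect_equal(mr_weighted_median(sym, n_boot = 100, seed = 1)$beta, 0.5)

  single <- mr_weighted_median(make_records(0.2, 0.1, 0.02),
                               n_boot = 100, seed = 1)
  expect_equal(single$beta, 0.5)

  # unequal weights against the long-hand prefix-sum oracle
  rec <- make_records(beta_x = c(0.1, 0.2, 0.25, 0.4),
                      beta_y = c(0.01, 0.08, 0.02, 0.1),
                      se_y = c(0.01, 0.02, 0.005, 0.02))
  rat <- ratio_estimates(rec)
  expect_equal(mr_weighted_median(rec, n_boot = 100, seed = 1)$beta,
               oracle_weighted_median(rat$ratio, rat$weight))

  # bootstrap se is seeded: same seed, same se
  a <- mr_weighted_median(rec, n_boot = 200, seed = 42)
  b <- mr_weighted_median(rec, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
})

test_that("penalization leaves homogeneous sets alone and tames outliers", {
  bx <- rep(0.2, 5)
  hom <- make_records(beta_x = bx, beta_y = 0.3 * bx, se_y = 0.01)
  wm <- mr_weighted_median(hom, n_boot = 100, seed = 1)
  pwm <- mr_penalized_weighted_median(hom, n_boot = 100, seed = 1)
  expect_equal(pwm$beta, wm$beta)

  # ten concordant ratios at 0.3 plus one gross outlier
  bx2 <- rep(0.2, 11)
  by2 <- 0.3 * bx2
  by2[11] <- 0.3 * 0.2 + 0.5
  out <- make_records(beta_x = bx2, beta_y = by2, se_y = 0.01)
  rat <- ratio_estimates(out)
  b0 <- mr_weighted_median(out, n_boot = 100, seed = 2)$beta
  q <- rat$weight * (rat$ratio - b0)^2
  pj <- pmax(stats::pchisq(q, 1, lower.tail = FALSE), .Machine$double.xmin)
  penalty <- pmin(1, 20 * pj)
  expect_true(all(penalty > 0 & penalty <= 1))
  expect_lt(penalty[11], 1)  # the outlier loses weight
  pwm2 <- mr_penalized_weighted_median(out, n_boot = 100, seed = 2)
  expect_equal(pwm2$beta, 0.3, tolerance = 1e-6)
})

test_that("heterogeneity statistics match direct summation and floor at zero", {
  rec <- make_records(beta_x = c(0.1, 0.2, 0.15),
                      beta_y = c(0.02, 0.05, 0.03),
                      se_y = c(0.01, 0.01, 0.02))
  het <- mr_heterogeneity(rec, "IVW")
  beta <- 131.25 / 556.25
  w <- 1 / rec$se_y^2
  Q_direct <- sum(w * (rec$beta_y - beta * rec$beta_x)^2)
  expect_equal(het$Q, Q_direct, tolerance = 1e-12)
  expect_equal(het$Q_pval, stats::pchisq(Q_direct, 2, lower.tail = FALSE))

  # near-collinear data: Q < df, I2 floored at 0
  tiny <- make_records(beta_x = c(0.1, 0.2, 0.3),
                       beta_y = 0.4 * c(0.1, 0.2, 0.3) + c(1e-5, -1e-5, 0),
                       se_y = 0.01)
  expect_equal(mr_heterogeneity(tiny, "IVW")$I2, 0)
  expect_error(mr_heterogeneity(make_records(0.2, 0.1, 0.01), "Egger"),
               "insufficient")
})

test_that("estimators are equivariant under instrument reordering", {
  set.seed(5)
  rec <- make_records(beta_x = runif(12, 0.05, 0.3),
                      beta_y = rnorm(12, 0.02, 0.03),
                      se_y = runif(12, 0.005, 0.03))
  perm <- rec[sample(nrow(rec)), ]
  expect_equal(mr_ivw(perm)$beta, mr_ivw(rec)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(perm)$beta, mr_egger(rec)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(perm, n_boot = 100, seed = 9)$beta,
               mr_weighted_median(rec, n_boot = 100, seed = 9)$beta,
               tolerance = 1e-12)
})
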