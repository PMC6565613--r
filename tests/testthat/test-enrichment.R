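test_that("penalized log-likelihood matches closed forms and the direct oracle", {
  # one block, one variant, BF = 1, Pi = 0.5: ln(0.5 + 0.5) = 0
  d1 <- tibble::tibble(variant_id = "a", pos = 1, block_id = 1L, ln_bf = 0)
  expect_equal(penalized_loglik(d1, NULL, stats::qlogis(0.5), penalty = 0.3), 0)

  # the penalty enters as exactly penalty * sum(lambda^2)
  d <- toy_block_data(3, 4, seed = 17)
  lam <- c(ann = 0.8)
  diff <- penalized_loglik(d, lam, 0.2, penalty = 0) -
    penalized_loglik(d, lam, 0.2, penalty = 0.3)
  expect_equal(diff, 0.3 * sum(lam^2))

  # brute-force equivalence on random small instances
  withr::with_seed(71, {
    for (i in 1:100) {
      dd <- toy_block_data(3, 4, seed = 1000 + i)
      lam <- c(ann = stats::rnorm(1))
      logit <- stats::rnorm(1)
      pen <- stats::runif(1)
      expect_equal(penalized_loglik(dd, lam, logit, pen),
                   oracle_penalized_loglik(dd, lam, stats::plogis(logit), pen),
                   tolerance = 1e-12)
    }
  })
})

test_that("an annotation marking every variant is shrunk to zero", {
  d <- toy_block_data(10, 5, seed = 23)
  d$ann <- 1L
  m <- fit_model(d, "ann", penalty = 0.3)
  # a constant annotation leaves the within-block softmax flat, so only the
  # ridge term moves lambda: the optimum is 0
  expect_equal(unname(m$lambda), 0, tolerance = 1e-4)
})

test_that("the fitted optimum dominates the null effect vector", {
  for (s in 1:3) {
    cfg <- sim_gwas_config(100, 10, c(atac = 0.3), 0.8, 0.4, 5, 0.007, seed = s)
    d <- add_ln_bf(simulate_gwas_dataset(cfg)$variants)
    m <- fit_model(d, "atac", penalty = 0.3)
    null_at_best_logit <- penalized_loglik(d, c(atac = 0), m$regional_logit, 0.3)
    expect_gte(m$penalized_loglik, null_at_best_logit)
  }
})

test_that("estimates are invariant to block and annotation column order", {
  cfg <- sim_gwas_config(120, 10, c(a1 = 0.3, a2 = 0.15), c(0.7, -0.3),
                         0.4, 5, 0.007, seed = 31)
  d <- add_ln_bf(simulate_gwas_dataset(cfg)$variants)
  m <- fit_model(d, c("a1", "a2"), penalty = 0.3)
  shuffled <- withr::with_seed(1, d[sample.int(nrow(d)), ])
  m2 <- fit_model(shuffled, c("a1", "a2"), penalty = 0.3)
  expect_equal(m2$lambda, m$lambda, tolerance = 1e-5)
  m3 <- fit_model(d, c("a2", "a1"), penalty = 0.3)
  expect_equal(m3$lambda[c("a1", "a2")], m$lambda, tolerance = 1e-5)
})

test_that("the single-annotation estimate matches a profile grid search", {
  cfg <- sim_gwas_config(40, 2, c(ann = 0.5), 1.5, 0.6, 6, 0.007, seed = 37)
  d <- add_ln_bf(simulate_gwas_dataset(cfg)$variants)
  m <- fit_model(d, "ann", penalty = 0)

  oracle_profile <- function(l) {
    stats::optimize(function(a) {
      oracle_penalized_loglik(d, c(ann = l), stats::plogis(a), 0)
    }, c(-10, 10), maximum = TRUE, tol = 1e-7)$objective
  }
  coarse <- seq(-5, 5, by = 0.01)
  l0 <- coarse[which.max(vapply(coarse, oracle_profile, numeric(1)))]
  fine <- seq(l0 - 0.05, l0 + 0.05, by = 0.001)
  lhat_grid <- fine[which.max(vapply(fine, oracle_profile, numeric(1)))]
  expect_equal(unname(m$lambda), lhat_grid, tolerance = 0.01)
})

test_that("intercept-only fits recover the regional signal fraction", {
  cfg <- sim_gwas_config(2000, 50, pi_regional = 0.5, causal_z_mean = 6,
                         se_value = 0.007, seed = 11)
  d <- add_ln_bf(simulate_gwas_dataset(cfg)$variants)
  m <- fit_model(d, annotations = character(0), penalty = 0)
  expect_lt(abs(m$pi_regional - 0.5), 0.1)
})

test_that("single-annotation enrichment has calibrated significance calls", {
  # type-I behaviour: a pure-noise annotation should rarely be called
  flags <- vapply(1:50, function(s) {
    cfg <- sim_gwas_config(200, 10, c(noise = 0.2), 0, 0.4, 6, 0.007, seed = s)
    d <- add_ln_bf(simulate_gwas_dataset(cfg)$variants)
    fit_single(d, "noise")$significant
  }, logical(1))
  expect_gte(mean(!flags), 0.9)
})

test_that("a strongly enriched annotation is detected with a positive estimate", {
  # annotation marking exactly the causal variants and no nulls
  cfg <- sim_gwas_config(150, 10, pi_regional = 0.6, causal_z_mean = 7,
                         se_value = 0.007, seed = 43)
  sim <- simulate_gwas_dataset(cfg)
  d <- add_ln_bf(sim$variants)
  causal_ids <- sim$truth$causal$causal_variant
  d$mark <- as.integer(d$variant_id %in% causal_ids)
  ci <- fit_single(d, "mark")
  expect_gt(ci$estimate, 0)
  expect_true(ci$significant)
  expect_lte(ci$conf.low, ci$estimate)
  expect_gte(ci$conf.high, ci$estimate)

  expect_error(fit_single(dplyr::mutate(d, none = 0L), "none"), "zero variants")
  expect_error(fit_single(d, "absent"), "not found")
})

test_that("penalty cross-validation is seeded, deterministic, and shrinks under noise", {
  cfg <- sim_gwas_config(100, 10, c(a = 0.3), 0.5, 0.4, 5, 0.007, seed = 47)
  d <- add_ln_bf(simulate_gwas_dataset(cfg)$variants)
  one <- cross_validate_penalty(d, "a", penalty_grid = 0.3, k_folds = 5, seed = 2)
  expect_equal(one$penalty, 0.3)

  cv1 <- cross_validate_penalty(d, "a", penalty_grid = c(0, 0.3), k_folds = 5, seed = 2)
  cv2 <- cross_validate_penalty(d, "a", penalty_grid = c(0, 0.3), k_folds = 5, seed = 2)
  expect_identical(cv1$table, cv2$table)

  few <- d[d$block_id <= 3, ]
  expect_error(cross_validate_penalty(few, "a", penalty_grid = 0.3, k_folds = 5),
               "fewer blocks")

  # pure-noise annotations prefer a positive ridge penalty most of the time
  chosen <- vapply(1:10, function(s) {
    cfgn <- sim_gwas_config(150, 15, c(a1 = 0.2, a2 = 0.3), c(0, 0),
                            0.4, 6, 0.007, seed = 400 + s)
    dn <- add_ln_bf(simulate_gwas_dataset(cfgn)$variants)
    cross_validate_penalty(dn, c("a1", "a2"), penalty_grid = c(0, 0.3, 1.0),
                           k_folds = 5, seed = s)$penalty
  }, numeric(1))
  expect_gte(mean(chosen > 0), 0.7)
})

test_that("backward elimination stops when the likelihood stops increasing", {
  cfg <- sim_gwas_config(300, 20, c(inform = 0.2, noise = 0.2), c(1.5, 0),
                         0.4, 6, 0.007, seed = 104)
  d <- add_ln_bf(simulate_gwas_dataset(cfg)$variants)
  full <- fit_model(d, c("inform", "noise"), penalty = 0.3)
  sw <- stepwise_reduce(d, full, k_folds = 10, seed = 4)
  if (nrow(sw$trace) > 0) {
    expect_true(all(sw$trace$loglik_after > sw$trace$loglik_before))
  }
  # empty annotation set: returned unchanged with empty trace
  m0 <- fit_model(d, annotations = character(0), penalty = 0.3)
  sw0 <- stepwise_reduce(d, m0, k_folds = 5, seed = 1)
  expect_equal(nrow(sw0$trace), 0L)
  expect_equal(sw0$model$lambda, m0$lambda)
})

test_that("broom-style accessors expose fits as tidy tables", {
  cfg <- sim_gwas_config(60, 8, c(atac = 0.3), 0.8, 0.4, 5, 0.007, seed = 53)
  d <- add_ln_bf(simulate_gwas_dataset(cfg)$variants)
  m <- fit_model(d, "atac", penalty = 0.3)
  td <- tidy(m)
  expect_equal(td$term, "atac")
  gl <- glance(m)
  expect_true(gl$converged)
  expect_equal(gl$n_blocks, 60)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")

  fm <- finemap_locus(d, d$variant_id[which.max(d$ln_bf)], model = m)
  expect_s3_class(ggplot2::autoplot(fm), "ggplot")
  expect_equal(glance(fm)$credible_set_size_post, nrow(attr(fm, "credible_set_post")))
})
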