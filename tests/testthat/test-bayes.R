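test_that("ln_abf matches its closed form and a quadrature oracle", {
  # z = 0: the exponential term vanishes, leaving the shrinkage factor
  expect_equal(ln_abf(0, 1, prior_variance_grid = 1), 0.5 * log(1 / 2))
  expect_equal(ln_abf(0, 1, prior_variance_grid = 1), -0.3465736, tolerance = 1e-6)

  # the worked case z = 5, se = 0.1, W = 0.1 against numerical integration
  expect_equal(ln_abf(5, 0.1, prior_variance_grid = 0.1),
               log(oracle_abf_quadrature(5, 0.1, 0.1)), tolerance = 1e-6)

  withr::with_seed(101, {
    for (i in 1:100) {
      z <- stats::runif(1, -6, 6)
      se <- stats::runif(1, 0.02, 1)
      W <- stats::runif(1, 0.01, 1)
      expect_equal(ln_abf(z, se, prior_variance_grid = W),
                   log(oracle_abf_quadrature(z, se, W)), tolerance = 1e-6)
    }
  })

  # grid averaging is the log of the arithmetic mean of per-W ABFs
  grid <- c(0.01, 0.1, 0.5)
  per_w <- vapply(grid, function(W) exp(ln_abf(2, 0.3, W)), numeric(1))
  expect_equal(ln_abf(2, 0.3, grid), log(mean(per_w)))

  expect_error(ln_abf(1, 0), "se")
  expect_error(ln_abf(1, 1, numeric(0)), "grid")
})

test_that("ln_abf is increasing in |z| and stable out to |z| = 40", {
  vals <- ln_abf(seq(0, 40, by = 0.5), 0.1)
  expect_true(all(diff(vals) > 0))
  expect_true(all(is.finite(vals)))
})

test_that("region posteriors obey the closed-form mixture arithmetic", {
  # single variant with BF = 1 carries no evidence: posterior = prior
  d1 <- tibble::tibble(variant_id = "a", pos = 1, ln_bf = 0)
  p1 <- region_posterior(d1, NULL, regional_logit = 0)
  expect_equal(p1$prior, 1)
  expect_equal(p1$ppa, 0.5)
  expect_equal(attr(p1, "region_signal_prob"), 0.5)

  # symmetry: equal BFs and no annotations split mass equally
  d2 <- tibble::tibble(variant_id = c("a", "b"), pos = 1:2, ln_bf = c(3, 3))
  p2 <- region_posterior(d2, NULL, regional_logit = -1)
  expect_equal(p2$ppa[1], p2$ppa[2])

  # direct enumeration: BF = (10, 5, 1), flat prior, Pi = 0.1
  d3 <- tibble::tibble(variant_id = c("a", "b", "c"), pos = 1:3,
                       ln_bf = log(c(10, 5, 1)))
  p3 <- region_posterior(d3, NULL, regional_logit = stats::qlogis(0.1))
  oracle <- oracle_region_posterior(c(10, 5, 1), rep(1, 3), 0.1)
  expect_equal(p3$ppa, oracle$ppa, tolerance = 1e-12)
  expect_equal(p3$conditional_post, oracle$conditional_post, tolerance = 1e-12)
  expect_equal(attr(p3, "region_signal_prob"), oracle$region_signal_prob,
               tolerance = 1e-12)

  expect_error(region_posterior(d3[0, ], NULL, 0), "no variants")
})

test_that("posterior mass is conserved and ordered on random regions", {
  withr::with_seed(202, {
    for (i in 1:200) {
      n <- sample(2:30, 1)
      d <- tibble::tibble(
        variant_id = sprintf("v%d", 1:n), pos = sample.int(1e6, n),
        ln_bf = stats::rnorm(n, 0, 5),
        ann = stats::rbinom(n, 1, 0.3)
      )
      lam <- c(ann = stats::rnorm(1))
      logit <- stats::rnorm(1, 0, 2)
      p <- region_posterior(d, lam, logit)
      rsp <- attr(p, "region_signal_prob")
      expect_equal(sum(p$ppa), rsp, tolerance = 1e-9)
      expect_equal(sum(p$prior), 1, tolerance = 1e-9)
      expect_true(all(p$ppa >= 0 & p$ppa <= rsp + 1e-12))
    }
  })
})

test_that("region signal probability is monotone in the regional prior and in each BF", {
  d <- tibble::tibble(variant_id = c("a", "b"), pos = 1:2, ln_bf = c(1, 2))
  rsp <- vapply(seq(-4, 4, by = 0.5), function(a) {
    attr(region_posterior(d, NULL, a), "region_signal_prob")
  }, numeric(1))
  expect_true(all(diff(rsp) > 0))

  rsp2 <- vapply(seq(0, 5, by = 0.5), function(lb) {
    d2 <- d; d2$ln_bf[1] <- lb
    attr(region_posterior(d2, NULL, 0), "region_signal_prob")
  }, numeric(1))
  expect_true(all(diff(rsp2) > 0))
})

test_that("credible sets are the smallest qualifying prefix", {
  mk <- function(mass, pos = seq_along(mass)) {
    tibble::tibble(variant_id = sprintf("v%d", seq_along(mass)), pos = pos,
                   conditional_post = mass, ppa = mass)
  }
  expect_equal(nrow(credible_set(mk(c(0.6, 0.3, 0.05, 0.05)), 0.95)), 3L)
  expect_equal(nrow(credible_set(mk(c(0.6, 0.3, 0.05, 0.05)), 1.0)), 4L)
  expect_error(credible_set(mk(c(1)), 0), "level")

  # ties broken by genomic position ascending
  tied <- credible_set(mk(c(0.5, 0.25, 0.25), pos = c(5, 30, 10)), 0.75)
  expect_equal(tied$variant_id, c("v1", "v3"))

  # brute force over prefixes on random masses
  withr::with_seed(303, {
    for (i in 1:50) {
      m <- stats::runif(20)
      m <- m / sum(m)
      cs <- credible_set(mk(m), 0.95)
      ord <- order(-m, seq_along(m))
      k <- which(cumsum(m[ord]) >= 0.95)[1]
      expect_equal(nrow(cs), k)
      expect_setequal(cs$variant_id, sprintf("v%d", ord[seq_len(k)]))
    }
  })
})

test_that("finemap_locus reproduces degenerate and null-model identities", {
  d <- tibble::tibble(variant_id = "solo", chrom = "chr1", pos = 5e5,
                      ln_bf = 10, ann = 1L)
  fm <- finemap_locus(d, "solo")
  expect_equal(attr(fm, "credible_set_post")$variant_id, "solo")

  expect_error(finemap_locus(d, "nope"), "not found")

  withr::with_seed(404, {
    n <- 50
    d2 <- tibble::tibble(
      variant_id = sprintf("v%d", 1:n), chrom = "chr1",
      pos = sort(sample.int(1e6, n)),
      ln_bf = stats::rnorm(n, 0, 4),
      ann = stats::rbinom(n, 1, 0.3)
    )
  })
  null_model <- structure(list(lambda = c(ann = 0), regional_logit = stats::qlogis(0.2)),
                          class = "enrichment_model")
  fm2 <- finemap_locus(d2, d2$variant_id[25], model = null_model)
  expect_equal(fm2$updated_ppa, fm2$original_ppa)

  # window restriction: only variants within the flanks enter
  lead <- d2[25, ]
  fm3 <- finemap_locus(d2, lead$variant_id, window_bp = 2e5)
  expect_true(all(abs(fm3$pos - lead$pos) <= 1e5))
  fm4 <- finemap_locus(d2, lead$variant_id, window_bp = 2e5, flank = "each_side")
  expect_true(all(abs(fm4$pos - lead$pos) <= 2e5))
  expect_gte(nrow(fm4), nrow(fm3))
})

test_that("enrichment-updated PPAs favour the planted causal variant", {
  cfg <- sim_gwas_config(800, 25, c(atac = 0.2), 1.5, 0.7, 6, 0.007, seed = 505)
  sim <- simulate_gwas_dataset(cfg)
  d <- add_ln_bf(sim$variants)
  model <- fit_model(d, "atac", penalty = 0.3)
  truth <- sim$truth$causal
  causal_ids <- truth$causal_variant[!is.na(truth$causal_variant)]
  improved <- vapply(causal_ids, function(id) {
    row <- d[d$variant_id == id, ]
    if (row$atac != 1) return(NA)
    blk <- d[d$block_id == row$block_id, ]
    p0 <- region_posterior(blk, NULL, model$regional_logit)
    p1 <- region_posterior(blk, model$lambda, model$regional_logit)
    p1$ppa[p1$variant_id == id] >= p0$ppa[p0$variant_id == id]
  }, logical(1))
  improved <- improved[!is.na(improved)]
  expect_gte(length(improved), 100)
  expect_gte(mean(improved), 0.8)
})

test_that("credible-set summaries reproduce the reduction arithmetic", {
  expect_equal(summarize_credible_sets(28.9, 23.5)$pct_reduction, 19)
  expect_equal(summarize_credible_sets(c(10, 20), c(10, 20))$pct_reduction, 0)
  s <- summarize_credible_sets(c(30, 20), c(24, 16))
  expect_equal(s$mean_pre, 25)
  expect_equal(s$mean_post, 20)
  expect_equal(s$pct_reduction, 20)
  expect_error(summarize_credible_sets(c(1, 2), 1), "paired")
})
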