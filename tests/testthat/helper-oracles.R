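# Independent oracles used to cross-check the package's implementations.
# These deliberately share no code with the package internals: plain
# arithmetic, explicit loops, no log-space tricks.

# Wakefield ABF by numerical integration of the marginal likelihood ratio:
# integral N(bhat; b, V) N(b; 0, W) db / N(bhat; 0, V).
oracle_abf_quadrature <- function(z, se, W) {
  V <- se^2
  bhat <- z * se
  num <- stats::integrate(function(b) {
    stats::dnorm(bhat, mean = b, sd = sqrt(V)) * stats::dnorm(b, 0, sqrt(W))
  }, -Inf, Inf, rel.tol = 1e-12, abs.tol = 0)$value
  num / stats::dnorm(bhat, 0, sqrt(V))
}

# Two-component mixture posterior for one region by direct summation.
oracle_region_posterior <- function(bf, prior_weights, Pi) {
  pi_i <- prior_weights / sum(prior_weights)
  R <- sum(pi_i * bf)
  denom <- (1 - Pi) + Pi * R
  list(
    region_signal_prob = Pi * R / denom,
    conditional_post = pi_i * bf / R,
    ppa = (Pi * R / denom) * (pi_i * bf / R)
  )
}

# Penalized mixture log-likelihood by per-block loops in linear space.
oracle_penalized_loglik <- function(data, lambda, Pi, penalty) {
  total <- 0
  for (b in unique(data$block_id)) {
    rows <- data[data$block_id == b, , drop = FALSE]
    w <- if (length(lambda) > 0L) {
      exp(as.matrix(rows[names(lambda)]) %*% lambda)[, 1L]
    } else {
      rep(1, nrow(rows))
    }
    pi_i <- w / sum(w)
    R <- sum(pi_i * exp(rows$ln_bf))
    total <- total + log((1 - Pi) + Pi * R)
  }
  total - penalty * sum(lambda^2)
}

# Two-sided minimum-likelihood binomial p at 0.5 from first principles
# (binomial coefficients, no dbinom).
oracle_binom_p <- function(ref, alt) {
  n <- ref + alt
  pmf <- choose(n, 0:n) * 0.5^n
  obs <- pmf[alt + 1L]
  min(1, sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

# Base-pair Jaccard by explicit per-base membership.
oracle_jaccard_perbase <- function(a, b) {
  cover <- function(x) {
    out <- character(0)
    for (i in seq_len(nrow(x))) {
      if (x$end[i] > x$start[i]) {
        out <- c(out, paste0(x$chrom[i], ":", seq(x$start[i], x$end[i] - 1L)))
      }
    }
    unique(out)
  }
  ca <- cover(a)
  cb <- cover(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

# Random small interval set on 1-2 chromosomes for oracle comparisons.
random_peak_set <- function(n = 5, span = 200) {
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE)
  len <- sample.int(30, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start, end = start + len)
}

# Tiny fine-mapping dataset built directly (no simulator): n_blocks blocks of
# block_size variants with explicit ln BFs and one annotation.
toy_block_data <- function(n_blocks = 3, block_size = 4, seed = 1) {
  withr::with_seed(seed, {
    n <- n_blocks * block_size
    tibble::tibble(
      variant_id = sprintf("v%d", seq_len(n)),
      chrom = "chr1",
      pos = seq_len(n) * 100,
      block_id = rep(seq_len(n_blocks), each = block_size),
      ln_bf = stats::rnorm(n, 0, 2),
      ann = stats::rbinom(n, 1, 0.4)
    )
  })
}
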