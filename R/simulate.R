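# Synthetic-data generators. These plant ground truth under exactly the
# statistical structure the downstream model assumes (single causal variant
# per block, log-linear annotation enrichment), so recovery and calibration
# are testable without external data. Variants carry no linkage
# disequilibrium: nulls are independent and at most one causal variant exists
# per block — a deliberate simplification relative to real GWAS loci.

#' Configuration for the GWAS summary-statistic simulator
#'
#' @param n_blocks Number of 1-Mb blocks (>= 1).
#' @param variants_per_block Variants per block (>= 2), evenly spaced so each
#'   block spans exactly 1 Mb of a single synthetic chromosome.
#' @param annotation_specs Named numeric vector: per-variant marking fraction
#'   for each annotation, each in (0, 1). May be empty.
#' @param lambda_true ln-OR enrichment effect per annotation; same length as
#'   `annotation_specs`.
#' @param pi_regional Probability in (0, 1) that a block carries a causal
#'   variant.
#' @param causal_z_mean Expected |Z| of causal variants (> 0); the causal Z
#'   is drawn from Normal(`causal_z_mean`, 1) with random sign.
#' @param se_value Constant standard error (> 0) used for all variants.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A validated list of class `sim_gwas_config`.
#' @export
sim_gwas_config <- function(n_blocks, variants_per_block, annotation_specs = numeric(0),
                            lambda_true = numeric(0), pi_regional, causal_z_mean,
                            se_value, seed = 1) {
  assert_count(n_blocks, "n_blocks", min = 1L)
  assert_count(variants_per_block, "variants_per_block", min = 2L)
  assert_scalar_number(pi_regional, "pi_regional")
  if (pi_regional <= 0 || pi_regional >= 1) stop_field("pi_regional", "must lie in (0, 1)")
  assert_scalar_number(causal_z_mean, "causal_z_mean")
  if (causal_z_mean <= 0) stop_field("causal_z_mean", "must be > 0")
  assert_scalar_number(se_value, "se_value")
  if (se_value <= 0) stop_field("se_value", "must be > 0")
  assert_count(seed, "seed")
  if (length(annotation_specs) != length(lambda_true)) {
    stop_field("lambda_true", "must have one effect per annotation in `annotation_specs`")
  }
  if (length(annotation_specs) > 0L) {
    if (is.null(names(annotation_specs)) || any(!nzchar(names(annotation_specs)))) {
      stop_field("annotation_specs", "must be a named vector of marking fractions")
    }
    if (any(annotation_specs <= 0 | annotation_specs >= 1)) {
      stop_field("annotation_specs", "marking fractions must lie in (0, 1)")
    }
  }
  structure(list(
    n_blocks = as.integer(n_blocks),
    variants_per_block = as.integer(variants_per_block),
    annotation_specs = annotation_specs,
    lambda_true = stats::setNames(lambda_true, names(annotation_specs)),
    pi_regional = pi_regional,
    causal_z_mean = causal_z_mean,
    se_value = se_value,
    seed = as.integer(seed)
  ), class = "sim_gwas_config")
}

#' Simulate GWAS summary statistics with planted causal variants
#'
#' Annotations are first assigned to each variant independently with the
#' configured marking fractions. Each block then independently carries a
#' causal variant with probability `pi_regional`; within a signal block the
#' causal variant is chosen with probability proportional to
#' \eqn{\exp(x_i \cdot \lambda_{true})}. Causal variants draw
#' Z ~ Normal(`causal_z_mean`, 1) with random sign; null variants draw
#' Z ~ Normal(0, 1); `beta = Z * se` everywhere. Positions lie on one
#' synthetic chromosome (`chrS`) at fixed spacing so blocks are exactly 1 Mb
#' and [segment_blocks()] reproduces the design.
#'
#' @param config A [sim_gwas_config()].
#' @return A list of class `sim_gwas` with elements `variants` (tibble with
#'   `variant_id`, `chrom`, `pos`, `beta`, `se`, `z`, `block_id`, and one 0/1
#'   column per annotation) and `truth` (list with `causal` — tibble of
#'   `block_id`, `causal_variant` (`NA` for null blocks) — plus
#'   `lambda_true` and `pi_regional`).
#' @export
simulate_gwas_dataset <- function(config) {
  stopifnot(inherits(config, "sim_gwas_config"))
  withr::with_seed(config$seed, {
    nb <- config$n_blocks
    vpb <- config$variants_per_block
    n <- nb * vpb
    K <- length(config$annotation_specs)
    block <- rep(seq_len(nb), each = vpb)
    within <- rep(seq_len(vpb), times = nb)
    pos <- (block - 1L) * 1e6 + floor((within - 1) * 1e6 / vpb) + 1
    X <- matrix(0L, n, K)
    for (k in seq_len(K)) {
      X[, k] <- stats::rbinom(n, 1L, config$annotation_specs[[k]])
    }
    signal <- stats::rbinom(nb, 1L, config$pi_regional) == 1L
    eta <- if (K > 0L) drop(X %*% config$lambda_true) else numeric(n)
    causal_idx <- rep(NA_integer_, nb)  # index within block
    for (b in which(signal)) {
      rows <- ((b - 1L) * vpb + 1L):(b * vpb)
      w <- exp(eta[rows] - max(eta[rows]))
      causal_idx[b] <- sample.int(vpb, 1L, prob = w)
    }
    z <- stats::rnorm(n)
    is_causal <- logical(n)
    for (b in which(signal)) {
      i <- (b - 1L) * vpb + causal_idx[b]
      is_causal[i] <- TRUE
      z[i] <- sample(c(-1, 1), 1L) * stats::rnorm(1L, config$causal_z_mean, 1)
    }
    variant_id <- sprintf("v%d_%d", block, within)
    variants <- tibble::tibble(
      variant_id = variant_id,
      chrom = "chrS",
      pos = as.numeric(pos),
      beta = z * config$se_value,
      se = config$se_value,
      z = z,
      block_id = block
    )
    if (K > 0L) {
      for (k in seq_len(K)) variants[[names(config$annotation_specs)[k]]] <- X[, k]
    }
    causal_variant <- ifelse(signal, sprintf("v%d_%d", seq_len(nb), causal_idx), NA_character_)
    structure(list(
      variants = variants,
      truth = list(
        causal = tibble::tibble(block_id = seq_len(nb),
                                causal_variant = causal_variant),
        lambda_true = config$lambda_true,
        pi_regional = config$pi_regional
      )
    ), class = "sim_gwas")
  })
}

#' Write a simulated GWAS dataset to disk
#'
#' Emits the same delimited summary-statistic format [read_summary_stats()]
#' reads, one BED file per annotation, and a JSON truth file.
#'
#' @param sim A [simulate_gwas_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_gwas <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_stats(sim$variants, file.path(dir, "summary_stats.tsv"))
  for (a in names(sim$truth$lambda_true)) {
    marked <- sim$variants[sim$variants[[a]] == 1, ]
    bed <- tibble::tibble(chrom = marked$chrom,
                          start = marked$pos - 1,
                          end = marked$pos)
    write_bed(bed, file.path(dir, paste0(a, ".bed")))
  }
  jsonlite::write_json(
    list(causal = sim$truth$causal,
         lambda_true = as.list(sim$truth$lambda_true),
         pi_regional = sim$truth$pi_regional),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Simulate heterozygous-site allelic read counts
#'
#' Per sample, a total read depth is drawn (negative binomial with the given
#' mean and dispersion; dispersion 0 gives a constant depth of
#' `round(mean_depth)`), and the alternative-allele count is
#' Binomial(depth, `theta`). All sites are labelled heterozygous with
#' mappability passing, since only such sites enter allele-specific testing.
#'
#' @param n_samples Number of samples (>= 0; 0 returns an empty tibble).
#' @param mean_depth Mean total read depth (> 0).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 for constant depth.
#' @param theta Probability in (0, 1) that a read carries the alternative
#'   allele (0.5 = no imbalance).
#' @param site_id Site label recycled across samples.
#' @param seed Integer seed.
#' @return Tibble with columns `sample_id`, `site_id`, `ref_count`,
#'   `alt_count`, `genotype`, `mappability_ok`.
#' @export
simulate_allele_counts <- function(n_samples, mean_depth, dispersion = 0,
                                   theta = 0.5, site_id = "site1", seed = 1) {
  assert_count(n_samples, "n_samples", min = 0L)
  assert_scalar_number(mean_depth, "mean_depth")
  if (mean_depth <= 0) stop_field("mean_depth", "must be > 0")
  assert_scalar_number(dispersion, "dispersion")
  if (dispersion < 0) stop_field("dispersion", "must be >= 0")
  assert_scalar_number(theta, "theta")
  if (theta <= 0 || theta >= 1) stop_field("theta", "must lie in (0, 1)")
  if (n_samples == 0L) {
    return(tibble::tibble(sample_id = character(), site_id = character(),
                          ref_count = integer(), alt_count = integer(),
                          genotype = character(), mappability_ok = logical()))
  }
  withr::with_seed(seed, {
    depth <- if (dispersion == 0) {
      rep(as.integer(round(mean_depth)), n_samples)
    } else {
      stats::rnbinom(n_samples, size = 1 / dispersion, mu = mean_depth)
    }
    alt <- stats::rbinom(n_samples, depth, theta)
    tibble::tibble(
      sample_id = sprintf("s%d", seq_len(n_samples)),
      site_id = site_id,
      ref_count = as.integer(depth - alt),
      alt_count = as.integer(alt),
      genotype = "het",
      mappability_ok = TRUE
    )
  })
}

#' Simulate a pair of peak interval sets with controlled overlap
#'
#' Generates `n_intervals` non-overlapping intervals of equal length on one
#' synthetic chromosome, then shifts every interval by
#' `shift_fraction * interval_length` to form the second set. For shift
#' fraction s, each interval pair overlaps by `(1 - s) * L` over a union of
#' `(1 + s) * L`, so the base-pair Jaccard similarity of the two sets is
#' exactly `(1 - s) / (1 + s)`.
#'
#' @param n_intervals Number of intervals (>= 1).
#' @param interval_length Interval length in bp (>= 1).
#' @param shift_fraction Shift as a fraction of the interval length, in
#'   \[0, 1\].
#' @param seed Integer seed (jitters the inter-interval gaps).
#' @return List with elements `a` and `b` (peak-set tibbles with `name`,
#'   `chrom`, `start`, `end`) and `expected_jaccard`.
#' @export
simulate_peak_sets <- function(n_intervals, interval_length, shift_fraction, seed = 1) {
  assert_count(n_intervals, "n_intervals", min = 1L)
  assert_count(interval_length, "interval_length", min = 1L)
  assert_scalar_number(shift_fraction, "shift_fraction")
  if (shift_fraction < 0 || shift_fraction > 1) {
    stop_field("shift_fraction", "must lie in [0, 1]")
  }
  withr::with_seed(seed, {
    # gaps of at least 2L between interval starts guarantee both the original
    # and the shifted set are non-overlapping
    gaps <- sample.int(interval_length, n_intervals, replace = TRUE)
    start <- cumsum(c(0, rep(3 * interval_length, n_intervals - 1L))) +
      cumsum(gaps) - gaps[[1L]]
    shift <- round(shift_fraction * interval_length)
    a <- tibble::tibble(name = "set_a", chrom = "chrS",
                        start = as.numeric(start),
                        end = as.numeric(start + interval_length))
    b <- tibble::tibble(name = "set_b", chrom = "chrS",
                        start = a$start + shift, end = a$end + shift)
    list(a = a, b = b,
         expected_jaccard = (1 - shift_fraction) / (1 + shift_fraction))
  })
}
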