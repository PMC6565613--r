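#' Exact binomial test for allelic imbalance at one site
#'
#' Two-sided exact binomial p-value for the observed reference/alternative
#' read counts against the expected 50% frequency at a heterozygous site.
#' The two-sided p is the minimum-likelihood definition: the sum of
#' probabilities of all outcomes whose point probability under
#' Binomial(n, 0.5) is no greater than that of the observed count, capped at
#' 1. Set `method = "double"` for the doubled-smaller-tail alternative.
#'
#' @param ref_count,alt_count Non-negative read counts; total must be >= 1.
#'   Vectorized (recycled to common length).
#' @param method `"min_lik"` (default) or `"double"`.
#' @return Numeric vector of p-values in \[0, 1\].
#' @examples
#' binomial_ase(5, 5)    # 1
#' binomial_ase(0, 10)   # 2 * 0.5^10
#' @export
binomial_ase <- function(ref_count, alt_count, method = c("min_lik", "double")) {
  method <- match.arg(method)
  n <- max(length(ref_count), length(alt_count))
  ref_count <- rep_len(ref_count, n)
  alt_count <- rep_len(alt_count, n)
  if (any(ref_count < 0 | alt_count < 0)) stop("read counts must be >= 0", call. = FALSE)
  tot <- ref_count + alt_count
  if (any(tot < 1)) stop("total read depth must be >= 1", call. = FALSE)
  vapply(seq_len(n), function(i) {
    size <- tot[[i]]
    x <- alt_count[[i]]
    d <- stats::dbinom(0:size, size, 0.5)
    p <- if (method == "min_lik") {
      # relative tolerance guards against ties broken by floating-point noise
      sum(d[d <= d[[x + 1L]] * (1 + 1e-7)])
    } else {
      2 * min(stats::pbinom(x, size, 0.5),
              stats::pbinom(size - x, size, 0.5))
    }
    min(p, 1)
  }, numeric(1))
}

#' Meta-analysis of allele-specific signal across heterozygous samples
#'
#' Computes a per-sample exact binomial p-value ([binomial_ase()]) at every
#' eligible (heterozygous, nonzero-depth) sample and combines them into one
#' meta-analysis p-value. The default combination is Stouffer's method on
#' signed per-sample Z scores — sign positive when the alternative-allele
#' fraction exceeds 0.5 — weighted by the square root of each sample's total
#' read depth, so discordant samples cancel. `method = "pooled"` instead
#' pools raw counts across samples into a single binomial test.
#'
#' @param counts Tibble with `sample_id`, `ref_count`, `alt_count` and
#'   (optionally) `genotype`; rows with `genotype` other than `"het"` are
#'   dropped.
#' @param method `"stouffer"` (default) or `"pooled"`.
#' @return A list of class `ase_result`: `per_sample` (tibble of
#'   `sample_id`, `p_value`, `alt_fraction`), `meta_p`, `n_het`, and
#'   `direction` (`"alt"`, `"ref"` or `"none"` from the pooled alternative
#'   fraction).
#' @export
meta_ase <- function(counts, method = c("stouffer", "pooled")) {
  method <- match.arg(method)
  if (!is.null(counts$genotype)) {
    counts <- dplyr::filter(counts, .data$genotype == "het")
  }
  counts <- dplyr::filter(counts, .data$ref_count + .data$alt_count >= 1)
  if (nrow(counts) == 0L) {
    stop("no eligible heterozygous samples with nonzero depth", call. = FALSE)
  }
  depth <- counts$ref_count + counts$alt_count
  frac <- counts$alt_count / depth
  p <- binomial_ase(counts$ref_count, counts$alt_count)
  per_sample <- tibble::tibble(sample_id = counts$sample_id,
                               p_value = p, alt_fraction = frac)
  pooled_frac <- sum(counts$alt_count) / sum(depth)
  if (nrow(counts) == 1L) {
    meta_p <- p[[1L]]
  } else if (method == "stouffer") {
    # |z| from the two-sided p, sign from the direction of imbalance
    z <- sign(frac - 0.5) * stats::qnorm(pmin(p, 1) / 2, lower.tail = FALSE)
    w <- sqrt(depth)
    meta_z <- sum(w * z) / sqrt(sum(w^2))
    meta_p <- 2 * stats::pnorm(-abs(meta_z))
  } else {
    meta_p <- binomial_ase(sum(counts$ref_count), sum(counts$alt_count))
  }
  structure(list(
    per_sample = per_sample,
    meta_p = meta_p,
    n_het = nrow(counts),
    direction = if (pooled_frac > 0.5) "alt" else if (pooled_frac < 0.5) "ref" else "none"
  ), class = "ase_result")
}

#' Probability that all subjects are homozygous reference
#'
#' Under Hardy-Weinberg equilibrium and independence across subjects, the
#' probability that `n_subjects` subjects all carry the homozygous reference
#' genotype is the squared reference-allele frequency raised to the number
#' of subjects, \eqn{(f^2)^n}.
#'
#' @param ref_allele_freq Reference-allele frequency in \[0, 1\].
#' @param n_subjects Number of subjects (>= 1).
#' @return The probability.
#' @examples
#' all_homref_probability(0.48, 4)  # ~0.003
#' @export
all_homref_probability <- function(ref_allele_freq, n_subjects) {
  assert_scalar_number(ref_allele_freq, "ref_allele_freq")
  if (ref_allele_freq < 0 || ref_allele_freq > 1) {
    stop_field("ref_allele_freq", "must lie in [0, 1]")
  }
  assert_count(n_subjects, "n_subjects", min = 1L)
  (ref_allele_freq^2)^n_subjects
}

#' Site filters for RNA allele-specific expression
#'
#' Retains heterozygous sites where (a) the reference or the alternative
#' allele has strictly more than `min_allele_reads` supporting read pairs,
#' (b) the reference allele frequency lies strictly between the bounds
#' (default 2%–98%), and (c) the site passes mappability when
#' `require_mappability` is set and a `mappability_ok` column is present.
#'
#' @param counts Tibble with `ref_count`, `alt_count` and optionally
#'   `genotype` and `mappability_ok` columns.
#' @param min_allele_reads Read-pair support threshold (strict inequality);
#'   default 8.
#' @param ref_freq_bounds Exclusive bounds on the reference allele
#'   frequency; default `c(0.02, 0.98)`.
#' @param require_mappability Drop sites failing mappability (default TRUE).
#' @return The retained rows, in input order.
#' @export
filter_ase_sites <- function(counts, min_allele_reads = 8,
                             ref_freq_bounds = c(0.02, 0.98),
                             require_mappability = TRUE) {
  if (!(ref_freq_bounds[[1L]] >= 0 && ref_freq_bounds[[1L]] < ref_freq_bounds[[2L]] &&
        ref_freq_bounds[[2L]] <= 1)) {
    stop_field("ref_freq_bounds", "must satisfy 0 <= lower < upper <= 1")
  }
  keep <- rep(TRUE, nrow(counts))
  if (!is.null(counts$genotype)) keep <- keep & counts$genotype == "het"
  tot <- counts$ref_count + counts$alt_count
  keep <- keep & tot > 0
  keep <- keep & (counts$ref_count > min_allele_reads |
                    counts$alt_count > min_allele_reads)
  rf <- counts$ref_count / pmax(tot, 1)
  keep <- keep & rf > ref_freq_bounds[[1L]] & rf < ref_freq_bounds[[2L]]
  if (require_mappability && !is.null(counts$mappability_ok)) {
    keep <- keep & counts$mappability_ok
  }
  counts[keep & !is.na(keep), , drop = FALSE]
}

#' Read an allele-count table
#'
#' Reads the tab-delimited allele-count format (columns `sample`/`sample_id`,
#' `site`/`site_id`, `ref_count`, `alt_count`, and optionally `chrom`, `pos`,
#' `genotype`, `mappability`/`mappability_ok`).
#'
#' @param path Path to a TSV file with a header.
#' @return Tibble with standardized column names.
#' @export
read_allele_counts <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(raw))
  pick <- function(aliases) {
    i <- which(nm %in% aliases)
    if (length(i) == 0L) NULL else raw[[i[[1L]]]]
  }
  out <- tibble::tibble(
    sample_id = as.character(pick(c("sample", "sample_id")) %||%
                               stop("missing sample column", call. = FALSE)),
    site_id = as.character(pick(c("site", "site_id")) %||%
                             stop("missing site column", call. = FALSE)),
    ref_count = as.integer(pick(c("ref_count", "refcount", "ref"))),
    alt_count = as.integer(pick(c("alt_count", "altcount", "alt")))
  )
  if (any(is.na(out$ref_count)) || any(is.na(out$alt_count)) ||
      any(out$ref_count < 0) || any(out$alt_count < 0)) {
    stop("ref/alt counts must be non-negative integers", call. = FALSE)
  }
  gt <- pick("genotype")
  if (!is.null(gt)) out$genotype <- as.character(gt)
  mp <- pick(c("mappability", "mappability_ok"))
  if (!is.null(mp)) out$mappability_ok <- as.logical(mp)
  out
}
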