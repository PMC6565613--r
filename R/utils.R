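# Internal numerical helpers. All likelihood work is done in log space so that
# Bayes factors for |z| up to ~40 (ln BF ~ 800) never overflow.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Pairwise log(exp(a) + exp(b)), vectorized.
lse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Grouped logsumexp. `g` must be a dense integer vector with groups 1..ng all
# present; returns a vector of length ng in group order.
grouped_lse <- function(x, g, ng) {
  m <- as.numeric(tapply(x, g, max))
  s <- rowsum(exp(x - m[g]), g, reorder = TRUE)
  m + log(as.numeric(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_scalar_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  invisible(x)
}

assert_count <- function(x, field, min = 0L) {
  assert_scalar_number(x, field)
  if (x != floor(x) || x < min) {
    stop_field(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}
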