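# Penalized hierarchical enrichment model.
#
# Likelihood: each ~1-Mb block either carries no causal variant (prob 1 - Pi)
# or exactly one (prob Pi), in which case variant i is causal with prior
# pi_i = softmax(x_i . lambda) over the block. Marginalizing,
#   L_b = (1 - Pi) + Pi * sum_i pi_i BF_i ,
# and the fitted objective is sum_b ln L_b - penalty * sum_k lambda_k^2
# (ridge on annotation effects only; the regional intercept is unpenalized).
# Everything is accumulated in log space; the gradient below is analytic.

# Reserved column names that are never treated as annotations.
.reserved_cols <- c("variant_id", "chrom", "pos", "ref", "alt", "beta", "se",
                    "z", "freq", "ln_bf", "block_id", "block_start",
                    "block_end", "prior", "conditional_post", "ppa")

#' Annotation columns of a variant table
#'
#' Returns the columns of `data` that look like binary annotation incidence
#' columns: every standard column (`variant_id`, `chrom`, `pos`, `beta`,
#' `se`, `z`, `freq`, `ln_bf`, `block_*`, posterior columns) is excluded and
#' the remainder must contain only 0/1 values.
#'
#' @param data Variant tibble.
#' @return Character vector of annotation column names.
#' @export
annotation_columns <- function(data) {
  cand <- setdiff(names(data), .reserved_cols)
  keep <- vapply(cand, function(nm) {
    v <- data[[nm]]
    is.numeric(v) && all(v %in% c(0, 1))
  }, logical(1))
  cand[keep]
}

# Precompute the structures the likelihood needs: ln BF vector, annotation
# matrix, dense block codes and per-block index lists.
mix_prepare <- function(data, annotations) {
  if (is.null(data$ln_bf)) stop("`data` must have an `ln_bf` column (see add_ln_bf)", call. = FALSE)
  if (is.null(data$block_id)) stop("`data` must have a `block_id` column (see segment_blocks)", call. = FALSE)
  g <- match(data$block_id, sort(unique(data$block_id)))
  ng <- max(g)
  X <- if (length(annotations) > 0L) {
    as.matrix(data[annotations])
  } else {
    matrix(0, nrow(data), 0L)
  }
  list(lnbf = data$ln_bf, X = X, g = g, ng = ng, n = nrow(data),
       annotations = annotations)
}

# Unpenalized mixture log-likelihood and, optionally, its analytic gradient
# with respect to (lambda, regional_logit).
mix_loglik <- function(prep, lambda, alpha, gradient = FALSE) {
  eta <- if (length(lambda) > 0L) drop(prep$X %*% lambda) else numeric(prep$n)
  lnZ <- grouped_lse(eta, prep$g, prep$ng)
  lnA <- grouped_lse(eta + prep$lnbf, prep$g, prep$ng)
  lnR <- lnA - lnZ
  ln_Pi <- stats::plogis(alpha, log.p = TRUE)
  ln_1mPi <- stats::plogis(-alpha, log.p = TRUE)
  lnD <- lse2(rep(ln_1mPi, prep$ng), ln_Pi + lnR)
  ll <- sum(lnD)
  if (!gradient) return(ll)

  r <- exp(ln_Pi + lnR - lnD)              # per-block signal posterior
  Pi <- exp(ln_Pi)
  # d/d alpha: Pi (1 - Pi) (R - 1) / D, written in overflow-safe form
  d_alpha <- sum((1 - Pi) * r - Pi * (1 - r))
  if (length(lambda) > 0L) {
    w_prior <- exp(eta - lnZ[prep$g])
    w_post <- exp(eta + prep$lnbf - lnA[prep$g])
    E_prior <- rowsum(prep$X * w_prior, prep$g, reorder = TRUE)
    E_post <- rowsum(prep$X * w_post, prep$g, reorder = TRUE)
    d_lambda <- drop(crossprod(E_post - E_prior, r))
  } else {
    d_lambda <- numeric(0)
  }
  list(loglik = ll, grad = c(d_lambda, d_alpha))
}

#' Penalized mixture log-likelihood of an enrichment model
#'
#' Evaluates \deqn{\sum_b \ln[(1-\Pi) + \Pi \sum_i \pi_i BF_i] - p \sum_k \lambda_k^2}
#' over all blocks of a variant table, in log space.
#'
#' @param data Variant tibble with `ln_bf`, `block_id` and the annotation
#'   columns named in `names(lambda)` (see [segment_blocks()],
#'   [add_ln_bf()], [annotate_variants()]).
#' @param lambda Named annotation-effect vector (ln odds); may be empty.
#' @param regional_logit Log-odds of the regional signal prior.
#' @param penalty Ridge weight `p >= 0` applied to `sum(lambda^2)` only.
#' @return The penalized log-likelihood (a single number).
#' @export
penalized_loglik <- function(data, lambda = NULL, regional_logit, penalty = 0.3) {
  lambda <- lambda %||% stats::setNames(numeric(0), character(0))
  assert_scalar_number(regional_logit, "regional_logit")
  assert_scalar_number(penalty, "penalty")
  if (penalty < 0) stop_field("penalty", "must be >= 0")
  prep <- mix_prepare(data, names(lambda))
  mix_loglik(prep, lambda, regional_logit) - penalty * sum(lambda^2)
}

# Shared optimizer: maximize the penalized likelihood over (lambda, alpha).
# The likelihood plateaus in alpha as Pi -> 0 or 1 (its gradient vanishes
# exponentially), so a raw quasi-Newton run from a distant start can strand
# on the plateau. The intercept is therefore warm-started by a 1-D search at
# the initial lambda, and each BFGS run is followed by a coordinate polish
# (re-optimize alpha at the current lambda, restart BFGS if that helps).
fit_optim <- function(prep, penalty, lambda_init, reltol = 1e-10) {
  K <- length(prep$annotations)
  fn <- function(par) {
    -(mix_loglik(prep, par[seq_len(K)], par[K + 1L]) -
        penalty * sum(par[seq_len(K)]^2))
  }
  gr <- function(par) {
    g <- mix_loglik(prep, par[seq_len(K)], par[K + 1L], gradient = TRUE)$grad
    if (K > 0L) g[seq_len(K)] <- g[seq_len(K)] - 2 * penalty * par[seq_len(K)]
    -g
  }
  best_alpha <- function(lambda, lower = -12, upper = 12) {
    stats::optimize(function(a) mix_loglik(prep, lambda, a),
                    interval = c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
  }
  run <- function(lambda_start) {
    a <- best_alpha(lambda_start)
    fit <- stats::optim(c(lambda_start, a), fn, gr, method = "BFGS",
                        control = list(maxit = 500L, reltol = reltol))
    for (polish in 1:5) {
      a2 <- best_alpha(fit$par[seq_len(K)])
      cand <- c(fit$par[seq_len(K)], a2)
      if (fn(cand) < fit$value - 1e-9) {
        fit <- stats::optim(cand, fn, gr, method = "BFGS",
                            control = list(maxit = 500L, reltol = reltol))
      } else {
        break
      }
    }
    fit
  }
  fit <- run(lambda_init)
  if (fit$convergence != 0L && K > 0L) {
    for (s in c(0.5, -0.5)) {
      alt <- run(rep(s, K))
      if (alt$value < fit$value || (alt$convergence == 0L && fit$convergence != 0L)) fit <- alt
      if (fit$convergence == 0L) break
    }
  }
  fit
}

#' Fit the annotation enrichment model
#'
#' Maximizes the penalized mixture log-likelihood over the annotation effect
#' vector \eqn{\lambda} and the regional signal log-odds by quasi-Newton
#' (BFGS) ascent with analytic gradients, starting from \eqn{\lambda = 0}
#' and \eqn{\Pi = 0.01}; restarts from \eqn{\lambda = \pm 0.5} if the first
#' run fails to converge.
#'
#' @param data Variant tibble with `ln_bf`, `block_id` and annotation
#'   columns.
#' @param annotations Annotation column names to include; default all columns
#'   identified by [annotation_columns()]. May be empty (intercept-only fit).
#' @param penalty Ridge weight on `sum(lambda^2)`; default 0.30, the
#'   cross-validated value used for the AMD analysis this package supports
#'   (see [cross_validate_penalty()]).
#' @return An object of class `enrichment_model`: a list with elements
#'   `lambda` (named), `regional_logit`, `pi_regional`, `penalty`,
#'   `penalized_loglik`, `loglik` (unpenalized), `converged`, `n_blocks`,
#'   `n_variants`. Supports [tidy()], [glance()] and `autoplot()`.
#' @export
fit_model <- function(data, annotations = annotation_columns(data), penalty = 0.3) {
  if (penalty < 0) stop_field("penalty", "must be >= 0")
  prep <- mix_prepare(data, annotations)
  if (prep$ng < 1L) stop("need at least one block", call. = FALSE)
  K <- length(annotations)
  fit <- fit_optim(prep, penalty, rep(0, K))
  if (fit$convergence != 0L) {
    warning("enrichment model did not converge; returning best iterate", call. = FALSE)
  }
  lambda <- stats::setNames(fit$par[seq_len(K)], annotations)
  alpha <- fit$par[K + 1L]
  structure(list(
    lambda = lambda,
    regional_logit = alpha,
    pi_regional = stats::plogis(alpha),
    penalty = penalty,
    penalized_loglik = -fit$value,
    loglik = mix_loglik(prep, lambda, alpha),
    converged = fit$convergence == 0L,
    n_blocks = prep$ng,
    n_variants = prep$n
  ), class = "enrichment_model")
}

# Profile log-likelihood in lambda for a single annotation: maximize over the
# regional intercept at each fixed lambda.
profile_ll <- function(prep, lambda_val) {
  opt <- stats::optimize(function(a) mix_loglik(prep, lambda_val, a),
                         interval = c(-15, 10), maximum = TRUE, tol = 1e-8)
  opt$objective
}

#' Single-annotation enrichment with profile-likelihood confidence interval
#'
#' Fits the one-annotation model (unpenalized by default) and derives a 95%
#' confidence interval for the enrichment ln(OR) by profile likelihood: the
#' bounds are where the profile log-likelihood (maximized over the regional
#' intercept) drops 1.92 units below its maximum. The annotation is called
#' significant when the interval excludes 0.
#'
#' @inheritParams fit_model
#' @param annotation Name of the annotation column to test.
#' @param penalty Ridge weight for the point estimate; default 0 (the CI is
#'   always computed on the unpenalized likelihood).
#' @param ci_search_limit Absolute search limit for the CI bounds: each bound
#'   is sought between the estimate and `-ci_search_limit` (lower) or
#'   `+ci_search_limit` (upper), extended past the estimate when it lies
#'   outside that range (an annotation marking only causal variants has a
#'   divergent maximum-likelihood estimate but a finite lower bound). A bound
#'   not found within the range is reported as +/-Inf.
#' @return One-row tibble of class `enrichment_ci` with columns `annotation`,
#'   `estimate`, `conf.low`, `conf.high`, `significant`, plus attribute
#'   `model` holding the fitted `enrichment_model`.
#' @export
fit_single <- function(data, annotation, penalty = 0, ci_search_limit = 60) {
  if (!annotation %in% names(data)) {
    stop(sprintf("annotation '%s' not found", annotation), call. = FALSE)
  }
  if (sum(data[[annotation]]) == 0) {
    stop(sprintf("annotation '%s' marks zero variants", annotation), call. = FALSE)
  }
  model <- fit_model(data, annotations = annotation, penalty = penalty)
  prep <- mix_prepare(data, annotation)
  est <- unname(model$lambda)
  ll_max <- profile_ll(prep, est)
  drop_target <- 1.92
  f <- function(l) profile_ll(prep, l) - (ll_max - drop_target)

  bound <- function(direction) {
    limit <- if (direction > 0) max(est, 0) + ci_search_limit else min(est, 0) - ci_search_limit
    step <- 0.25
    prev <- est
    repeat {
      cur <- prev + direction * step
      if (direction * (cur - limit) > 0) return(direction * Inf)
      if (f(cur) < 0) {
        lo <- min(prev, cur); hi <- max(prev, cur)
        return(stats::uniroot(f, c(lo, hi), tol = 1e-6)$root)
      }
      prev <- cur
      step <- step * 2
    }
  }
  lower <- bound(-1)
  upper <- bound(+1)
  out <- tibble::tibble(
    annotation = annotation,
    estimate = est,
    conf.low = lower,
    conf.high = upper,
    significant = (lower > 0) || (upper < 0)
  )
  attr(out, "model") <- model
  class(out) <- c("enrichment_ci", class(out))
  out
}

#' Single-annotation enrichment table for several annotations
#'
#' Maps [fit_single()] over a set of annotations, producing the per-
#' annotation ln(OR) + 95% CI table used to compare candidate annotations.
#'
#' @inheritParams fit_single
#' @param annotations Annotation column names; default all.
#' @return Tibble of class `enrichment_ci` with one row per annotation.
#' @export
fit_single_all <- function(data, annotations = annotation_columns(data), penalty = 0) {
  out <- purrr::map_dfr(annotations, function(a) fit_single(data, a, penalty = penalty))
  class(out) <- c("enrichment_ci", setdiff(class(out), "enrichment_ci"))
  out
}

# Seeded assignment of blocks to k cross-validation folds.
cv_folds <- function(block_ids, k_folds, seed) {
  blocks <- sort(unique(block_ids))
  if (length(blocks) < k_folds) {
    stop("fewer blocks than cross-validation folds", call. = FALSE)
  }
  fold_of_block <- withr::with_seed(seed, sample(rep_len(seq_len(k_folds), length(blocks))))
  fold_of_block[match(block_ids, blocks)]
}

# Total held-out (unpenalized) log-likelihood of a k-fold fit at one penalty.
cv_heldout_ll <- function(data, annotations, penalty, fold) {
  k <- max(fold)
  total <- 0
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    m <- fit_model(train, annotations = annotations, penalty = penalty)
    prep_test <- mix_prepare(test, annotations)
    total <- total + mix_loglik(prep_test, m$lambda, m$regional_logit)
  }
  total
}

#' Choose the ridge penalty by block-level cross-validation
#'
#' Partitions blocks into `k_folds` folds (seeded), fits the model on k-1
#' folds at each candidate penalty, sums the unpenalized log-likelihood on
#' the held-out fold, and returns the penalty maximizing the total held-out
#' likelihood (ties broken toward the smaller penalty).
#'
#' @inheritParams fit_model
#' @param penalty_grid Non-empty vector of candidate ridge weights.
#' @param k_folds Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @return List of class `penalty_cv` with elements `penalty` (the choice)
#'   and `table` (tibble of penalty vs held-out log-likelihood).
#' @export
cross_validate_penalty <- function(data, annotations = annotation_columns(data),
                                   penalty_grid, k_folds = 10, seed = 1) {
  if (length(penalty_grid) == 0L) stop_field("penalty_grid", "must be non-empty")
  if (k_folds < 2L) stop_field("k_folds", "must be >= 2")
  fold <- cv_folds(data$block_id, k_folds, seed)
  grid <- sort(penalty_grid)
  ll <- vapply(grid, function(p) cv_heldout_ll(data, annotations, p, fold), numeric(1))
  chosen <- grid[[which.max(ll)]]  # which.max takes the first (smallest) on ties
  structure(list(
    penalty = chosen,
    table = tibble::tibble(penalty = grid, heldout_loglik = ll),
    k_folds = k_folds,
    seed = seed
  ), class = "penalty_cv")
}

#' Reduce the annotation set by backward elimination
#'
#' Starting from a fitted combined model, repeatedly removes the annotation
#' whose removal most increases the model's cross-validated held-out
#' likelihood, stopping when no removal increases it — i.e. annotations are
#' removed until the likelihood stops increasing. The same seeded fold
#' assignment is used throughout. Set `criterion = "in_sample"` to compare
#' penalized in-sample log-likelihoods of refits instead.
#'
#' @inheritParams cross_validate_penalty
#' @param model Fitted `enrichment_model` whose annotations seed the search.
#' @param penalty Ridge weight used for every refit; defaults to the model's.
#' @param criterion `"cv"` (default) or `"in_sample"`.
#' @return List of class `stepwise_result` with elements `model` (refit on
#'   the retained annotations) and `trace` (tibble with one row per accepted
#'   removal: `removed`, `loglik_before`, `loglik_after`).
#' @export
stepwise_reduce <- function(data, model, penalty = model$penalty, k_folds = 10,
                            seed = 1, criterion = c("cv", "in_sample")) {
  criterion <- match.arg(criterion)
  current <- names(model$lambda)
  trace <- tibble::tibble(removed = character(), loglik_before = numeric(),
                          loglik_after = numeric())
  if (length(current) == 0L) {
    return(structure(list(model = model, trace = trace), class = "stepwise_result"))
  }
  score <- if (criterion == "cv") {
    fold <- cv_folds(data$block_id, k_folds, seed)
    function(set) cv_heldout_ll(data, set, penalty, fold)
  } else {
    function(set) fit_model(data, annotations = set, penalty = penalty)$penalized_loglik
  }
  cur_ll <- score(current)
  repeat {
    if (length(current) == 0L) break
    cand_ll <- vapply(current, function(a) score(setdiff(current, a)), numeric(1))
    best <- which.max(cand_ll)
    if (cand_ll[[best]] > cur_ll) {
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        removed = current[[best]],
        loglik_before = cur_ll,
        loglik_after = cand_ll[[best]]
      ))
      current <- setdiff(current, current[[best]])
      cur_ll <- cand_ll[[best]]
    } else {
      break
    }
  }
  final <- fit_model(data, annotations = current, penalty = penalty)
  structure(list(model = final, trace = trace), class = "stepwise_result")
}
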