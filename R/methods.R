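# tidy()/glance()/autoplot()/print() methods for the package's result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy enrichment_model
#' @export
tidy.enrichment_model <- function(x, ...) {
  tibble::tibble(term = names(x$lambda), estimate = unname(x$lambda))
}

#' @method glance enrichment_model
#' @export
glance.enrichment_model <- function(x, ...) {
  tibble::tibble(
    n_annotations = length(x$lambda),
    pi_regional = x$pi_regional,
    regional_logit = x$regional_logit,
    penalty = x$penalty,
    penalized_loglik = x$penalized_loglik,
    loglik = x$loglik,
    converged = x$converged,
    n_blocks = x$n_blocks,
    n_variants = x$n_variants
  )
}

#' @method print enrichment_model
#' @export
print.enrichment_model <- function(x, ...) {
  cat(sprintf("Annotation enrichment model (%d annotations, %d blocks, %d variants)\n",
              length(x$lambda), x$n_blocks, x$n_variants))
  cat(sprintf("  regional prior Pi = %.4f   ridge penalty = %.2f   %s\n",
              x$pi_regional, x$penalty,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  penalized log-likelihood = %.4f\n", x$penalized_loglik))
  if (length(x$lambda) > 0L) {
    cat("  ln(OR) estimates:\n")
    for (nm in names(x$lambda)) cat(sprintf("    %-20s %+.3f\n", nm, x$lambda[[nm]]))
  }
  invisible(x)
}

#' @method autoplot enrichment_model
#' @export
autoplot.enrichment_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "enrichment ln(OR)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot enrichment_ci
#' @export
autoplot.enrichment_ci <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$estimate,
                                       y = stats::reorder(.data$annotation, .data$estimate),
                                       colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey50")) +
    ggplot2::labs(x = "enrichment ln(OR), 95% CI", y = NULL, colour = "CI excludes 0") +
    ggplot2::theme_minimal()
}

#' @method tidy region_posterior
#' @export
tidy.region_posterior <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance region_posterior
#' @export
glance.region_posterior <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x),
    region_signal_prob = attr(x, "region_signal_prob"),
    ln_region_bf = attr(x, "ln_region_bf"),
    prior_region_prob = attr(x, "prior_region_prob")
  )
}

#' @method tidy finemap_result
#' @export
tidy.finemap_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance finemap_result
#' @export
glance.finemap_result <- function(x, ...) {
  tibble::tibble(
    lead_variant = attr(x, "lead_variant"),
    n_variants = nrow(x),
    region_signal_prob = attr(x, "region_signal_prob"),
    credible_set_size_pre = nrow(attr(x, "credible_set_pre")),
    credible_set_size_post = nrow(attr(x, "credible_set_post")),
    level = attr(x, "level")
  )
}

#' @method autoplot finemap_result
#' @export
autoplot.finemap_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$original_ppa, y = .data$updated_ppa,
                               colour = .data$in_credible_set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey50")) +
    ggplot2::labs(x = "original PPA", y = "updated PPA",
                  colour = "in 95% credible set") +
    ggplot2::theme_minimal()
}

#' @method tidy penalty_cv
#' @export
tidy.penalty_cv <- function(x, ...) x$table

#' @method glance penalty_cv
#' @export
glance.penalty_cv <- function(x, ...) {
  tibble::tibble(penalty = x$penalty, k_folds = x$k_folds, seed = x$seed)
}

#' @method tidy stepwise_result
#' @export
tidy.stepwise_result <- function(x, ...) x$trace

#' @method glance stepwise_result
#' @export
glance.stepwise_result <- function(x, ...) {
  tibble::tibble(
    n_removed = nrow(x$trace),
    n_retained = length(x$model$lambda),
    final_penalized_loglik = x$model$penalized_loglik
  )
}

#' @method tidy ase_result
#' @export
tidy.ase_result <- function(x, ...) x$per_sample

#' @method glance ase_result
#' @export
glance.ase_result <- function(x, ...) {
  tibble::tibble(meta_p = x$meta_p, n_het = x$n_het, direction = x$direction)
}

#' @method print ase_result
#' @export
print.ase_result <- function(x, ...) {
  cat(sprintf("Allele-specific signal across %d heterozygous sample(s)\n", x$n_het))
  cat(sprintf("  meta-analysis p = %.3g   direction: %s\n", x$meta_p, x$direction))
  invisible(x)
}

#' @method autoplot ase_result
#' @export
autoplot.ase_result <- function(object, ...) {
  ggplot2::ggplot(object$per_sample,
                  ggplot2::aes(x = .data$sample_id, y = .data$alt_fraction)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "alternative-allele read fraction") +
    ggplot2::theme_minimal()
}

#' Plot a Jaccard similarity matrix
#'
#' @param mat Matrix from [jaccard_matrix()].
#' @return A ggplot heatmap of pairwise similarities.
#' @export
plot_jaccard_matrix <- function(mat) {
  df <- tibble::as_tibble(as.table(mat), .name_repair = ~c("a", "b", "jaccard"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
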