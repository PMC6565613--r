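#' Functional class of a fine-mapped lead variant
#'
#' Assigns one of four mutually exclusive functional classes from a
#' variant's annotation incidence, with precedence: a missense variant is
#' `coding`; otherwise a promoter variant is `local_regulatory`; otherwise a
#' variant in any ATAC-seq or H3K27ac peak is `distal_regulatory`; anything
#' else — including a variant in an exon or UTR with no other marks — is
#' `unknown`.
#'
#' @param presence Named 0/1 (or logical) vector of annotation incidence.
#'   Recognized names: `missense`, `promoter`, `atac_any`, `h3k27ac_any`,
#'   `exon`, `utr`, `synonymous`. Unrecognized names are ignored with a
#'   warning. Alternative column names can be mapped via `mapping`.
#' @param mapping Optional named character vector mapping recognized roles to
#'   the names actually present, e.g. `c(atac_any = "atac_peaks")`.
#' @return One of `"coding"`, `"local_regulatory"`, `"distal_regulatory"`,
#'   `"unknown"`.
#' @examples
#' classify_lead_variant(c(missense = 1, atac_any = 1))  # coding
#' classify_lead_variant(c(promoter = 0, atac_any = 1))  # distal_regulatory
#' @export
classify_lead_variant <- function(presence, mapping = NULL) {
  nm <- names(presence)
  if (is.null(nm)) stop("`presence` must be a named vector", call. = FALSE)
  if (!is.null(mapping)) {
    for (role in names(mapping)) nm[nm == mapping[[role]]] <- role
    names(presence) <- nm
  }
  recognized <- c("missense", "promoter", "atac_any", "h3k27ac_any",
                  "exon", "utr", "synonymous")
  unknown_names <- setdiff(nm, recognized)
  if (length(unknown_names) > 0L) {
    warning(sprintf("ignoring unrecognized annotation(s): %s",
                    paste(unknown_names, collapse = ", ")), call. = FALSE)
  }
  on <- function(role) role %in% nm && isTRUE(presence[[role]] == 1 || isTRUE(presence[[role]]))
  if (on("missense")) return("coding")
  if (on("promoter")) return("local_regulatory")
  if (on("atac_any") || on("h3k27ac_any")) return("distal_regulatory")
  "unknown"
}

#' Summarize functional classes across lead variants
#'
#' @param reports Tibble with a `functional_class` column (values from
#'   [classify_lead_variant()]) and optionally the annotation presence
#'   columns used to classify.
#' @return A list with `counts` (tibble of class, n, and fraction over
#'   annotated variants), `n_total`, and `n_annotated` (variants whose class
#'   is not `unknown` or that carry any recognized annotation mark).
#' @export
summarize_classes <- function(reports) {
  classes <- c("coding", "local_regulatory", "distal_regulatory", "unknown")
  if (nrow(reports) == 0L) {
    return(list(
      counts = tibble::tibble(functional_class = classes, n = 0L, fraction = NA_real_),
      n_total = 0L, n_annotated = 0L
    ))
  }
  fc <- factor(reports$functional_class, levels = classes)
  n <- as.integer(table(fc))
  mark_cols <- intersect(c("missense", "promoter", "atac_any", "h3k27ac_any",
                           "exon", "utr", "synonymous"), names(reports))
  n_annotated <- if (length(mark_cols) > 0L) {
    sum(rowSums(as.matrix(reports[mark_cols])) > 0)
  } else {
    sum(fc != "unknown")
  }
  frac <- if (n_annotated > 0) n / n_annotated else rep(NA_real_, length(n))
  list(
    counts = tibble::tibble(functional_class = classes, n = n, fraction = frac),
    n_total = nrow(reports),
    n_annotated = as.integer(n_annotated)
  )
}
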