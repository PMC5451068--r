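#' Filter a tissue panel by minimum sample count
#'
#' Tissues with fewer than `min_samples` samples are removed before
#' selectivity scoring (the inclusive boundary: a tissue with exactly
#' `min_samples` is kept).
#'
#' @param panel data.frame with `tissue`, `n_samples`, `is_brain`.
#' @param min_samples minimum sample count (default 50).
#' @return the retained panel rows; error if nothing survives.
#' @export
filter_tissues <- function(panel, min_samples = 50) {
  stopifnot(nrow(panel) > 0, all(panel$n_samples > 0))
  keep <- panel$n_samples >= min_samples
  if (!any(keep)) stop("no tissue passes the minimum-sample filter")
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fractional brain expression of one gene
#'
#' `100 * sum(expression over brain tissues) / sum(over all tissues)`;
#' undefined (NA) when the gene has zero total expression.
#'
#' @param expr_row nonnegative expression values aligned to `panel` rows.
#' @param panel tissue panel (already filtered).
#' @return percentage in \[0, 100\], or NA.
#' @export
fractional_brain_expression <- function(expr_row, panel) {
  stopifnot(length(expr_row) == nrow(panel))
  if (any(expr_row < 0)) stop("negative expression value")
  total <- sum(expr_row)
  if (total == 0) return(NA_real_)
  100 * sum(expr_row[panel$is_brain]) / total
}

#' Z-score a gene's expression profile across tissues
#'
#' Uses the population (n-denominator) standard deviation, the convention
#' for profile normalization ahead of clustering.  Constant rows give an
#' all-zero profile with a `constant` attribute set.
#'
#' @param expr_row expression values over >= 2 tissues.
#' @param population use the n-denominator sd (default TRUE).
#' @return numeric Z-score vector; `attr(, "constant")` flags degenerate
#'   rows.
#' @export
zscore_profile <- function(expr_row, population = TRUE) {
  stopifnot(length(expr_row) >= 2)
  n <- length(expr_row)
  m <- mean(expr_row)
  s <- sd(expr_row)
  if (population) s <- s * sqrt((n - 1) / n)
  if (is.na(s) || s == 0) {
    return(structure(rep(0, n), constant = TRUE, names = names(expr_row)))
  }
  structure((expr_row - m) / s, constant = FALSE, names = names(expr_row))
}

#' Tissue-selectivity scores for every gene
#'
#' Applies the panel filter, then computes fractional brain expression and
#' the cross-tissue Z profile per gene.  A gene is brain-selective when its
#' fractional brain expression strictly exceeds `threshold` percent;
#' all-zero genes are reported with NA and are never selective.
#'
#' @param expr gene x tissue matrix, columns named by tissue.
#' @param panel tissue panel data.frame.
#' @param threshold selectivity threshold in percent (default 50).
#' @param min_samples minimum tissue sample count (default 50).
#' @return list with `scores` (data.frame `gene_id`,
#'   `fractional_brain_expression`, `brain_selective`), `z` (gene x tissue
#'   Z-score matrix) and the filtered `panel`.
#' @export
specificity_scores <- function(expr, panel, threshold = 50,
                               min_samples = 50) {
  panel <- filter_tissues(panel, min_samples)
  if (!all(panel$tissue %in% colnames(expr))) {
    stop("panel tissues missing from the expression matrix")
  }
  expr <- expr[, panel$tissue, drop = FALSE]
  fbe <- apply(expr, 1, fractional_brain_expression, panel = panel)
  z <- t(apply(expr, 1, function(r) as.numeric(zscore_profile(r))))
  dimnames(z) <- dimnames(expr)
  scores <- data.frame(
    gene_id = rownames(expr),
    fractional_brain_expression = fbe,
    brain_selective = !is.na(fbe) & fbe > threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(scores = scores, z = z, panel = panel)
}
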