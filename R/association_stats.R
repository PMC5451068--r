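#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1); NA p-values propagate.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

mean_pairwise <- function(C, idx) {
  s <- length(idx)
  (sum(C[idx, idx]) - s) / (s * (s - 1))
}

#' Permutation test of within-module co-expression
#'
#' Per module, the observed statistic is the mean correlation over all
#' within-module gene pairs; the null is the same statistic on `B` random
#' gene sets of equal size drawn (without replacement) from all network
#' genes.  The one-sided empirical p-value uses the add-one correction
#' `(r + 1) / (B + 1)`, so it can never be 0 and is bounded below by
#' `1 / (B + 1)`; p-values are BH-adjusted across modules.
#'
#' @param expr gene x sample matrix covering the network genes.
#' @param partition a `module_partition` (or named gene -> label vector).
#' @param B permutation count (default 10000).
#' @param seed RNG seed for the null draws.
#' @param cor_method correlation kind for the statistic.
#' @param corr optional precomputed correlation matrix over `rownames(expr)`.
#' @return data.frame (class `permutation_result`) with `target`,
#'   `observed_stat`, `null_mean`, `null_sd`, `B`, `empirical_p`, `adj_p`,
#'   `direction`.
#' @export
module_coexpression_test <- function(expr, partition, B = 10000, seed = 1,
                                     cor_method = "bicor", corr = NULL) {
  labels <- if (inherits(partition, "module_partition")) {
    partition$modules
  } else {
    partition
  }
  labels <- labels[intersect(names(labels), rownames(expr))]
  if (is.null(corr)) corr <- cor_matrix(expr[names(labels), ], cor_method)
  mods <- setdiff(unique(labels), "unassigned")
  if (any(table(labels[labels %in% mods]) < 2)) {
    stop("modules must have >= 2 genes")
  }
  n <- length(labels)
  set.seed(seed)
  rows <- lapply(mods, function(m) {
    idx <- which(labels == m)
    obs <- mean_pairwise(corr, idx)
    null <- vapply(seq_len(B), function(b) {
      mean_pairwise(corr, sample.int(n, length(idx)))
    }, numeric(1))
    data.frame(target = m, observed_stat = obs, null_mean = mean(null),
               null_sd = sd(null), B = B,
               empirical_p = (sum(null >= obs) + 1) / (B + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$empirical_p)
  out$direction <- sign(out$observed_stat - out$null_mean)
  class(out) <- c("permutation_result", class(out))
  out
}

#' Permutation test of module differential-expression overlay
#'
#' Each network gene gets an effective log2 fold change: its DE estimate if
#' significant, otherwise 0 (genes never tested also get 0).  The observed
#' statistic per module is the mean effective fold change over module
#' genes; the null is `B` random equal-size gene sets from the network.
#' The empirical p-value is two-sided around the null mean, with the
#' add-one correction, BH-adjusted across modules; `direction` is the sign
#' of the observed mean.
#'
#' @param partition `module_partition` or named gene -> label vector.
#' @param de DE result table from [nb_wald_test()].
#' @param B permutation count.
#' @param seed RNG seed.
#' @return `permutation_result` data.frame as in
#'   [module_coexpression_test()].
#' @export
module_de_overlay_test <- function(partition, de, B = 10000, seed = 1) {
  labels <- if (inherits(partition, "module_partition")) {
    partition$modules
  } else {
    partition
  }
  eff <- setNames(rep(0, length(labels)), names(labels))
  hit <- de$gene_id[de$significant %in% TRUE]
  hit <- intersect(hit, names(eff))
  eff[hit] <- de$log2fc[match(hit, de$gene_id)]
  mods <- setdiff(unique(labels), "unassigned")
  if (any(tabulate(factor(labels, levels = mods)) == 0)) stop("empty module")
  n <- length(labels)
  set.seed(seed)
  rows <- lapply(mods, function(m) {
    idx <- which(labels == m)
    obs <- mean(eff[idx])
    null <- vapply(seq_len(B), function(b) {
      mean(eff[sample.int(n, length(idx))])
    }, numeric(1))
    nm <- mean(null)
    data.frame(target = m, observed_stat = obs, null_mean = nm,
               null_sd = sd(null), B = B,
               empirical_p = (sum(abs(null - nm) >= abs(obs - nm)) + 1) /
                 (B + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$empirical_p)
  out$direction <- sign(out$observed_stat)
  class(out) <- c("permutation_result", class(out))
  out
}

#' Permutation test of lncRNA / risk-gene-set summed co-expression
#'
#' The observed statistic is the sum of correlations over all pairs of a
#' fixed lncRNA set against a gene set (pairs with identical ids excluded);
#' the null replaces the gene set with `B` random same-size sets from the
#' network while the lncRNA set stays fixed.  One-sided greater with the
#' add-one correction.
#'
#' @param expr gene x sample matrix over network genes.
#' @param lnc_ids fixed lncRNA ids (must be in `expr`).
#' @param set_ids gene-set ids (must be in `expr`), or a named list of
#'   several sets (BH is applied across sets).
#' @param B permutation count.
#' @param seed RNG seed.
#' @param cor_method correlation kind.
#' @param corr optional precomputed correlation matrix.
#' @return `permutation_result` data.frame, one row per gene set.
#' @export
lncrna_geneset_coexpression_test <- function(expr, lnc_ids, set_ids,
                                             B = 10000, seed = 1,
                                             cor_method = "bicor",
                                             corr = NULL) {
  if (!is.list(set_ids)) set_ids <- list(gene_set = set_ids)
  genes <- rownames(expr)
  lnc_ids <- intersect(lnc_ids, genes)
  if (!length(lnc_ids)) stop("no lncRNA ids present in the matrix")
  for (nm in names(set_ids)) {
    miss <- setdiff(set_ids[[nm]], genes)
    if (length(miss) == length(set_ids[[nm]])) {
      stop("gene set '", nm, "' absent from the matrix")
    }
    set_ids[[nm]] <- intersect(set_ids[[nm]], genes)
  }
  if (is.null(corr)) corr <- cor_matrix(expr, cor_method)
  li <- match(lnc_ids, genes)
  sum_cross <- function(si) {
    ## total over all (l, g) pairs minus the self pairs (bicor = 1)
    sum(corr[li, si]) - length(intersect(li, si))
  }
  set.seed(seed)
  rows <- lapply(names(set_ids), function(nm) {
    si <- match(set_ids[[nm]], genes)
    obs <- sum_cross(si)
    null <- vapply(seq_len(B), function(b) {
      sum_cross(sample.int(length(genes), length(si)))
    }, numeric(1))
    data.frame(target = nm, observed_stat = obs, null_mean = mean(null),
               null_sd = sd(null), B = B,
               empirical_p = (sum(null >= obs) + 1) / (B + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$empirical_p)
  out$direction <- sign(out$observed_stat - out$null_mean)
  class(out) <- c("permutation_result", class(out))
  out
}

#' One-sided Fisher exact enrichment of a gene set in a module
#'
#' 2x2 table `a = |module & set|`, `b = |module \ set|`, `c = |set \
#' module|`, `d = N - a - b - c`; the one-sided (greater) p-value is the
#' hypergeometric tail `P(X >= a)`, and the odds ratio is the sample
#' `(a d) / (b c)` with a Haldane 0.5 correction applied to all cells when
#' any cell is zero.
#'
#' @param module_genes,gene_set,universe character id vectors; both sets
#'   must be subsets of the universe.
#' @return one-row data.frame with `universe_size`, `module_size`,
#'   `set_size`, `overlap`, `odds_ratio`, `p`.
#' @export
fisher_enrichment <- function(module_genes, gene_set, universe) {
  if (length(setdiff(module_genes, universe)) ||
      length(setdiff(gene_set, universe))) {
    stop("module genes and gene set must be subsets of the universe; ",
         "intersect with the universe first")
  }
  N <- length(unique(universe))
  m <- length(unique(module_genes))
  n <- length(unique(gene_set))
  a <- length(intersect(module_genes, gene_set))
  b <- m - a
  cc <- n - a
  d <- N - a - b - cc
  p <- phyper(a - 1, n, N - n, m, lower.tail = FALSE)
  if (a == 0 || b == 0 || cc == 0 || d == 0) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    or <- (a * d) / (b * cc)
  }
  data.frame(universe_size = N, module_size = m, set_size = n, overlap = a,
             odds_ratio = or, p = p)
}

#' Fisher enrichment of several gene sets across all modules
#'
#' Applies [fisher_enrichment()] to every (module, gene set) pair, adjusts
#' all p-values together by BH, and flags enrichment as `adj_p < alpha`
#' together with `odds_ratio > 1`.  This is also the generic
#' overrepresentation engine: any user-supplied term -> gene map can be
#' passed as `gene_sets`.
#'
#' @param partition `module_partition` or named gene -> label vector.
#' @param gene_sets named list of gene-id vectors; ids outside the universe
#'   are dropped (and counted in `set_dropped`).
#' @param universe gene universe; defaults to all genes in the partition
#'   (assigned or not).
#' @param alpha FDR threshold for the `enriched` flag.
#' @param include_unassigned test the `"unassigned"` group too
#'   (default FALSE).
#' @return data.frame (class `enrichment_table`) with one row per
#'   (module, gene set) pair: sizes, `overlap`, `odds_ratio`, `p`, `adj_p`,
#'   `enriched`.
#' @export
enrichment_table <- function(partition, gene_sets, universe = NULL,
                             alpha = 0.05, include_unassigned = FALSE) {
  labels <- if (inherits(partition, "module_partition")) {
    partition$modules
  } else {
    partition
  }
  if (is.null(universe)) universe <- names(labels)
  mods <- setdiff(unique(labels), if (include_unassigned) NULL else "unassigned")
  rows <- list()
  for (m in mods) {
    mg <- intersect(names(labels)[labels == m], universe)
    for (s in names(gene_sets)) {
      gs_all <- unique(gene_sets[[s]])
      gs <- intersect(gs_all, universe)
      r <- fisher_enrichment(mg, gs, universe)
      r <- data.frame(module = m, gene_set = s, r,
                      set_dropped = length(gs_all) - length(gs),
                      stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out$enriched <- out$adj_p < alpha & out$odds_ratio > 1
  out$neg_log10_adj_p <- -log10(out$adj_p)
  class(out) <- c("enrichment_table", class(out))
  out
}
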