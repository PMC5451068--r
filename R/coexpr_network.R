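#' Network construction parameters
#'
#' @param beta soft-threshold power for the signed adjacency (default 12,
#'   the standard choice approximating scale-free topology on brain
#'   developmental data).
#' @param min_module_size smallest branch kept as a module (default 30).
#' @param cut_method `"height"` (static cut of the dendrogram at a fixed
#'   fraction of its total height) or `"hybrid"` (same cut followed by
#'   reassignment of unassigned genes with strong module membership).
#' @param cut_quantile fraction of the maximum merge height at which to cut
#'   (default 0.99): module branches join well below it while unstructured
#'   genes merge essentially at the top of the dendrogram.
#' @param merge_threshold eigengene correlation above which modules merge;
#'   NULL (default) disables merging.
#' @param cor_method `"bicor"` (biweight midcorrelation, robust default) or
#'   `"pearson"`.
#' @param refine_kme minimum absolute module membership for hybrid
#'   reassignment (default 0.7).
#' @return list of class `network_params`.
#' @export
network_params <- function(beta = 12, min_module_size = 30,
                           cut_method = c("height", "hybrid"),
                           cut_quantile = 0.99, merge_threshold = NULL,
                           cor_method = c("bicor", "pearson"),
                           refine_kme = 0.7) {
  cut_method <- match.arg(cut_method)
  cor_method <- match.arg(cor_method)
  if (beta < 1) stop("beta must be >= 1")
  if (min_module_size < 3) stop("min_module_size must be >= 3")
  structure(list(beta = beta, min_module_size = as.integer(min_module_size),
                 cut_method = cut_method, cut_quantile = cut_quantile,
                 merge_threshold = merge_threshold, cor_method = cor_method,
                 refine_kme = refine_kme),
            class = "network_params")
}

#' Variance filter: keep the most variable half of the genes
#'
#' Removes the bottom two quartiles of genes by across-sample variance.
#' Genes whose variance ties the median are kept (stable rule), so with
#' all-equal variances nothing is removed.
#'
#' @param expr gene x sample matrix (>= 4 genes).
#' @return the retained submatrix, original row order preserved.
#' @export
variance_filter <- function(expr) {
  stopifnot(nrow(expr) >= 4)
  v <- apply(expr, 1, var)
  expr[v >= median(v), , drop = FALSE]
}

## Biweight deviation vector for one sample-vector; NULL when degenerate
## (zero MAD or all weights vanish), in which case the caller falls back to
## Pearson for every pair involving that vector.
biweight_deviations <- function(x) {
  med <- median(x)
  madx <- median(abs(x - med))   # unscaled MAD (no 1.4826 factor)
  if (madx == 0) return(NULL)
  u <- (x - med) / (9 * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  if (all(w == 0)) return(NULL)
  (x - med) * w
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation built from Tukey biweight weights around the median:
#' `u_i = (x_i - med(x)) / (9 * MAD(x))` with unscaled MAD, weights
#' `(1 - u^2)^2` on `|u| < 1`, deviations `d_i = (x_i - med(x)) * w_i`, and
#' `bicor = sum(d_i e_i) / sqrt(sum(d_i^2) sum(e_i^2))`.  When either
#' vector has zero MAD or all-zero weights the pair falls back to the
#' Pearson correlation (reported via the `fallback` attribute).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\]; `attr(, "fallback")` is TRUE when the
#'   Pearson fallback was used.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need length >= 3")
  d <- biweight_deviations(x)
  e <- biweight_deviations(y)
  if (is.null(d) || is.null(e)) {
    return(structure(cor(x, y), fallback = TRUE))
  }
  structure(sum(d * e) / sqrt(sum(d^2) * sum(e^2)), fallback = FALSE)
}

#' Correlation matrix across genes
#'
#' Computes the full gene-by-gene correlation matrix (genes in rows of
#' `expr`) with the configured correlation.  For bicor, genes with a
#' degenerate biweight (zero MAD) use the Pearson fallback for every pair
#' they participate in, matching the pairwise [bicor()] semantics.
#'
#' @param expr gene x sample matrix.
#' @param method `"bicor"` or `"pearson"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
cor_matrix <- function(expr, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  if (method == "pearson") {
    C <- cor(t(expr))
  } else {
    n <- nrow(expr)
    D <- matrix(0, n, ncol(expr))
    degen <- logical(n)
    for (g in seq_len(n)) {
      d <- biweight_deviations(expr[g, ])
      if (is.null(d)) {
        degen[g] <- TRUE
        d <- expr[g, ] - mean(expr[g, ])
      }
      nrm <- sqrt(sum(d^2))
      D[g, ] <- if (nrm > 0) d / nrm else 0
    }
    C <- tcrossprod(D)
    if (any(degen)) {
      ## pairs involving a degenerate gene are full-Pearson on both sides
      P <- expr - rowMeans(expr)
      nrm <- sqrt(rowSums(P^2))
      nrm[nrm == 0] <- 1
      P <- P / nrm
      CP <- tcrossprod(P)
      C[degen, ] <- CP[degen, ]
      C[, degen] <- CP[, degen]
    }
  }
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  dimnames(C) <- list(rownames(expr), rownames(expr))
  C
}

#' Signed soft-thresholded adjacency
#'
#' `a_ij = ((1 + c_ij) / 2)^beta`, so anti-correlated genes get adjacency
#' near 0 and the diagonal is 1.
#'
#' @param corr symmetric correlation matrix in \[-1, 1\].
#' @param beta soft-threshold power >= 1.
#' @return adjacency matrix in \[0, 1\].
#' @export
signed_adjacency <- function(corr, beta = 12) {
  if (beta < 1) stop("beta must be >= 1")
  if (any(abs(corr - t(corr)) > 1e-12)) stop("correlation matrix not symmetric")
  a <- ((1 + corr) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' With connectivity `k_i = sum_{u != i} a_iu` and shared-neighbour weight
#' `l_ij = sum_{u != i,j} a_iu a_uj`:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, diagonal 1.
#' The clustering dissimilarity is `1 - TOM`.
#'
#' @param adjacency symmetric adjacency with unit diagonal.
#' @return TOM similarity matrix in \[0, 1\].
#' @export
topological_overlap <- function(adjacency) {
  if (any(abs(adjacency - t(adjacency)) > 1e-12)) {
    stop("adjacency not symmetric")
  }
  A <- adjacency
  diag(A) <- 1
  k <- rowSums(A) - 1
  L <- A %*% A - 2 * A           # removes the u = i and u = j terms off-diag
  num <- L + A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(adjacency)
  tom
}

module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta"
)

#' Module eigengene
#'
#' First principal component of the standardized module submatrix, as a
#' sample-length vector, sign-oriented so that it correlates positively
#' with the module's mean standardized expression, and scaled to unit
#' variance.
#'
#' @param expr gene x sample matrix restricted to one module's genes.
#' @return numeric vector over samples (mean 0, sd 1).
#' @export
module_eigengene <- function(expr) {
  Z <- t(scale(t(expr)))
  Z[!is.finite(Z)] <- 0
  sv <- svd(Z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  avg <- colMeans(Z)
  if (sum(e * (avg - mean(avg))) < 0) e <- -e
  s <- sd(e)
  if (s == 0) stop("constant eigengene")
  as.numeric((e - mean(e)) / s)
}

#' Detect co-expression modules
#'
#' Builds the signed weighted network (configured correlation, soft power
#' `beta`), computes topological overlap, clusters `1 - TOM` with
#' average-linkage hierarchical clustering and cuts the tree at a fixed
#' fraction of its total height.  Branches smaller than
#' `min_module_size` are relabeled `"unassigned"`.  Modules are named by
#' size rank with stable color-style labels; each gets an eigengene and
#' per-gene module membership (correlation of the gene's profile with its
#' module eigengene, using the configured correlation).
#'
#' @param expr filtered gene x sample matrix.
#' @param params a [network_params()] object.
#' @return object of class `module_partition`: list with `modules` (named
#'   character vector gene -> label), `sizes`, `eigengenes` (sample x
#'   module matrix), `membership` (named numeric), `tree` (hclust), `tom`
#'   dissimilarity summary and `params`.
#' @export
detect_modules <- function(expr, params = network_params()) {
  if (nrow(expr) < params$min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    part <- list(
      modules = setNames(rep("unassigned", nrow(expr)), rownames(expr)),
      sizes = integer(0),
      eigengenes = matrix(0, ncol(expr), 0,
                          dimnames = list(colnames(expr), NULL)),
      membership = setNames(rep(NA_real_, nrow(expr)), rownames(expr)),
      tree = NULL, params = params
    )
    return(structure(part, class = "module_partition"))
  }
  C <- cor_matrix(expr, params$cor_method)
  A <- signed_adjacency(C, params$beta)
  tom <- topological_overlap(A)
  d <- 1 - tom
  tree <- hclust(as.dist(d), method = "average")
  h <- params$cut_quantile * max(tree$height)
  cl <- cutree(tree, h = h)

  sizes <- table(cl)
  keep <- names(sizes)[sizes >= params$min_module_size]
  labels <- rep("unassigned", nrow(expr))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep])]
    pal <- rep_len(module_palette, length(ord))
    for (i in seq_along(ord)) {
      labels[cl == as.integer(ord[i])] <- pal[i]
    }
  }
  names(labels) <- rownames(expr)

  if (params$cut_method == "hybrid") {
    labels <- hybrid_refine(expr, labels, params)
  }
  if (!is.null(params$merge_threshold)) {
    labels <- merge_close_modules(expr, labels, params$merge_threshold)
  }

  mods <- setdiff(unique(labels), "unassigned")
  mods <- mods[order(-tabulate(factor(labels, levels = mods)))]
  eig <- matrix(0, ncol(expr), length(mods),
                dimnames = list(colnames(expr), mods))
  for (m in mods) {
    eig[, m] <- module_eigengene(expr[labels == m, , drop = FALSE])
  }
  membership <- setNames(rep(NA_real_, nrow(expr)), rownames(expr))
  corr_fun <- if (params$cor_method == "bicor") {
    function(a, b) as.numeric(bicor(a, b))
  } else {
    function(a, b) cor(a, b)
  }
  for (g in seq_len(nrow(expr))) {
    m <- labels[g]
    if (m != "unassigned") membership[g] <- corr_fun(expr[g, ], eig[, m])
  }
  structure(list(
    modules = labels,
    sizes = sort(table(labels[labels != "unassigned"]), decreasing = TRUE),
    eigengenes = eig, membership = membership, tree = tree, params = params
  ), class = "module_partition")
}

## Hybrid-style refinement: unassigned genes with strong membership in some
## module are pulled in.
hybrid_refine <- function(expr, labels, params) {
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) return(labels)
  eig <- vapply(mods, function(m) {
    module_eigengene(expr[labels == m, , drop = FALSE])
  }, numeric(ncol(expr)))
  for (g in which(labels == "unassigned")) {
    kme <- vapply(seq_along(mods), function(i) {
      as.numeric(bicor(expr[g, ], eig[, i]))
    }, numeric(1))
    best <- which.max(kme)
    if (kme[best] >= params$refine_kme) labels[g] <- mods[best]
  }
  labels
}

merge_close_modules <- function(expr, labels, threshold) {
  repeat {
    mods <- setdiff(unique(labels), "unassigned")
    if (length(mods) < 2) return(labels)
    eig <- vapply(mods, function(m) {
      module_eigengene(expr[labels == m, , drop = FALSE])
    }, numeric(ncol(expr)))
    ec <- cor(eig)
    diag(ec) <- -Inf
    top <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    if (ec[top[1], top[2]] < threshold) return(labels)
    labels[labels == mods[top[2]]] <- mods[top[1]]
  }
}

#' Correlation of module eigengenes with sample age
#'
#' @param partition a `module_partition`.
#' @param ages numeric vector aligned to samples.
#' @return named numeric vector of Pearson correlations, one per module.
#' @export
eigengene_age_correlation <- function(partition, ages) {
  eig <- partition$eigengenes
  stopifnot(length(ages) == nrow(eig))
  vapply(colnames(eig), function(m) {
    e <- eig[, m]
    if (sd(e) == 0) stop("constant eigengene for module ", m)
    cor(e, ages)
  }, numeric(1))
}

#' Most highly co-expressed gene from a candidate set
#'
#' Returns the candidate maximizing the correlation (default bicor) with the
#' query gene's profile; the query itself is excluded and ties are broken by
#' lexicographic gene id.
#'
#' @param expr gene x sample matrix.
#' @param query_gene gene id present in `expr`.
#' @param candidates candidate gene ids (e.g. protein-coding genes).
#' @param method correlation kind.
#' @return list with `gene_id` and `correlation`.
#' @export
top_correlated_gene <- function(expr, query_gene, candidates,
                                method = c("bicor", "pearson")) {
  method <- match.arg(method)
  if (!query_gene %in% rownames(expr)) stop("query gene not in matrix")
  candidates <- setdiff(intersect(candidates, rownames(expr)), query_gene)
  if (!length(candidates)) stop("empty candidate set")
  candidates <- sort(candidates)
  q <- expr[query_gene, ]
  r <- vapply(candidates, function(g) {
    if (method == "bicor") as.numeric(bicor(q, expr[g, ])) else cor(q, expr[g, ])
  }, numeric(1))
  best <- which.max(r)   # first max = lexicographically smallest tie
  list(gene_id = candidates[best], correlation = unname(r[best]))
}
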