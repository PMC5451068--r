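#' Collapse technical replicates by summing counts
#'
#' Technical replicates of one biological sample are summed into a single
#' column before testing, since the NB model assumes independent biological
#' units.  Replicate groups that span conditions are an error.
#'
#' @param counts integer gene x sample matrix.
#' @param samples sample sheet with `sample`, `condition`, `subject`.
#' @return list with collapsed `counts` (one column per subject) and the
#'   collapsed `samples` sheet.
#' @export
collapse_technical_replicates <- function(counts, samples) {
  stopifnot(setequal(colnames(counts), samples$sample))
  counts <- counts[, samples$sample, drop = FALSE]
  spans <- tapply(samples$condition, samples$subject,
                  function(x) length(unique(x)))
  if (any(spans > 1)) {
    stop("replicate group(s) span conditions: ",
         paste(names(spans)[spans > 1], collapse = ", "))
  }
  subjects <- unique(samples$subject)
  out <- matrix(0L, nrow(counts), length(subjects),
                dimnames = list(rownames(counts), subjects))
  for (s in subjects) {
    out[, s] <- as.integer(rowSums(counts[, samples$subject == s,
                                          drop = FALSE]))
  }
  cond <- samples$condition[match(subjects, samples$subject)]
  list(counts = out,
       samples = data.frame(sample = subjects, condition = cond,
                            subject = subjects, stringsAsFactors = FALSE))
}

#' Median-of-ratios size factors
#'
#' The standard library-size estimator behind NB count models: for each
#' sample, the median over genes (with nonzero geometric mean across all
#' samples) of the ratio of its count to the gene's geometric mean; factors
#' are then rescaled so their geometric mean is 1.
#'
#' @param counts integer gene x sample matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))   # -Inf where any zero
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop("no gene has nonzero counts in every sample; consider a ",
         "pseudo-reference fallback")
  }
  geo <- exp(log_geo[use])
  raw <- apply(counts[use, , drop = FALSE], 2,
               function(col) median(col / geo))
  sf <- raw / exp(mean(log(raw)))    # geometric mean 1
  setNames(sf, colnames(counts))
}

#' Per-gene NB dispersion by pooled method of moments
#'
#' On size-factor-normalized counts, within-group variances are pooled and a
#' moment estimate of the NB dispersion `alpha` (variance = mu + alpha*mu^2)
#' is taken: `alpha_g = max(floor, (s2_g - mu_g) / mu_g^2)`.  Optional linear
#' shrinkage pulls each estimate toward the across-gene mean, stabilizing
#' the noisy per-gene moments at small sample sizes.
#'
#' @param counts integer gene x sample matrix.
#' @param sf size factors from [size_factors()].
#' @param condition group labels aligned to columns.
#' @param mom_weight weight in \[0, 1\] retained by the per-gene moment
#'   estimate; the complement goes to the across-gene mean (default 0.25 —
#'   strong shrinkage, which keeps the Wald test calibrated at very small
#'   sample sizes; 1 disables shrinkage).
#' @param alpha_floor lower bound for the estimate.
#' @return list with `alpha` (per-gene estimate, NA for untestable genes)
#'   and `testable` (logical; FALSE where the normalized mean is 0).
#' @export
estimate_dispersion <- function(counts, sf, condition, mom_weight = 0.25,
                                alpha_floor = 1e-8) {
  stopifnot(length(sf) == ncol(counts), length(condition) == ncol(counts))
  groups <- unique(condition)
  if (any(table(condition) < 2)) stop("need >= 2 samples per group")
  norm <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(norm)
  ss <- 0
  df <- 0
  for (g in groups) {
    sub <- norm[, condition == g, drop = FALSE]
    gm <- rowMeans(sub)
    ss <- ss + rowSums((sub - gm)^2)
    df <- df + (ncol(sub) - 1L)
  }
  s2 <- ss / df
  testable <- mu > 0
  alpha <- rep(NA_real_, nrow(counts))
  alpha[testable] <- pmax(alpha_floor,
                          (s2[testable] - mu[testable]) / mu[testable]^2)
  if (mom_weight < 1 && sum(testable) > 1L) {
    m <- mean(alpha[testable])
    alpha[testable] <- mom_weight * alpha[testable] + (1 - mom_weight) * m
  }
  list(alpha = setNames(alpha, rownames(counts)),
       testable = setNames(testable, rownames(counts)))
}

## One-gene NB GLM with log link, fixed dispersion, offset log(sf),
## design [intercept, group]: fit by IRLS, return coef, SE, convergence.
nb_irls_gene <- function(y, sf, x, alpha, max_iter = 50L, tol = 1e-8) {
  X <- cbind(1, x)
  ## moment start: group means on the normalized scale
  norm <- y / sf
  m0 <- mean(norm[x == 0])
  m1 <- mean(norm[x == 1])
  beta <- c(log(max(m0, 1e-8)), log(max(m1, 1e-8)) - log(max(m0, 1e-8)))
  off <- log(sf)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + off
    mu <- exp(eta)
    mu <- pmin(pmax(mu, 1e-10), 1e12)
    w <- mu / (1 + alpha * mu)            # working weights, log link
    z <- eta - off + (y - mu) / mu        # working response
    XtW <- t(X * w)
    fit <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(fit)) return(list(ok = FALSE))
    new_beta <- drop(fit)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      conv <- TRUE
      break
    }
    beta <- new_beta
  }
  eta <- drop(X %*% beta) + off
  mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
  w <- mu / (1 + alpha * mu)
  info <- t(X * w) %*% X
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) return(list(ok = FALSE))
  list(ok = conv, beta = beta, se = sqrt(diag(cov)))
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Per gene, a NB log-link GLM with a group indicator is fit by iteratively
#' reweighted least squares at the supplied (fixed) dispersion, with
#' `log(size factor)` offsets.  The log2 fold change is the group
#' coefficient divided by `ln 2`; the Wald statistic `coef/SE` is referred
#' to the standard normal, two-sided.  P-values are Benjamini-Hochberg
#' adjusted over all testable, converged genes, and a gene is flagged
#' significant when `adj_p < alpha` and `|log2fc| >= lfc_min` (the inclusive
#' fold-change rule).  Positive log2fc means higher in the case group.
#'
#' @param counts integer gene x sample matrix (technical replicates already
#'   collapsed).
#' @param samples sample sheet aligned to columns.
#' @param case,control the two condition labels (defaults `"case"`,
#'   `"control"`).
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_min minimum absolute log2 fold change (default 1).
#' @param dispersion optional per-gene dispersion vector; estimated via
#'   [estimate_dispersion()] when NULL.
#' @param mom_weight dispersion moment-estimate weight passed through.
#' @return data.frame with `gene_id`, `base_mean`, `log2fc`, `se`, `p`,
#'   `adj_p`, `significant`, `status`
#'   (`"ok"`, `"untestable"` or `"not_converged"`).
#' @export
nb_wald_test <- function(counts, samples, case = "case", control = "control",
                         alpha = 0.05, lfc_min = 1, dispersion = NULL,
                         mom_weight = 0.25) {
  stopifnot(setequal(colnames(counts), samples$sample))
  counts <- counts[, samples$sample, drop = FALSE]
  keep <- samples$condition %in% c(case, control)
  counts <- counts[, keep, drop = FALSE]
  condition <- samples$condition[keep]
  if (length(unique(condition)) != 2L) stop("need both groups present")
  if (any(table(condition) < 2)) stop("need >= 2 biological samples per group")

  sf <- size_factors(counts)
  if (is.null(dispersion)) {
    disp <- estimate_dispersion(counts, sf, condition, mom_weight = mom_weight)
  } else {
    disp <- list(alpha = dispersion,
                 testable = !is.na(dispersion) & rowMeans(counts) > 0)
  }
  x <- as.numeric(condition == case)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)

  n <- nrow(counts)
  log2fc <- se <- p <- rep(NA_real_, n)
  status <- rep("untestable", n)
  for (g in seq_len(n)) {
    if (!isTRUE(disp$testable[g])) next
    fit <- nb_irls_gene(counts[g, ], sf, x, disp$alpha[g])
    if (!isTRUE(fit$ok)) {
      status[g] <- "not_converged"
      next
    }
    status[g] <- "ok"
    log2fc[g] <- fit$beta[2] / log(2)
    se[g] <- fit$se[2] / log(2)
    z <- fit$beta[2] / fit$se[2]
    p[g] <- 2 * pnorm(-abs(z))
  }
  adj_p <- rep(NA_real_, n)
  ok <- status == "ok"
  adj_p[ok] <- bh_adjust(p[ok])
  significant <- !is.na(adj_p) & adj_p < alpha & abs(log2fc) >= lfc_min
  data.frame(
    gene_id = rownames(counts), base_mean = base_mean, log2fc = log2fc,
    se = se, p = p, adj_p = adj_p, significant = significant,
    status = status, stringsAsFactors = FALSE, row.names = NULL
  )
}
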