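test_that("bicor matches its definition and resists outliers", {
  set.seed(1)
  x <- rnorm(20)
  expect_equal(as.numeric(bicor(x, x)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(bicor(x, 5 - 2 * x)), -1, tolerance = 1e-12)

  xo <- c(1, 2, 3, 4, 100)
  yo <- c(1, 2, 3, 5, 4)
  b <- as.numeric(bicor(xo, yo))
  expect_equal(b, oracle_bicor(xo, yo), tolerance = 1e-12)
  expect_gt(abs(b - cor(xo, yo)), 0.1)   # robust metric disagrees w/ Pearson

  for (i in 1:20) {
    u <- rnorm(15)
    v <- rnorm(15)
    expect_equal(as.numeric(bicor(u, v)), oracle_bicor(u, v),
                 tolerance = 1e-12)
  }

  expect_error(bicor(1:5, 1:4), "length mismatch")
  expect_error(bicor(1:2, 1:2), "length >= 3")
  cst <- suppressWarnings(bicor(rep(1, 10), rnorm(10)))
  expect_true(attr(cst, "fallback"))
})

test_that("bicor and Pearson agree on clean Gaussian data", {
  set.seed(2)
  X <- matrix(rnorm(20 * 1000), nrow = 20)
  C <- cor_matrix(X, "bicor")
  P <- cor(t(X))
  expect_lt(max(abs(C - P)), 0.05)
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 20))
  ## matrix path agrees with the pairwise function
  for (pair in list(c(1, 2), c(3, 17), c(5, 9))) {
    expect_equal(C[pair[1], pair[2]],
                 as.numeric(bicor(X[pair[1], ], X[pair[2], ])),
                 tolerance = 1e-12)
  }
  ## zero-MAD (but non-constant) gene falls back to Pearson pairs
  X[1, ] <- c(rep(3, 998), 5, 1)
  C2 <- cor_matrix(X, "bicor")
  expect_equal(unname(C2[1, 2]), cor(X[1, ], X[2, ]))
})

test_that("signed adjacency obeys closed forms and monotonicity", {
  c2 <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(unname(signed_adjacency(c2, 12)[1, 2]), 2^-12)
  cm <- matrix(c(1, -1, -1, 1), 2)
  expect_equal(unname(signed_adjacency(cm, 12)[1, 2]), 0)
  cp <- matrix(1, 2, 2)
  expect_equal(unname(signed_adjacency(cp, 12)[1, 2]), 1)
  cc <- seq(-1, 1, by = 0.05)
  a <- ((1 + cc) / 2)^12
  expect_true(all(diff(a) > 0))
  expect_error(signed_adjacency(c2, 0.5), "beta")
  asym <- matrix(c(1, 0.2, 0.5, 1), 2)
  expect_error(signed_adjacency(asym, 12), "symmetric")
})

test_that("topological overlap matches closed forms and the brute force", {
  a <- 0.37
  A2 <- matrix(c(1, a, a, 1), 2)
  expect_equal(unname(topological_overlap(A2)[1, 2]), a, tolerance = 1e-12)

  ## maximal overlap: two connected genes sharing every binary neighbour
  A3 <- matrix(0, 4, 4)
  A3[1, 2] <- A3[2, 1] <- 1      # direct connection
  A3[1, 3] <- A3[3, 1] <- 1      # shared neighbour
  A3[2, 3] <- A3[3, 2] <- 1
  diag(A3) <- 1
  expect_equal(unname(topological_overlap(A3)[1, 2]), 1, tolerance = 1e-12)

  set.seed(4)
  for (i in 1:3) {
    n <- 10
    R <- matrix(runif(n * n), n)
    A <- (R + t(R)) / 2
    diag(A) <- 1
    expect_lt(max(abs(topological_overlap(A) - oracle_tom(A))), 1e-10)
  }
  B <- matrix(runif(16), 4)
  expect_error(topological_overlap(B), "symmetric")
})

test_that("variance filter keeps the top half with a stable tie rule", {
  set.seed(6)
  X <- matrix(rnorm(8 * 30), nrow = 8) * (1:8)
  rownames(X) <- paste0("g", 1:8)
  kept <- variance_filter(X)
  expect_equal(nrow(kept), 4L)
  v <- apply(X, 1, var)
  expect_setequal(rownames(kept), names(sort(v, decreasing = TRUE))[1:4])
  ## all-equal variances: everything survives
  Y <- X[rep(1, 6), ]
  rownames(Y) <- paste0("h", 1:6)
  expect_equal(nrow(variance_filter(Y)), 6L)
  ## order invariance
  perm <- sample(nrow(X))
  expect_setequal(rownames(variance_filter(X[perm, ])), rownames(kept))
})

test_that("module detection separates clean orthogonal modules exactly", {
  cfg <- sim_config(seed = 12L, n_genes = 120L, n_lncRNAs = 15L,
                    module_sizes = c(30L, 30L), n_dev_background = 0L,
                    n_dev_samples = 60L, module_strength = 1,
                    n_module_lnc = 5L, n_risk_genes = 10L)
  dev <- simulate_developmental_matrix(cfg)
  filt <- variance_filter(dev$expr)
  part <- detect_modules(filt, network_params())
  truth <- dev$truth$module_labels[names(part$modules)]
  expect_equal(length(part$sizes), 2L)
  expect_equal(ari(part$modules, truth), 1)
  ## gene-order invariance (same partition up to label names)
  perm <- sample(nrow(filt))
  part2 <- detect_modules(filt[perm, ], network_params())
  expect_equal(ari(part2$modules[names(part$modules)], part$modules), 1)
  ## eigengenes are unit variance and track the planted trajectory
  for (m in colnames(part$eigengenes)) {
    expect_equal(sd(part$eigengenes[, m]), 1, tolerance = 1e-9)
  }
  ## a module whose members all equal one trajectory reproduces it
  m1_ids <- names(truth)[truth == "M1"]
  traj <- dev$expr[m1_ids[1], ]
  me <- module_eigengene(dev$expr[m1_ids, ])
  expect_equal(abs(cor(me, traj)), 1, tolerance = 1e-9)
  expect_gt(cor(me, traj), 0)  # orientation follows the mean profile
})

test_that("tiny inputs yield an all-unassigned partition with a warning", {
  X <- matrix(rnorm(5 * 10), 5, dimnames = list(paste0("g", 1:5), NULL))
  expect_warning(part <- detect_modules(X, network_params()), "unassigned")
  expect_true(all(part$modules == "unassigned"))
})

test_that("eigengene-age correlations behave at the extremes", {
  ages <- sort(runif(40, 2, 12))
  fake <- structure(list(
    eigengenes = cbind(aligned = as.numeric(scale(ages)),
                       ortho = as.numeric(scale(residuals(lm(rnorm(40) ~ ages)))))
  ), class = "module_partition")
  r <- eigengene_age_correlation(fake, ages)
  expect_equal(unname(r["aligned"]), 1, tolerance = 1e-9)
  expect_lt(abs(r["ortho"]), 1e-9)

  ## planted monotone module at strength 0.9 tracks age strongly
  cfg <- sim_config(seed = 14L, n_genes = 120L, n_lncRNAs = 10L,
                    module_sizes = c(40L), n_dev_background = 20L,
                    n_dev_samples = 80L, module_strength = 0.9,
                    n_module_lnc = 4L, n_risk_genes = 10L)
  dev <- simulate_developmental_matrix(cfg)
  part <- detect_modules(variance_filter(dev$expr), network_params())
  r2 <- eigengene_age_correlation(part, dev$meta$age_months)
  expect_gt(max(abs(r2)), 0.5)
})

test_that("top correlated gene is found deterministically", {
  set.seed(8)
  ns <- 50
  latent <- rnorm(ns)
  expr <- rbind(
    query = 0.95 * latent + sqrt(1 - 0.95^2) * rnorm(ns),
    partner = 0.95 * latent + sqrt(1 - 0.95^2) * rnorm(ns),
    matrix(rnorm(8 * ns), 8, dimnames = list(paste0("bg", 1:8), NULL))
  )
  got <- top_correlated_gene(expr, "query", c("partner", paste0("bg", 1:8)))
  expect_equal(got$gene_id, "partner")
  expect_gt(got$correlation, 0.8)
  ## identical profile gives correlation 1 and beats everything
  expr2 <- rbind(expr, twin = expr["query", ])
  got2 <- top_correlated_gene(expr2, "query", rownames(expr2))
  expect_equal(got2$gene_id, "twin")
  expect_equal(got2$correlation, 1, tolerance = 1e-12)
  ## invariant to candidate order
  got3 <- top_correlated_gene(expr, "query", rev(c("partner", paste0("bg", 1:8))))
  expect_identical(got3$gene_id, got$gene_id)
  expect_error(top_correlated_gene(expr, "query", character(0)), "candidate")
})
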