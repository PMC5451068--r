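two_group_sheet <- function(n_per_group) {
  data.frame(
    sample = paste0("s", seq_len(2 * n_per_group)),
    condition = rep(c("case", "control"), each = n_per_group),
    subject = paste0("s", seq_len(2 * n_per_group)),
    stringsAsFactors = FALSE
  )
}

test_that("technical replicates collapse by summation", {
  counts <- matrix(c(3L, 4L, 10L, 20L), nrow = 1,
                   dimnames = list("g1", c("a_r1", "a_r2", "b_r1", "b_r2")))
  samples <- data.frame(sample = colnames(counts),
                        condition = c("case", "case", "control", "control"),
                        subject = c("a", "a", "b", "b"))
  got <- collapse_technical_replicates(counts, samples)
  expect_identical(got$counts[1, ], c(a = 7L, b = 30L))

  ## single-replicate samples pass through unchanged
  single <- collapse_technical_replicates(
    counts[, c(1, 3), drop = FALSE],
    samples[c(1, 3), ][, ]
  )
  expect_identical(unname(single$counts[1, ]), c(3L, 10L))

  ## the standard design: 6 biological x 2 technical -> 6 columns
  cfg <- small_sim_config()
  cc <- simulate_case_control_counts(cfg)
  expect_identical(ncol(cc$counts), 12L)
  coll <- collapse_technical_replicates(cc$counts, cc$samples)
  expect_identical(ncol(coll$counts), 6L)
  expect_identical(unname(coll$counts[, "case1"]),
                   unname(cc$counts[, "case1_r1"] + cc$counts[, "case1_r2"]))

  bad <- samples
  bad$subject <- "a"
  expect_error(collapse_technical_replicates(counts, bad), "span")
})

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(unname(size_factors(same)), rep(1, 3), tolerance = 1e-12)

  set.seed(7)
  r <- matrix(rnbinom(200, mu = 50, size = 5) + 1L, ncol = 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  expect_equal(unname(size_factors(r)), unname(oracle_size_factors(r)),
               tolerance = 1e-12)

  allzero <- matrix(c(0L, 5L, 3L, 0L), ncol = 2)
  expect_error(size_factors(allzero), "pseudo-reference")
})

test_that("dispersion estimation recovers the truth and flags edge cases", {
  set.seed(11)
  n <- 2000
  cond <- rep(c("case", "control"), each = 200)
  ## Poisson data: moment numerator <= 0, estimate pinned at the floor
  pois <- matrix(rpois(50 * 8, 100), nrow = 50,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  dp <- estimate_dispersion(pois, rep(1, 8), rep(c("case", "control"), each = 4),
                            mom_weight = 1)
  expect_lt(median(dp$alpha), 0.02)

  ## NB truth alpha = 0.2 at n = 200/group, shrinkage off
  nb <- matrix(rnbinom(n * 400, mu = 100, size = 5), nrow = n,
               dimnames = list(paste0("g", 1:n), paste0("s", 1:400)))
  dn <- estimate_dispersion(nb, rep(1, 400), cond, mom_weight = 1)
  expect_gt(median(dn$alpha), 0.15)
  expect_lt(median(dn$alpha), 0.25)

  ## all-zero gene is untestable
  nb[1, ] <- 0L
  dz <- estimate_dispersion(nb, rep(1, 400), cond)
  expect_false(dz$testable[1])
  expect_true(is.na(dz$alpha[1]))
})

test_that("Wald test applies the inclusive significance rule", {
  cfg <- small_sim_config(seed = 8L)
  cc <- simulate_case_control_counts(cfg)
  coll <- collapse_technical_replicates(cc$counts, cc$samples)
  de <- nb_wald_test(coll$counts, coll$samples)
  ok <- de$status == "ok"
  expect_true(all(de$adj_p[ok] >= de$p[ok]))
  expect_identical(de$significant,
                   !is.na(de$adj_p) & de$adj_p < 0.05 & abs(de$log2fc) >= 1)
  ## untestable / non-converged genes carry NA p and are never significant
  expect_true(all(is.na(de$p[!ok])))
  expect_true(all(!de$significant[!ok]))
  ## planted signal is detected with the planted sign
  tr <- cc$truth$de_genes
  hit <- de[match(tr$gene_id, de$gene_id), ]
  expect_gt(mean(hit$significant), 0.7)
  expect_true(all(sign(hit$log2fc[hit$significant]) ==
                    sign(tr$planted_log2fc[hit$significant])))
})

test_that("swapping group labels negates fold changes, keeps p-values", {
  cfg <- small_sim_config(seed = 9L)
  cc <- simulate_case_control_counts(cfg)
  coll <- collapse_technical_replicates(cc$counts, cc$samples)
  de1 <- nb_wald_test(coll$counts, coll$samples)
  de2 <- nb_wald_test(coll$counts, coll$samples,
                      case = "control", control = "case")
  ok <- de1$status == "ok" & de2$status == "ok"
  expect_equal(de1$log2fc[ok], -de2$log2fc[ok], tolerance = 1e-9)
  expect_equal(de1$p[ok], de2$p[ok], tolerance = 1e-9)
})

test_that("rescaling one sample moves its size factor, not the estimates", {
  set.seed(13)
  n <- 1000
  sheet <- two_group_sheet(50)
  mu <- rlnorm(n, log(100), 1)
  counts <- sapply(seq_len(100), function(j) rnbinom(n, mu = mu, size = 20))
  dimnames(counts) <- list(paste0("g", 1:n), sheet$sample)
  sf1 <- size_factors(counts)
  scaled <- counts
  scaled[, 1] <- scaled[, 1] * 3L
  sf2 <- size_factors(scaled)
  expect_equal(unname((sf2[1] / sf1[1]) / (sf2[2] / sf1[2])), 3,
               tolerance = 0.02)
  de1 <- nb_wald_test(counts, sheet)
  de2 <- nb_wald_test(scaled, sheet)
  expect_lt(mean(abs(de1$log2fc - de2$log2fc), na.rm = TRUE), 0.05)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(21)
  for (i in 1:5) {
    p <- runif(50)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
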