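test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(module_strength = -0.1), "module_strength")
  expect_error(sim_config(n_genes = 300, n_lncRNAs = 30, module_sizes = c(200L, 150L)),
               "module_sizes")
  expect_error(sim_config(n_brain_tissues = 30, n_tissues = 10),
               "n_brain_tissues")
  expect_error(
    simulate_ground_truth(sim_config(n_genes = 2000, de_fraction = 1e-4)),
    "DE genes")
})

test_that("ground truth is internally consistent and covered by annotation", {
  truth <- simulate_ground_truth(small_sim_config())
  all_ids <- truth$annotation$gene_id
  expect_true(all(truth$de_genes$gene_id %in% all_ids))
  expect_true(all(truth$lncRNA_ids %in% all_ids))
  expect_true(all(unlist(truth$risk_sets) %in% all_ids))
  expect_true(all(truth$brain_selective %in% all_ids))
  expect_true(all(names(truth$cnv_hits) %in% all_ids))
  ## planted lncRNAs have lncRNA biotypes, risk genes are protein-coding
  bio <- setNames(truth$annotation$biotype, all_ids)
  expect_true(all(bio[truth$lncRNA_ids] != "protein_coding"))
  expect_true(all(bio[truth$risk_sets$risk_primary] == "protein_coding"))
  ## gene intervals are valid and non-overlapping per chromosome
  ann <- truth$annotation
  expect_true(all(ann$start < ann$end))
  for (ch in unique(ann$chrom)) {
    a <- ann[ann$chrom == ch, ]
    a <- a[order(a$start), ]
    expect_true(all(head(a$end, -1) <= a$start[-1]))
  }
})

test_that("count simulation honours planted effects and determinism", {
  cfg0 <- small_sim_config(de_fraction = 0)
  expect_equal(nrow(simulate_case_control_counts(cfg0)$truth$de_genes), 0)

  cfg_null <- small_sim_config(seed = 4L, de_log2fc = 0, n_case = 30L,
                               n_control = 30L, n_tech_reps = 1L)
  cc <- simulate_case_control_counts(cfg_null)
  expect_true(all(cc$truth$de_genes$planted_log2fc == 0))
  case <- cc$samples$condition == "case"
  lr <- log2(rowMeans(cc$counts[, case]) + 1) -
    log2(rowMeans(cc$counts[, !case]) + 1)
  de_rows <- match(cc$truth$de_genes$gene_id, rownames(cc$counts))
  expect_lt(mean(abs(lr[de_rows])), 0.15)

  cfg <- sim_config(seed = 1L, n_genes = 2000L, de_fraction = 0.05,
                    n_lncRNAs = 100L, module_sizes = c(60L, 40L),
                    n_dev_background = 900L)
  a <- simulate_case_control_counts(cfg)
  b <- simulate_case_control_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
})

test_that("planted log2 fold changes are recovered at large replication", {
  cfg <- small_sim_config(seed = 5L, n_case = 50L, n_control = 50L,
                          n_tech_reps = 1L)
  cc <- simulate_case_control_counts(cfg)
  norm <- sweep(cc$counts, 2, size_factors(cc$counts), "/")
  case <- cc$samples$condition == "case"
  emp <- log2(rowMeans(norm[, case])) - log2(rowMeans(norm[, !case]))
  tr <- cc$truth$de_genes
  err <- abs(emp[match(tr$gene_id, rownames(norm))] - tr$planted_log2fc)
  expect_lt(mean(err), 0.1)
})

test_that("developmental matrix plants recoverable module structure", {
  ## perfect loading: within-module correlations are exactly +/-1
  cfg1 <- small_sim_config(module_strength = 1)
  dev <- simulate_developmental_matrix(cfg1)
  m1 <- dev$expr[dev$truth$module_labels == "M1", ]
  cc <- cor(t(m1))
  expect_equal(max(abs(abs(cc) - 1)), 0, tolerance = 1e-12)
  expect_true(all(dev$expr >= 0))

  ## determinism
  dev2 <- simulate_developmental_matrix(cfg1)
  expect_identical(dev$expr, dev2$expr)

  ## zero loading: module genes look like background (Monte-Carlo)
  diffs <- vapply(1:20, function(s) {
    cfg0 <- sim_config(seed = s, n_genes = 120L, n_lncRNAs = 12L,
                       module_sizes = c(30L, 20L), n_dev_background = 40L,
                       n_dev_samples = 200L, module_strength = 0,
                       n_module_lnc = 4L, n_risk_genes = 8L)
    d <- simulate_developmental_matrix(cfg0)
    lab <- d$truth$module_labels
    within <- cor(t(d$expr[lab == "M1", ]))
    bg_ids <- names(lab)[lab == "background"][1:30]
    bg <- cor(t(d$expr[bg_ids, ]))
    mean(abs(within[upper.tri(within)])) - mean(abs(bg[upper.tri(bg)]))
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("tissue matrix makes planted genes brain-selective", {
  cfg <- small_sim_config(seed = 2L)
  tis <- simulate_tissue_matrix(cfg)
  expect_identical(dim(tis$expr), c(cfg$n_genes, cfg$n_tissues))
  expect_true(all(tis$panel$n_samples > 0))
  ## extreme inflation drives fractional brain expression to 100
  cfg_inf <- small_sim_config(seed = 2L, brain_inflation = 1e9)
  tis_inf <- simulate_tissue_matrix(cfg_inf)
  panel <- tis_inf$panel
  sel <- tis_inf$truth$brain_selective[1]
  row <- tis_inf$expr[sel, panel$tissue]
  fbe <- 100 * sum(row[panel$is_brain]) / sum(row)
  expect_gt(fbe, 99.99)
  expect_identical(tis$expr, simulate_tissue_matrix(cfg)$expr)
})

test_that("planted CNVs cover their designated lncRNAs", {
  cfg <- small_sim_config(seed = 3L)
  sim <- simulate_cnvs(cfg)
  counts <- cnv_overlap_counts(sim$truth$annotation, sim$cnvs)
  for (gid in names(sim$truth$cnv_hits)) {
    expect_gte(counts[[gid]], sim$truth$cnv_hits[[gid]])
  }
  expect_identical(sim$cnvs, simulate_cnvs(cfg)$cnvs)
  expect_true(all(sim$cnvs$start < sim$cnvs$end))
})
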