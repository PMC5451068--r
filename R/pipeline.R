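#' Run the full pipeline on a simulated dataset
#'
#' Orchestrates every stage in dependency order: simulate inputs, collapse
#' technical replicates and test differential expression, score tissue
#' selectivity, build the signed co-expression network on the
#' variance-filtered developmental matrix and detect modules, run the three
#' permutation tests, compute Fisher enrichment of the risk-gene and
#' DE-lncRNA sets per module, count CNV overlaps (Major reports only) and
#' produce the final ranked candidate table.  All outputs are written as
#' TSV under `outdir` together with a JSON run manifest carrying the
#' resolved configuration, the seed and an md5 content hash for every file;
#' re-running with the same config and seed reproduces the hashes.
#'
#' A failure inside a stage halts the run with a stage-named error; outputs
#' of completed stages remain on disk.
#'
#' @param outdir output directory (created if missing).
#' @param config run configuration from [read_run_config()] /
#'   [default_run_config()].
#' @param sim_cfg simulation configuration; defaults to [sim_config()] with
#'   the run seed.
#' @return list (invisibly) with all stage results and the `manifest`.
#' @export
#' @examples
#' \donttest{
#' cfg <- read_run_config(overrides = list(n_perm = 200L, seed = 7L))
#' res <- run_all(tempfile("run"), config = cfg)
#' head(res$priority)
#' }
run_all <- function(outdir, config = default_run_config(),
                    sim_cfg = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(sim_cfg)) sim_cfg <- sim_config(seed = config$seed)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- character(0)
  add_path <- function(p) paths[[length(paths) + 1L]] <<- p

  ## 1. simulate
  sim <- run_stage("simulate", simulate_dataset(sim_cfg))
  data_paths <- write_dataset(sim, file.path(outdir, "data"))
  for (p in data_paths) add_path(p)

  ## 2. differential expression (technical replicates collapsed by sum)
  de <- run_stage("de", {
    coll <- collapse_technical_replicates(sim$counts, sim$samples)
    nb_wald_test(coll$counts, coll$samples, alpha = config$alpha,
                 lfc_min = config$lfc_min, mom_weight = config$dispersion_mom_weight)
  })
  de_path <- file.path(outdir, "de.tsv")
  write_table_tsv(de, de_path)
  add_path(de_path)
  de_lnc <- intersect(de$gene_id[de$significant],
                      sim$annotation$gene_id[is_lncRNA(sim$annotation)])

  ## 3. tissue selectivity
  tissue <- run_stage("tissue", specificity_scores(
    sim$tissue_expr, sim$tissue_panel,
    threshold = config$specificity_threshold,
    min_samples = config$tissue_min_samples
  ))
  tissue_path <- file.path(outdir, "specificity.tsv")
  write_table_tsv(tissue$scores, tissue_path)
  add_path(tissue_path)

  ## 4. network
  net <- run_stage("network", {
    filtered <- variance_filter(sim$dev_expr)
    params <- network_params(beta = config$beta,
                             min_module_size = config$min_module_size,
                             cut_quantile = config$cut_quantile,
                             cor_method = config$cor_method)
    detect_modules(filtered, params)
  })
  net_expr <- sim$dev_expr[names(net$modules), , drop = FALSE]
  assign_path <- file.path(outdir, "modules.tsv")
  write_table_tsv(data.frame(gene_id = names(net$modules),
                             module = unname(net$modules),
                             membership = unname(net$membership)),
                  assign_path)
  add_path(assign_path)
  eig_path <- file.path(outdir, "eigengenes.tsv")
  write_table_tsv(data.frame(sample = rownames(net$eigengenes),
                             net$eigengenes, check.names = FALSE),
                  eig_path)
  add_path(eig_path)

  ## shared correlation matrix for the permutation statistics
  corr <- cor_matrix(net_expr, config$cor_method)

  ## 5. permutation tests
  perm_coexpr <- run_stage("perm_coexpr", module_coexpression_test(
    net_expr, net, B = config$n_perm,
    seed = stage_seed(config$seed, "perm_coexpr"), corr = corr
  ))
  perm_overlay <- run_stage("perm_overlay", module_de_overlay_test(
    net, de, B = config$n_perm,
    seed = stage_seed(config$seed, "perm_overlay")
  ))
  gene_sets <- c(sim$gene_lists, list(de_lncRNA = de_lnc))
  perm_setcor <- run_stage("perm_setcor", {
    if (length(de_lnc) >= 1) {
      lncrna_geneset_coexpression_test(
        net_expr, de_lnc, sim$gene_lists, B = config$n_perm,
        seed = stage_seed(config$seed, "perm_setcor"), corr = corr
      )
    } else {
      NULL
    }
  })
  for (nm in c("perm_coexpr", "perm_overlay", "perm_setcor")) {
    obj <- get(nm)
    if (!is.null(obj)) {
      f <- file.path(outdir, paste0(nm, ".tsv"))
      write_table_tsv(obj, f)
      add_path(f)
    }
  }

  ## 6. enrichment
  enrich <- run_stage("enrich", enrichment_table(
    net, gene_sets, alpha = config$alpha
  ))
  enrich_path <- file.path(outdir, "enrichment.tsv")
  write_table_tsv(enrich, enrich_path)
  add_path(enrich_path)

  ## 7. CNV overlaps (Major reports only)
  overlaps <- run_stage("cnv", {
    major <- sim$cnvs[sim$cnvs$report_class == "Major", , drop = FALSE]
    cnv_overlap_counts(sim$annotation, major)
  })

  ## 8. prioritization
  priority <- run_stage("prioritize", {
    candidates <- intersect(de_lnc, names(net$modules))
    pc <- sim$annotation$gene_id[!is_lncRNA(sim$annotation)]
    pc_net <- intersect(pc, names(net$modules))
    top_corr <- do.call(rbind, lapply(candidates, function(g) {
      tc <- top_correlated_gene(net_expr, g, pc_net,
                                method = config$cor_method)
      data.frame(gene_id = g, top_gene = tc$gene_id,
                 correlation = tc$correlation, stringsAsFactors = FALSE)
    }))
    risk_scores <- setNames(rep(1, length(sim$gene_lists$risk_primary)),
                            sim$gene_lists$risk_primary)
    rank_candidates(
      de_lnc, net, enrich, overlaps, specificity = tissue$scores, de = de,
      top_corr = top_corr, risk_set_names = names(sim$gene_lists),
      lnc_set_name = "de_lncRNA", risk_scores = risk_scores
    )
  })
  priority_path <- file.path(outdir, "priority.tsv")
  write_table_tsv(priority, priority_path)
  add_path(priority_path)

  manifest <- list(
    config = config,
    sim_config = unclass(sim_cfg),
    seed = config$seed,
    n_de_genes = sum(de$significant, na.rm = TRUE),
    n_de_lncRNAs = length(de_lnc),
    n_modules = length(net$sizes),
    files = as.list(tools::md5sum(unlist(paths))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    sim = sim, de = de, tissue = tissue, network = net,
    perm_coexpr = perm_coexpr, perm_overlay = perm_overlay,
    perm_setcor = perm_setcor, enrichment = enrich,
    cnv_overlaps = overlaps, priority = priority, manifest = manifest
  ))
}
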