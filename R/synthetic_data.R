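#' Planted ground truth for a simulated dataset
#'
#' Derives, deterministically from the configuration, the full planted
#' structure shared by every generator: gene annotation (ids, biotypes,
#' non-overlapping coordinates on an artificial genome), planted DE genes
#' with signed effect sizes, planted co-expression module labels, the
#' risk-gene lists, the brain-selective gene set, and which lncRNAs are hit
#' by planted CNVs.  All generators call this first, so a lncRNA planted to
#' be simultaneously differentially expressed, co-assigned with the risk
#' genes and CNV-hit is consistent across the count matrix, the
#' developmental matrix, the tissue panel, the CNV table and the gene lists.
#'
#' The layout is convergence-by-construction: the first module hosts both
#' planted lncRNAs (forced into the DE set, down-regulated) and the
#' protein-coding risk genes; remaining planted lncRNAs are spread over the
#' other modules and the background.
#'
#' @param cfg a [sim_config()] object.
#' @return A list of class `lnc_ground_truth` with elements `annotation`,
#'   `module_labels` (named vector, `"background"` for unstructured genes),
#'   `de_genes` (data.frame of `gene_id`, `planted_log2fc`),
#'   `lncRNA_ids`, `risk_sets` (named list of id vectors),
#'   `brain_selective`, `cnv_hits` (named integer vector of planted overlap
#'   counts per gene), `top_lncRNAs` (ids expected to lead the final
#'   ranking) and `dev_gene_tier` (high / low variance tier in the
#'   developmental matrix).
#' @export
simulate_ground_truth <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "annotation"))

  n <- cfg$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))

  ## module labels: contiguous blocks at the head of the gene list
  module_labels <- rep("background", n)
  pos <- 1L
  for (m in seq_along(cfg$module_sizes)) {
    sz <- cfg$module_sizes[m]
    module_labels[pos:(pos + sz - 1L)] <- paste0("M", m)
    pos <- pos + sz
  }
  names(module_labels) <- gene_id

  ## variance tier in the developmental matrix: module genes plus a block of
  ## variable background genes pass the variance filter; the rest do not
  n_struct <- sum(cfg$module_sizes)
  dev_gene_tier <- rep("low", n)
  if (n_struct > 0L) dev_gene_tier[seq_len(n_struct)] <- "high"
  if (cfg$n_dev_background > 0L) {
    dev_gene_tier[n_struct + seq_len(cfg$n_dev_background)] <- "high"
  }
  names(dev_gene_tier) <- gene_id

  ## lncRNA placement: head of module 1, a few per remaining module, rest in
  ## the variable background
  lnc_idx <- integer(0)
  if (cfg$n_module_lnc > 0L && length(cfg$module_sizes) > 0L) {
    lnc_idx <- seq_len(cfg$n_module_lnc)
  }
  per_other <- 4L
  if (length(cfg$module_sizes) > 1L) {
    start <- cfg$module_sizes[1]
    for (m in 2:length(cfg$module_sizes)) {
      k <- min(per_other, cfg$module_sizes[m])
      avail <- cfg$n_lncRNAs - length(lnc_idx)
      if (avail <= 0L) break
      lnc_idx <- c(lnc_idx, start + seq_len(min(k, avail)))
      start <- start + cfg$module_sizes[m]
    }
  }
  n_left <- cfg$n_lncRNAs - length(lnc_idx)
  if (n_left > 0L) {
    pool <- setdiff(which(module_labels == "background"), lnc_idx)
    lnc_idx <- c(lnc_idx, sort(sample(pool, min(n_left, length(pool)))))
  }
  lnc_idx <- sort(unique(lnc_idx))

  biotype <- rep("protein_coding", n)
  lnc_biotypes <- c("lincRNA", "antisense", "processed_transcript",
                    "sense_intronic", "other_lncRNA")
  ## mix leans intergenic/antisense, matching observed lncRNA class balance
  biotype[lnc_idx] <- sample(lnc_biotypes, length(lnc_idx), replace = TRUE,
                             prob = c(0.45, 0.41, 0.06, 0.04, 0.04))
  lncRNA_ids <- gene_id[lnc_idx]

  ## risk genes: protein-coding members of module 1 right after the planted
  ## lncRNAs, plus a handful outside the module (primary list); a secondary,
  ## module-derived list covers a wider slice of module 1
  risk_core <- integer(0)
  risk_secondary <- character(0)
  if (length(cfg$module_sizes) > 0L && cfg$n_risk_genes > 0L) {
    m1_idx <- which(module_labels == "M1")
    m1_pc <- setdiff(m1_idx, lnc_idx)
    risk_core <- m1_pc[seq_len(min(cfg$n_risk_genes, length(m1_pc)))]
    risk_secondary <- gene_id[m1_pc[seq_len(min(2L * cfg$n_risk_genes,
                                                length(m1_pc)))]]
  }
  out_pool <- setdiff(which(module_labels == "background" &
                              biotype == "protein_coding"), risk_core)
  risk_extra <- sort(sample(out_pool, min(5L, length(out_pool))))
  risk_sets <- list(
    risk_primary = gene_id[sort(c(risk_core, risk_extra))],
    risk_secondary = risk_secondary
  )

  ## planted DE genes: module-1 lncRNAs forced in (down-regulated, the
  ## direction of the synaptic module), then module-2 lncRNAs (up), then a
  ## random fill with random signs
  n_de <- round(cfg$de_fraction * n)
  if (cfg$de_fraction > 0 && n_de < 1) {
    stop("de_fraction * n_genes < 1: no DE genes can be planted")
  }
  de_idx <- integer(0)
  de_sign <- numeric(0)
  if (n_de > 0L) {
    m1_lnc <- intersect(lnc_idx, which(module_labels == "M1"))
    m2_lnc <- intersect(lnc_idx, which(module_labels == "M2"))
    forced <- c(m1_lnc, m2_lnc)
    forced <- forced[seq_len(min(n_de, length(forced)))]
    forced_sign <- c(rep(-1, length(intersect(forced, m1_lnc))),
                     rep(+1, length(intersect(forced, m2_lnc))))
    fill_pool <- setdiff(seq_len(n), forced)
    n_fill <- n_de - length(forced)
    fill <- if (n_fill > 0L) sort(sample(fill_pool, n_fill)) else integer(0)
    fill_sign <- sample(c(-1, 1), length(fill), replace = TRUE)
    de_idx <- c(forced, fill)
    de_sign <- c(forced_sign, fill_sign)
  }
  de_genes <- data.frame(
    gene_id = gene_id[de_idx],
    planted_log2fc = de_sign * cfg$de_log2fc,
    stringsAsFactors = FALSE
  )

  ## brain-selective genes: all module-1 lncRNAs plus half of the remaining
  ## DE lncRNAs plus a few non-DE lncRNAs
  de_lnc <- intersect(de_genes$gene_id, lncRNA_ids)
  m1_lnc_ids <- gene_id[intersect(lnc_idx, which(module_labels == "M1"))]
  other_de_lnc <- setdiff(de_lnc, m1_lnc_ids)
  sel_extra <- if (length(other_de_lnc) > 0L) {
    sort(sample(other_de_lnc, ceiling(length(other_de_lnc) / 2)))
  } else character(0)
  non_de_lnc <- setdiff(lncRNA_ids, c(de_lnc, m1_lnc_ids))
  sel_non_de <- if (length(non_de_lnc) > 0L) {
    sort(sample(non_de_lnc, min(5L, length(non_de_lnc))))
  } else character(0)
  brain_selective <- unique(c(m1_lnc_ids, sel_extra, sel_non_de))

  ## planted CNV hits: the first module-1 lncRNA is the designed top
  ## candidate (5 overlapping CNVs); the next two get 2 and 1
  cnv_hits <- integer(0)
  top_lncRNAs <- character(0)
  if (length(m1_lnc_ids) > 0L && cfg$n_cnvs > 0L) {
    planted <- c(5L, 2L, 1L)[seq_len(min(3L, length(m1_lnc_ids)))]
    cnv_hits <- setNames(planted, m1_lnc_ids[seq_along(planted)])
    cnv_hits <- cnv_hits[cumsum(cnv_hits) <= cfg$n_cnvs]
    top_lncRNAs <- names(cnv_hits)[1]
  }

  ## non-overlapping coordinates, round-robin over artificial chromosomes
  chrom <- paste0("chr", ((seq_len(n) - 1L) %% cfg$n_chroms) + 1L)
  slot <- (seq_len(n) - 1L) %/% cfg$n_chroms
  gene_len <- 2000L
  gap <- 1000L
  start <- slot * (gene_len + gap)
  end <- start + gene_len
  if (max(end) > cfg$genome_length) {
    stop("genome_length too small for n_genes gene slots")
  }
  annotation <- data.frame(
    gene_id = gene_id,
    symbol = paste0("SYM", seq_len(n)),
    biotype = biotype,
    chrom = chrom,
    start = start,
    end = end,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  structure(list(
    annotation = annotation,
    module_labels = module_labels,
    dev_gene_tier = dev_gene_tier,
    de_genes = de_genes,
    lncRNA_ids = lncRNA_ids,
    risk_sets = risk_sets,
    brain_selective = brain_selective,
    cnv_hits = cnv_hits,
    top_lncRNAs = top_lncRNAs
  ), class = "lnc_ground_truth")
}

#' Simulate a case/control RNA-seq count matrix
#'
#' Counts are drawn from a negative-binomial model with a lognormal baseline
#' mean per gene, per-sample size factors drawn around 1, and dispersion
#' `alpha` so that `variance = mu + alpha * mu^2`.  Planted DE genes have
#' their case-group mean multiplied by `2^planted_log2fc`; technical
#' replicates of the same biological sample share the biological mean but
#' receive independent NB draws (sequencing noise).  Planted DE baselines are
#' kept at a mean of at least 100 so the planted effect is detectable at the
#' simulated depth.
#'
#' @param cfg a [sim_config()] object.
#' @return list with `counts` (integer gene x sample matrix), `samples`
#'   (data.frame `sample`, `condition`, `subject`) and `truth`
#'   (the shared [simulate_ground_truth()] object).
#' @export
simulate_case_control_counts <- function(cfg) {
  truth <- simulate_ground_truth(cfg)
  set.seed(stage_seed(cfg$seed, "counts"))

  n <- cfg$n_genes
  subjects <- c(paste0("case", seq_len(cfg$n_case)),
                paste0("ctrl", seq_len(cfg$n_control)))
  condition_by_subject <- rep(c("case", "control"),
                              c(cfg$n_case, cfg$n_control))
  samples <- data.frame(
    sample = paste0(rep(subjects, each = cfg$n_tech_reps), "_r",
                    rep(seq_len(cfg$n_tech_reps), length(subjects))),
    condition = rep(condition_by_subject, each = cfg$n_tech_reps),
    subject = rep(subjects, each = cfg$n_tech_reps),
    stringsAsFactors = FALSE
  )

  mu <- rlnorm(n, meanlog = log(150), sdlog = 1.2)
  de_pos <- match(truth$de_genes$gene_id, truth$annotation$gene_id)
  mu[de_pos] <- pmax(mu[de_pos], 100)

  lfc <- rep(0, n)
  lfc[de_pos] <- truth$de_genes$planted_log2fc
  mu_case <- mu * 2^lfc
  mu_ctrl <- mu

  sf <- rlnorm(nrow(samples), 0, 0.1)
  size <- if (cfg$nb_dispersion > 0) 1 / cfg$nb_dispersion else Inf

  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(truth$annotation$gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    m <- if (samples$condition[j] == "case") mu_case else mu_ctrl
    counts[, j] <- rnbinom(n, mu = m * sf[j], size = size)
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate a developmental expression matrix with planted modules
#'
#' Each planted module is driven by a latent trajectory over age
#' (monotone in log-age, sinusoidal, or age-flat — a shared random factor —
#' assigned round-robin): for member gene g and sample j,
#' `x_gj = r * f_m(age_j) + sqrt(1 - r^2) * noise`, with `r` the
#' `module_strength` loading.  A configured block of background genes is
#' equally variable but unstructured; the remaining genes get low variance so
#' the standard across-sample variance filter removes them.  Ages are drawn
#' log-uniformly over `age_range_months` (dense early sampling) and the final
#' matrix is shifted to be nonnegative.
#'
#' @param cfg a [sim_config()] object.
#' @return list with `expr` (gene x sample matrix), `meta` (data.frame
#'   `sample`, `age_months`) and `truth`.
#' @export
simulate_developmental_matrix <- function(cfg) {
  truth <- simulate_ground_truth(cfg)
  set.seed(stage_seed(cfg$seed, "development"))

  ns <- cfg$n_dev_samples
  ages <- sort(exp(runif(ns, log(cfg$age_range_months[1]),
                         log(cfg$age_range_months[2]))))
  meta <- data.frame(sample = sprintf("D%03d", seq_len(ns)),
                     age_months = ages, stringsAsFactors = FALSE)

  zscale <- function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  ## round-robin trajectory kinds; repeats of a kind are made distinct
  ## (sign flip / phase shift / fresh random factor) so that every module is
  ## separable in a signed network
  latent_for <- function(m) {
    kind <- c("monotone", "sinusoid", "flat")[((m - 1L) %% 3L) + 1L]
    pass <- (m - 1L) %/% 3L
    t01 <- (log(ages) - log(cfg$age_range_months[1])) /
      (log(cfg$age_range_months[2]) - log(cfg$age_range_months[1]))
    base <- switch(kind,
      monotone = log(ages) * (-1)^pass,
      ## cosine harmonics: orthogonal to the monotone trend and to each other
      sinusoid = cos(2 * pi * (pass + 1) * t01),
      flat = rnorm(ns)
    )
    zscale(base)
  }

  n <- cfg$n_genes
  r <- cfg$module_strength
  sd_hi <- 2
  sd_lo <- 0.5
  expr <- matrix(0, nrow = n, ncol = ns,
                 dimnames = list(truth$annotation$gene_id, meta$sample))
  latents <- lapply(seq_along(cfg$module_sizes), latent_for)
  for (g in seq_len(n)) {
    lab <- truth$module_labels[g]
    if (lab != "background") {
      m <- as.integer(sub("^M", "", lab))
      expr[g, ] <- sd_hi * (r * latents[[m]] + sqrt(1 - r^2) * rnorm(ns))
    } else if (truth$dev_gene_tier[g] == "high") {
      expr[g, ] <- sd_hi * rnorm(ns)
    } else {
      expr[g, ] <- sd_lo * rnorm(ns)
    }
  }
  expr <- expr - min(expr)
  list(expr = expr, meta = meta, truth = truth)
}

#' Simulate a multi-tissue median-expression panel
#'
#' Median expression per gene per tissue drawn lognormally; planted
#' brain-selective genes get their brain-tissue means multiplied by
#' `brain_inflation`, pushing their fractional brain expression above the
#' 50 percent selectivity threshold.  A few non-brain tissues are given fewer
#' than 50 samples so the minimum-sample filter has something to remove.
#'
#' @param cfg a [sim_config()] object.
#' @return list with `expr` (gene x tissue matrix), `panel` (data.frame
#'   `tissue`, `n_samples`, `is_brain`) and `truth`.
#' @export
simulate_tissue_matrix <- function(cfg) {
  truth <- simulate_ground_truth(cfg)
  set.seed(stage_seed(cfg$seed, "tissue"))

  nt <- cfg$n_tissues
  nb <- cfg$n_brain_tissues
  is_brain <- c(rep(TRUE, nb), rep(FALSE, nt - nb))
  tissue <- ifelse(is_brain,
                   paste0("brain_", seq_len(nt)),
                   paste0("tissue_", seq_len(nt)))
  n_samples <- 50L + as.integer(runif(nt, 10, 150))
  small <- which(!is_brain)
  small <- small[seq_len(min(cfg$n_small_tissues, length(small)))]
  n_samples[small] <- as.integer(runif(length(small), 20, 49))
  panel <- data.frame(tissue = tissue, n_samples = n_samples,
                      is_brain = is_brain, stringsAsFactors = FALSE)

  n <- cfg$n_genes
  expr <- matrix(rlnorm(n * nt, meanlog = 0, sdlog = 0.5), nrow = n,
                 dimnames = list(truth$annotation$gene_id, tissue))
  sel <- match(truth$brain_selective, truth$annotation$gene_id)
  expr[sel, is_brain] <- expr[sel, is_brain] * cfg$brain_inflation
  list(expr = expr, panel = panel, truth = truth)
}

#' Simulate the gene annotation table
#'
#' @param cfg a [sim_config()] object.
#' @return list with `annotation` (data.frame) and `truth`.
#' @export
simulate_annotation <- function(cfg) {
  truth <- simulate_ground_truth(cfg)
  list(annotation = truth$annotation, truth = truth)
}

#' Simulate a CNV interval table
#'
#' Planted CNVs are placed directly over the spans of the designated
#' candidate lncRNAs (with small random extensions) and carry report class
#' `"Major"`; the remaining CNVs are random intervals with a mixed report
#' class, so the class filter and the overlap counter both have work to do.
#'
#' @param cfg a [sim_config()] object.
#' @return list with `cnvs` (data.frame `cnv_id`, `chrom`, `start`, `end`,
#'   `report_class`; 0-based half-open) and `truth`.
#' @export
simulate_cnvs <- function(cfg) {
  truth <- simulate_ground_truth(cfg)
  set.seed(stage_seed(cfg$seed, "cnv"))

  ann <- truth$annotation
  planted <- truth$cnv_hits
  rows <- list()
  for (gid in names(planted)) {
    g <- ann[ann$gene_id == gid, ]
    for (k in seq_len(planted[[gid]])) {
      ext_l <- as.integer(runif(1, 0, 500))
      ext_r <- as.integer(runif(1, 0, 500))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = max(0L, g$start - ext_l),
        end = g$end + ext_r, report_class = "Major",
        stringsAsFactors = FALSE
      )
    }
  }
  n_random <- cfg$n_cnvs - length(rows)
  if (n_random < 0L) stop("n_cnvs too small for planted CNV hits")
  if (n_random > 0L) {
    chrom <- paste0("chr", sample.int(cfg$n_chroms, n_random, replace = TRUE))
    width <- as.integer(runif(n_random, 5e3, 5e4))
    start <- as.integer(runif(n_random, 0, cfg$genome_length - width))
    cls <- sample(c("Major", "Minor"), n_random, replace = TRUE,
                  prob = c(0.8, 0.2))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = start, end = start + width,
      report_class = cls, stringsAsFactors = FALSE
    )
  }
  cnvs <- do.call(rbind, rows)
  cnvs <- data.frame(cnv_id = sprintf("CNV%04d", seq_len(nrow(cnvs))), cnvs,
                     stringsAsFactors = FALSE)
  list(cnvs = cnvs, truth = truth)
}

#' Simulate the risk-gene lists
#'
#' Two lists are produced: a curated-style primary risk list (module-1 core
#' plus a few genes outside the module) and a module-derived secondary list,
#' mirroring the use of an evidence-scored database list alongside an
#' independently derived co-expression module list.
#'
#' @param cfg a [sim_config()] object.
#' @return list with `gene_lists` (named list of character vectors) and
#'   `truth`.
#' @export
simulate_gene_lists <- function(cfg) {
  truth <- simulate_ground_truth(cfg)
  list(gene_lists = truth$risk_sets, truth = truth)
}

#' Simulate every pipeline input in one call
#'
#' Convenience wrapper that runs all generators off one shared ground truth.
#'
#' @param cfg a [sim_config()] object.
#' @return list with `counts`, `samples`, `dev_expr`, `dev_meta`,
#'   `tissue_expr`, `tissue_panel`, `annotation`, `cnvs`, `gene_lists`,
#'   `truth`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1, n_genes = 200,
#'                                    module_sizes = c(30L, 20L),
#'                                    n_dev_background = 50L,
#'                                    n_lncRNAs = 20L, n_risk_genes = 10L))
#' dim(sim$counts)
simulate_dataset <- function(cfg) {
  cc <- simulate_case_control_counts(cfg)
  dev <- simulate_developmental_matrix(cfg)
  tis <- simulate_tissue_matrix(cfg)
  cnv <- simulate_cnvs(cfg)
  gl <- simulate_gene_lists(cfg)
  list(
    counts = cc$counts, samples = cc$samples,
    dev_expr = dev$expr, dev_meta = dev$meta,
    tissue_expr = tis$expr, tissue_panel = tis$panel,
    annotation = cc$truth$annotation, cnvs = cnv$cnvs,
    gene_lists = gl$gene_lists, truth = cc$truth
  )
}
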