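#' Count CNV overlaps per gene
#'
#' A gene overlaps a CNV when their intervals share at least one base on
#' the same chromosome (strand ignored); coordinates are 0-based half-open,
#' so abutting intervals do not overlap.  CNVs on chromosomes absent from
#' the annotation are skipped with a warning.
#'
#' @param annotation annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param cnvs CNV data.frame (`cnv_id`, `chrom`, `start`, `end`).
#' @return named integer vector of overlap counts per gene.
#' @export
cnv_overlap_counts <- function(annotation, cnvs) {
  unknown <- !(cnvs$chrom %in% annotation$chrom)
  if (any(unknown)) {
    warning(sum(unknown), " CNV(s) on chromosome(s) absent from the ",
            "annotation were skipped: ",
            paste(unique(cnvs$chrom[unknown]), collapse = ", "))
    cnvs <- cnvs[!unknown, , drop = FALSE]
  }
  genes <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(start = annotation$start + 1L, end = annotation$end)
  )
  if (nrow(cnvs) == 0L) {
    return(setNames(integer(nrow(annotation)), annotation$gene_id))
  }
  cv <- GenomicRanges::GRanges(
    cnvs$chrom,
    IRanges::IRanges(start = cnvs$start + 1L, end = cnvs$end)
  )
  setNames(GenomicRanges::countOverlaps(genes, cv), annotation$gene_id)
}

#' Rank candidate lncRNAs by module tier, then CNV overlaps
#'
#' Candidates are the differentially expressed lncRNAs present in the
#' network.  Modules are tiered: tier 1 = enriched for at least one
#' risk-gene set, tier 2 = enriched for the DE-lncRNA set only, tier 3 =
#' everything else (including unassigned).  Within a tier, modules are
#' ordered by their best enrichment adjusted p-value; within a module,
#' candidates are ranked by descending CNV overlap count, with remaining
#' ties broken by descending `|log2fc|` and then gene id.  Candidates
#' missing from an evidence table get NA in that column and sort last
#' within their group.
#'
#' @param de_lncrnas character vector of DE lncRNA ids (the candidates).
#' @param partition `module_partition` or named gene -> label vector over
#'   network genes.
#' @param enrichment an [enrichment_table()] over the same modules.
#' @param cnv_counts named overlap counts from [cnv_overlap_counts()].
#' @param specificity scores data.frame from [specificity_scores()]
#'   (`$scores`), or NULL.
#' @param de DE table from [nb_wald_test()], or NULL.
#' @param top_corr data.frame `gene_id`, `top_gene`, `correlation` (e.g.
#'   built with [top_correlated_gene()]), or NULL.
#' @param risk_set_names which `gene_set` values in `enrichment` are
#'   risk-gene sets.
#' @param lnc_set_name which `gene_set` value is the DE-lncRNA set.
#' @param risk_scores optional named numeric vector of risk-evidence scores
#'   used to annotate the top correlated gene.
#' @return data.frame of `priority_record` rows sorted by `final_rank`.
#' @export
rank_candidates <- function(de_lncrnas, partition, enrichment, cnv_counts,
                            specificity = NULL, de = NULL, top_corr = NULL,
                            risk_set_names, lnc_set_name = NULL,
                            risk_scores = NULL) {
  labels <- if (inherits(partition, "module_partition")) {
    partition$modules
  } else {
    partition
  }
  cand <- intersect(de_lncrnas, names(labels))
  if (!length(cand)) stop("no candidate lncRNA is present in the network")

  risk_enr <- enrichment[enrichment$gene_set %in% risk_set_names &
                           enrichment$enriched, , drop = FALSE]
  lnc_enr <- if (!is.null(lnc_set_name)) {
    enrichment[enrichment$gene_set %in% lnc_set_name & enrichment$enriched, ,
               drop = FALSE]
  } else {
    enrichment[0, , drop = FALSE]
  }
  tier_of <- function(mod) {
    if (mod %in% risk_enr$module) "risk_enriched"
    else if (mod %in% lnc_enr$module) "lnc_enriched"
    else "other"
  }
  best_adjp <- function(mod) {
    r <- enrichment[enrichment$module == mod, "adj_p"]
    if (length(r)) min(r) else Inf
  }

  rec <- data.frame(lncrna_id = sort(cand), stringsAsFactors = FALSE)
  rec$module <- unname(labels[rec$lncrna_id])
  rec$module_tier <- vapply(rec$module, tier_of, character(1))
  rec$cnv_overlaps <- unname(cnv_counts[rec$lncrna_id])
  if (any(is.na(rec$cnv_overlaps))) {
    warning("candidate(s) missing from the CNV overlap table: ",
            paste(rec$lncrna_id[is.na(rec$cnv_overlaps)], collapse = ", "))
  }
  rec$log2fc_asd <- if (!is.null(de)) {
    de$log2fc[match(rec$lncrna_id, de$gene_id)]
  } else {
    NA_real_
  }
  rec$fractional_brain_expression <- if (!is.null(specificity)) {
    specificity$fractional_brain_expression[
      match(rec$lncrna_id, specificity$gene_id)]
  } else {
    NA_real_
  }
  if (!is.null(top_corr)) {
    i <- match(rec$lncrna_id, top_corr$gene_id)
    rec$top_corr_gene <- top_corr$top_gene[i]
    rec$top_corr <- top_corr$correlation[i]
  } else {
    rec$top_corr_gene <- NA_character_
    rec$top_corr <- NA_real_
  }
  rec$top_corr_gene_risk_score <- if (!is.null(risk_scores)) {
    unname(risk_scores[rec$top_corr_gene])
  } else {
    NA_real_
  }

  tier_rank <- c(risk_enriched = 1L, lnc_enriched = 2L, other = 3L)
  mod_order <- vapply(rec$module, best_adjp, numeric(1))
  cnv_key <- ifelse(is.na(rec$cnv_overlaps), -1L, rec$cnv_overlaps)
  lfc_key <- ifelse(is.na(rec$log2fc_asd), -1, abs(rec$log2fc_asd))
  ord <- order(tier_rank[rec$module_tier], mod_order, rec$module,
               -cnv_key, -lfc_key, rec$lncrna_id)
  rec <- rec[ord, , drop = FALSE]
  rec$final_rank <- seq_len(nrow(rec))
  rownames(rec) <- NULL
  class(rec) <- c("priority_record", class(rec))
  rec
}
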