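# R-gene cataloguing: select NBS-domain genes and label domain-order
# subgroups (NBS / CC-NBS / TIR-NBS major classes; subgroups like
# "CC-NBS-LRR" are the hyphen-join of the ordered domain string).

#' Label an R-gene subgroup from its ordered domains
#'
#' The label is the hyphen-join of the domains in protein order with
#' multiplicity preserved: repeated adjacent domains are *not* collapsed,
#' so "NBS-NBS-LRR" and "NBS-LRR" are distinct subgroups.
#'
#' @param domains_ordered nonempty character vector of domain names sorted
#'   by protein position.
#' @return character scalar subgroup label.
#' @export
subgroup_label <- function(domains_ordered) {
  stopifnot(length(domains_ordered) >= 1L)
  paste(domains_ordered, collapse = "-")
}

# Sort one protein's domains by envelope start (ties: longer domain first,
# then name), then drop domains overlapping a kept one by more than half of
# the shorter of the two (keeping the lower-evalue, then earlier-start one).
order_and_dedup_domains <- function(ann) {
  len <- ann$env_end - ann$env_start + 1L
  o <- order(ann$env_start, -len, ann$domain_name)
  ann <- ann[o, , drop = FALSE]
  # prefer low evalue when deduplicating; missing evalues rank last
  ev <- ifelse(is.na(ann$evalue), Inf, ann$evalue)
  pref <- order(ev, ann$env_start)
  keep <- rep(TRUE, nrow(ann))
  for (i in pref) {
    if (!keep[i]) next
    for (j in pref) {
      if (j == i || !keep[j]) next
      ov <- min(ann$env_end[i], ann$env_end[j]) -
        max(ann$env_start[i], ann$env_start[j]) + 1L
      shorter <- min(ann$env_end[i] - ann$env_start[i],
                     ann$env_end[j] - ann$env_start[j]) + 1L
      if (ov > 0.5 * shorter) keep[j] <- FALSE
    }
  }
  ann[keep, , drop = FALSE][order(ann$env_start[keep],
                                  -(ann$env_end - ann$env_start + 1L)[keep],
                                  ann$domain_name[keep]), , drop = FALSE]
}

#' Select NBS R genes and assign subgroup labels
#'
#' Keeps exactly the genes whose protein carries at least one NBS domain.
#' Candidates with domains but no NBS are counted and discarded (message).
#' Annotations are matched to genes by transcript id first, then gene id;
#' annotations referencing unknown ids are skipped with a message.
#'
#' Major class: TIR present anywhere wins (TIR-NBS), else CC (CC-NBS), else
#' plain NBS.
#'
#' @param domain_annotations tibble from [read_domains()] (dialects may be
#'   concatenated with `rbind`).
#' @param gene_models a gene_table from [read_gff3()].
#' @return tibble gene_id, chrom, start, end, transcript_id, subgroup,
#'   major_class, domains_ordered (list column).
#' @export
select_nbs_genes <- function(domain_annotations, gene_models) {
  by_tx <- stats::setNames(gene_models$gene_id, gene_models$transcript_id)
  by_gene <- stats::setNames(gene_models$gene_id, gene_models$gene_id)
  gid <- by_tx[domain_annotations$protein_id]
  miss <- is.na(gid)
  gid[miss] <- by_gene[domain_annotations$protein_id[miss]]
  unknown <- is.na(gid)
  if (any(unknown)) {
    message(sum(unknown), " annotation(s) reference unknown gene ids; skipped")
  }
  ann <- domain_annotations[!unknown, , drop = FALSE]
  ann$gene_id <- gid[!unknown]

  recs <- lapply(split(ann, ann$gene_id), function(a) {
    a <- order_and_dedup_domains(a)
    doms <- a$domain_name
    if (!"NBS" %in% doms) return(NULL)
    major <- if ("TIR" %in% doms) "TIR-NBS" else if ("CC" %in% doms) "CC-NBS" else "NBS"
    g <- gene_models[match(a$gene_id[1L], gene_models$gene_id), ]
    tibble::tibble(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
                   end = g$end, transcript_id = g$transcript_id,
                   subgroup = subgroup_label(doms), major_class = major,
                   domains_ordered = list(doms))
  })
  n_cand <- length(unique(ann$gene_id))
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- tibble::tibble(gene_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          transcript_id = character(0), subgroup = character(0),
                          major_class = character(0),
                          domains_ordered = list())
  }
  message(n_cand, " candidate gene(s) with domains; ", nrow(out),
          " retained with an NBS domain")
  out[order(out$gene_id), , drop = FALSE]
}

#' Summarize an R-gene catalog
#'
#' Counts genes per subgroup and reports the NBS-R / total-gene ratio as a
#' percentage with two decimals (e.g. 535 of 34,584 genes -> "1.55").
#'
#' @param records tibble from [select_nbs_genes()].
#' @param total_gene_count total annotated genes in the genome (> 0).
#' @return list with `subgroups` (tibble subgroup, n, sorted by decreasing
#'   n), `n_r_genes`, `total_genes`, `ratio_pct` (character).
#' @export
catalog_summary <- function(records, total_gene_count) {
  stopifnot(total_gene_count > 0)
  tab <- table(records$subgroup)
  sub <- tibble::tibble(subgroup = names(tab), n = as.integer(tab))
  sub <- sub[order(-sub$n, sub$subgroup), , drop = FALSE]
  stopifnot(sum(sub$n) == nrow(records))
  list(subgroups = sub, n_r_genes = nrow(records),
       total_genes = as.integer(total_gene_count),
       ratio_pct = fmt_pct2(nrow(records), total_gene_count))
}
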