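# Tandem-duplication arrays and R loci.
#
# A tandem array is a maximal run of homologous genes (one single-linkage
# homology cluster) on one chromosome in which consecutive members are
# separated by at most `max_gap` intervening (non-member) genes. An R locus
# is either a tandem array of R genes (represented by one member) or an R
# singleton.

#' Single-linkage homology clusters from BLAST hits
#'
#' Connected components of the undirected homology graph restricted to hits
#' with `evalue <= evalue_max`. Genes in `universe` absent from any kept hit
#' become singleton clusters.
#'
#' @param hits tibble from [read_blast_tab()].
#' @param universe optional character vector of all gene ids to cluster.
#' @param evalue_max e-value cutoff (default 1e-2, the tandem-detection
#'   homology threshold).
#' @return named integer vector: gene id -> cluster id.
#' @export
homology_clusters <- function(hits, universe = NULL, evalue_max = 1e-2) {
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  verts <- sort(unique(c(hits$query_id, hits$subject_id, universe)))
  if (length(verts) == 0L) return(stats::setNames(integer(0), character(0)))
  g <- igraph::graph_from_data_frame(
    hits[, c("query_id", "subject_id")], directed = FALSE,
    vertices = data.frame(name = verts))
  comp <- igraph::components(g)$membership
  # relabel components deterministically by smallest member id
  first <- vapply(split(names(comp), comp), min, character(1))
  relab <- stats::setNames(rank(first, ties.method = "first"), names(first))
  stats::setNames(as.integer(relab[as.character(comp)]), names(comp))
}

#' Detect tandem-duplication arrays
#'
#' Per chromosome and homology cluster, scans member genes in ordinal order
#' and joins consecutive members separated by at most `max_gap` intervening
#' genes (ordinal gap minus one). Runs of two or more members become arrays;
#' lone members stay singletons. The boundary is inclusive: exactly
#' `max_gap` intervening genes still joins.
#'
#' @param gene_models gene_table with ordinals (scan runs over *these*
#'   genes' ordinals; intervening genes are counted from the full gene set
#'   used to assign ordinals).
#' @param clusters named vector from [homology_clusters()]; genes missing
#'   from it are treated as singleton clusters.
#' @param max_gap maximum intervening genes between consecutive members
#'   (default 5).
#' @return tibble array_id, chrom, member_gene_ids (list), n_members,
#'   representative_id, start, end.
#' @export
detect_tandem_arrays <- function(gene_models, clusters, max_gap = 5L) {
  cl <- clusters[gene_models$gene_id]
  # unclustered genes get unique negative ids (never form arrays)
  miss <- is.na(cl)
  cl[miss] <- -seq_len(sum(miss))
  clen <- cds_length(gene_models)
  rows <- list()
  for (key in unique(paste(gene_models$chrom, cl, sep = "\r"))) {
    idx <- which(paste(gene_models$chrom, cl, sep = "\r") == key)
    if (length(idx) < 2L) next
    sub <- gene_models[idx, , drop = FALSE]
    sub <- sub[order(sub$ordinal), , drop = FALSE]
    gap <- diff(sub$ordinal) - 1L
    run <- cumsum(c(0L, as.integer(gap > max_gap)))
    for (r in split(seq_len(nrow(sub)), run)) {
      if (length(r) < 2L) next
      mem <- sub[r, , drop = FALSE]
      rep_id <- mem$gene_id[order(-clen[mem$gene_id], mem$start)][1L]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = mem$chrom[1L], member_gene_ids = list(mem$gene_id),
        n_members = nrow(mem), representative_id = rep_id,
        start = min(mem$start), end = max(mem$end))
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(array_id = character(0), chrom = character(0),
                          member_gene_ids = list(), n_members = integer(0),
                          representative_id = character(0),
                          start = integer(0), end = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  members <- unlist(out$member_gene_ids)
  stopifnot(!anyDuplicated(members))   # arrays partition their members
  out$array_id <- sprintf("TD_%s_%03d", out$chrom,
                          as.integer(stats::ave(seq_len(nrow(out)), out$chrom,
                                                FUN = seq_along)))
  out[, c("array_id", "chrom", "member_gene_ids", "n_members",
          "representative_id", "start", "end")]
}

#' Reduce R genes to R loci
#'
#' One locus per R-gene tandem array (its representative: the member with
#' the longest CDS, ties by smallest start) plus one locus per R singleton.
#'
#' @param r_records tibble from [select_nbs_genes()].
#' @param arrays tibble from [detect_tandem_arrays()] computed on the R
#'   genes (members must all be R genes).
#' @return tibble locus_id, kind ("TD" or "singleton"), chrom,
#'   gene_ids (list), representative_id.
#' @export
to_r_loci <- function(r_records, arrays) {
  td_members <- unlist(arrays$member_gene_ids)
  stopifnot(all(td_members %in% r_records$gene_id))
  singles <- r_records[!(r_records$gene_id %in% td_members), , drop = FALSE]
  td <- tibble::tibble(locus_id = arrays$array_id, kind = "TD",
                       chrom = arrays$chrom,
                       gene_ids = arrays$member_gene_ids,
                       representative_id = arrays$representative_id)
  sg <- tibble::tibble(locus_id = singles$gene_id, kind = "singleton",
                       chrom = singles$chrom,
                       gene_ids = lapply(singles$gene_id, identity),
                       representative_id = singles$gene_id)
  out <- rbind(td, sg)
  out[order(out$locus_id), , drop = FALSE]
}

#' Count R loci the way genome summary tables do
#'
#' @param loci tibble from [to_r_loci()].
#' @param n_r_genes total number of NBS R genes in the genome.
#' @return list: n_td_arrays, n_td_genes, td_over_nbs (character, 2
#'   decimals, e.g. "0.57"), n_singletons, n_loci.
#' @export
r_locus_counts <- function(loci, n_r_genes) {
  td <- loci[loci$kind == "TD", , drop = FALSE]
  n_td_genes <- sum(lengths(td$gene_ids))
  n_single <- sum(loci$kind == "singleton")
  stopifnot(n_td_genes + n_single == n_r_genes)  # Table-2 identity
  list(n_td_arrays = nrow(td), n_td_genes = n_td_genes,
       td_over_nbs = fmt_ratio2(n_td_genes, n_r_genes),
       n_singletons = n_single, n_loci = nrow(loci))
}

#' Collapse tandem arrays to their representatives
#'
#' Replaces every array's members by its single representative gene and
#' recomputes ordinals, so downstream synteny sees one locus per array.
#'
#' @param gene_models gene_table.
#' @param arrays tibble from [detect_tandem_arrays()].
#' @return gene_table without non-representative array members.
#' @export
collapse_to_loci <- function(gene_models, arrays) {
  drop <- setdiff(unlist(arrays$member_gene_ids), arrays$representative_id)
  recompute_ordinals(gene_models[!(gene_models$gene_id %in% drop), ,
                                 drop = FALSE])
}
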