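# Population genetics on VCF variants: MAF filtering, variant effect
# classification, functional burden, per-gene pi and Tajima's D.
#
# pi here is per-variant-locus: at each biallelic site the unbiased
# heterozygosity h = n/(n-1) (1 - p^2 - q^2) over the n called alleles, and
# a gene's pi is the mean of h over its variant loci (dimensionless, 0-1).
# Tajima's D uses the 1989 constants with Pi = sum of per-site h (the mean
# pairwise difference count) and S the number of segregating sites.

# Per-site allele counts from a variant_set's GT matrix.
site_allele_stats <- function(vs) {
  alleles <- function(gt_row) {
    a <- unlist(strsplit(gt_row, "[/|]"))
    a[a != "."]
  }
  n_called <- integer(nrow(vs$sites))
  n_alt <- integer(nrow(vs$sites))
  for (i in seq_len(nrow(vs$sites))) {
    a <- alleles(vs$gt[i, ])
    n_called[i] <- length(a)
    n_alt[i] <- sum(a == "1")
  }
  maf <- ifelse(n_called > 0, pmin(n_alt, n_called - n_alt) / n_called, NA)
  tibble::tibble(n_called = n_called, n_alt = n_alt, maf = maf)
}

#' Filter variant sites by allele count and minor allele frequency
#'
#' Keeps biallelic sites whose minor-allele frequency over called alleles
#' is at least `maf_min` (a site exactly at the threshold is kept) and at
#' most `maf_max`. Sites with zero called alleles are dropped (message).
#'
#' @param vs a `variant_set` from [read_vcf()].
#' @param maf_min minimum MAF (default 0.05).
#' @param maf_max maximum MAF (default 0.5, i.e. no upper filter).
#' @return the filtered `variant_set`.
#' @export
filter_sites <- function(vs, maf_min = 0.05, maf_max = 0.5) {
  st <- site_allele_stats(vs)
  no_call <- st$n_called == 0L
  if (any(no_call)) message(sum(no_call), " site(s) with no called alleles dropped")
  biallelic <- !grepl(",", vs$sites$alt, fixed = TRUE) &
    vs$sites$alt != vs$sites$ref
  keep <- !no_call & biallelic & st$maf >= maf_min & st$maf <= maf_max
  keep[is.na(keep)] <- FALSE
  new_variant_set(vs$sites[keep, , drop = FALSE],
                  vs$gt[keep, , drop = FALSE])
}

# Per-gene structural lookup used by classify_variants.
gene_structures <- function(gene_models, cds_seqs) {
  lapply(seq_len(nrow(gene_models)), function(i) {
    g <- gene_models[i, ]
    ex <- g$exons[[1L]]
    cd <- g$cds[[1L]]
    introns <- NULL
    if (!is.null(ex) && nrow(ex) >= 2L) {
      introns <- cbind(start = ex[-nrow(ex), 2L] + 1L,
                       end = ex[-1L, 1L] - 1L)
      introns <- introns[introns[, 1L] <= introns[, 2L], , drop = FALSE]
    }
    nm <- names(cds_seqs)
    cds_seq <- if (g$transcript_id %in% nm) cds_seqs[[g$transcript_id]]
      else if (g$gene_id %in% nm) cds_seqs[[g$gene_id]] else NULL
    list(gene_id = g$gene_id, chrom = g$chrom, start = g$start, end = g$end,
         strand = g$strand, exons = ex, cds = cd, introns = introns,
         cds_seq = cds_seq)
  })
}

# Map a genomic position inside a CDS segment to its 1-based index in the
# CDS sequence (transcript orientation).
cds_index_of <- function(str, pos) {
  cd <- str$cds
  seg_len <- cd[, 2L] - cd[, 1L] + 1L
  k <- which(pos >= cd[, 1L] & pos <= cd[, 2L])
  if (length(k) == 0L) return(NA_integer_)
  plus_idx <- sum(seg_len[seq_len(k - 1L)]) + (pos - cd[k, 1L] + 1L)
  if (str$strand == "+") plus_idx else sum(seg_len) - plus_idx + 1L
}

classify_one <- function(pos, ref, alt, is_snp, indel_length, str,
                         gc = codon_table()) {
  # region: CDS > UTR (exon outside CDS) > intron, within the gene span
  if (in_intervals(pos, str$cds)) {
    region <- "CDS"
  } else if (in_intervals(pos, str$exons)) {
    region <- "UTR"
  } else {
    region <- "intronic"
  }
  effect <- "non_coding"; functional <- FALSE
  if (region == "CDS") {
    if (!is_snp) {
      effect <- if (abs(indel_length) %% 3L != 0L) "frameshift_indel" else "inframe_indel"
      functional <- TRUE   # any coding InDel alters the protein product
    } else {
      idx <- cds_index_of(str, pos)
      seq <- str$cds_seq
      if (is.na(idx) || is.null(seq) || idx > nchar(seq)) {
        effect <- "non_synonymous"; functional <- TRUE
      } else {
        codon_i <- (idx - 1L) %/% 3L
        within <- idx - 3L * codon_i
        codon <- substr(seq, 3L * codon_i + 1L, 3L * codon_i + 3L)
        sub_base <- if (str$strand == "+") alt else unname(comp_base(alt))
        mut <- codon
        substr(mut, within, within) <- sub_base
        same <- !is.na(gc[codon]) && !is.na(gc[mut]) && gc[codon] == gc[mut]
        effect <- if (same) "synonymous" else "non_synonymous"
        functional <- !same
      }
    }
  } else if (region == "intronic" && !is.null(str$introns) &&
             nrow(str$introns) > 0L) {
    near <- (pos - str$introns[, 1L] <= 1L & pos >= str$introns[, 1L]) |
      (str$introns[, 2L] - pos <= 1L & pos <= str$introns[, 2L])
    if (any(near)) {
      effect <- "splice"; functional <- TRUE
    }
  }
  list(region = region, effect = effect, functional = functional)
}

#' Classify variants by genic context and functional effect
#'
#' Region is assigned by interval lookup within the containing gene
#' (CDS > UTR > intron; outside any gene span: intergenic). Coding SNPs are
#' translated against the reference codon (from the primary transcript's
#' CDS sequence) for synonymous/non-synonymous; intronic positions within
#' 2 bp of an intron boundary are splice variants; coding InDels are
#' frameshift when their length is not a multiple of 3, inframe otherwise.
#' Functional = non-synonymous SNP, splice variant, or any coding InDel.
#' Multi-base variants are classified by their leftmost base; a variant
#' overlapping several genes uses the first gene by position order.
#'
#' @param vs a `variant_set`.
#' @param gene_models gene_table from [read_gff3()].
#' @param cds_seqs named character vector/list of CDS strings keyed by
#'   transcript id (or gene id).
#' @return tibble chrom, pos, gene_id (NA when intergenic), region, effect,
#'   functional.
#' @export
classify_variants <- function(vs, gene_models, cds_seqs) {
  strs <- gene_structures(gene_models, cds_seqs)
  by_chrom <- split(seq_along(strs), gene_models$chrom)
  sites <- vs$sites
  n <- nrow(sites)
  gene_id <- rep(NA_character_, n)
  region <- rep("intergenic", n)
  effect <- rep("intergenic", n)
  functional <- rep(FALSE, n)
  for (i in seq_len(n)) {
    cand <- by_chrom[[sites$chrom[i]]]
    if (is.null(cand)) next
    pos <- sites$pos[i]
    hit <- NULL
    for (k in cand) {
      if (pos >= strs[[k]]$start && pos <= strs[[k]]$end) { hit <- strs[[k]]; break }
    }
    if (is.null(hit)) next
    cls <- classify_one(pos, sites$ref[i], sites$alt[i], sites$is_snp[i],
                        sites$indel_length[i], hit)
    gene_id[i] <- hit$gene_id
    region[i] <- cls$region
    effect[i] <- cls$effect
    functional[i] <- cls$functional
  }
  tibble::tibble(chrom = sites$chrom, pos = sites$pos, gene_id = gene_id,
                 region = region, effect = effect, functional = functional)
}

#' Functional-variant burden per gene and per gene set
#'
#' @param effects tibble from [classify_variants()], or any tibble with
#'   gene_id and functional columns.
#' @param gene_sets named list of gene-id vectors (e.g. all, R, R_TD,
#'   R_singleton); genes without variants count zero.
#' @return list with `per_gene` (tibble gene_id, n_functional over the
#'   union of all sets) and `summary` (tibble set, n_genes, n_functional,
#'   per_gene with two decimals as character).
#' @export
functional_burden <- function(effects, gene_sets) {
  func <- effects[effects$functional & !is.na(effects$gene_id), ,
                  drop = FALSE]
  counts <- table(func$gene_id)
  all_genes <- unique(unlist(gene_sets))
  per_gene <- tibble::tibble(
    gene_id = all_genes,
    n_functional = as.integer(ifelse(is.na(counts[all_genes]), 0L,
                                     counts[all_genes])))
  rows <- lapply(names(gene_sets), function(s) {
    ids <- gene_sets[[s]]
    tot <- sum(per_gene$n_functional[per_gene$gene_id %in% ids])
    tibble::tibble(set = s, n_genes = length(ids), n_functional = tot,
                   per_gene = fmt_ratio2(tot, length(ids)))
  })
  list(per_gene = per_gene, summary = do.call(rbind, rows))
}

#' Tajima (1989) constants for sample size n
#' @param n number of sequences (called alleles), >= 2.
#' @return list a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Per-site unbiased heterozygosity table for one gene's sites; sites with
# fewer than 4 called alleles are dropped.
site_h <- function(st) {
  keep <- st$n_called >= 4L & st$n_alt > 0L & st$n_alt < st$n_called
  st <- st[keep, , drop = FALSE]
  p <- st$n_alt / st$n_called
  q <- 1 - p
  st$h <- st$n_called / (st$n_called - 1) * (1 - p^2 - q^2)
  st
}

#' Per-variant-locus nucleotide diversity of one gene
#'
#' Mean over the gene's segregating sites of the unbiased per-site
#' heterozygosity n/(n-1) (1 - p^2 - q^2) with n the called alleles at the
#' site. `NA` when the gene has no segregating site.
#'
#' @param st tibble with n_called and n_alt per variant site in the gene
#'   (from the internal allele-count pass; see [gene_diversity()]).
#' @return numeric scalar in 0..1, or NA.
#' @export
gene_pi <- function(st) {
  st <- site_h(st)
  if (nrow(st) == 0L) return(NA_real_)
  mean(st$h)
}

#' Tajima's D of one gene
#'
#' D = (Pi - S/a1) / sqrt(e1 S + e2 S (S-1)) with Pi the mean pairwise
#' difference count (sum of per-site unbiased heterozygosities) and
#' constants from [tajima_constants()] at the modal per-site sample size
#' (a message is emitted when sites differ in n). `NA` when S = 0.
#'
#' @param st tibble with n_called and n_alt per variant site.
#' @return numeric scalar, or NA.
#' @export
gene_tajimas_d <- function(st) {
  st <- site_h(st)
  S <- nrow(st)
  if (S == 0L) return(NA_real_)
  n <- modal_value(st$n_called)
  if (length(unique(st$n_called)) > 1L) {
    message("sites differ in called-allele count; using modal n = ", n)
  }
  k <- tajima_constants(n)
  Pi <- sum(st$h)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (Pi - S / k$a1) / denom
}

#' Per-gene diversity and selection statistics
#'
#' Assigns each variant site to the gene whose span contains it (first by
#' position order) and computes segregating sites S, per-variant-locus pi,
#' Tajima's D, and the functional-variant count per gene.
#'
#' @param vs a filtered `variant_set`.
#' @param gene_models gene_table.
#' @param effects optional tibble from [classify_variants()] to fill
#'   functional_count (0 otherwise).
#' @return tibble gene_id, n_accessions, S, pi, tajimas_d,
#'   functional_count.
#' @export
gene_diversity <- function(vs, gene_models, effects = NULL) {
  st <- site_allele_stats(vs)
  st$chrom <- vs$sites$chrom
  st$pos <- vs$sites$pos
  func_counts <- if (!is.null(effects)) {
    tab <- table(effects$gene_id[effects$functional & !is.na(effects$gene_id)])
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  rows <- lapply(seq_len(nrow(gene_models)), function(i) {
    g <- gene_models[i, ]
    sub <- st[st$chrom == g$chrom & st$pos >= g$start & st$pos <= g$end, ,
              drop = FALSE]
    hsub <- site_h(sub)
    fc <- func_counts[g$gene_id]
    tibble::tibble(gene_id = g$gene_id,
                   n_accessions = ncol(vs$gt),
                   S = nrow(hsub),
                   pi = gene_pi(sub),
                   tajimas_d = suppressMessages(gene_tajimas_d(sub)),
                   functional_count = if (is.na(fc)) 0L else as.integer(fc))
  })
  do.call(rbind, rows)
}
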