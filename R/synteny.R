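# Flanking-gene synteny: pairwise syntenic orthologs, multi-genome
# families, R-locus synteny summaries, and synteny depth (ploidy check).
#
# A homologous pair (gA, gB) is syntenic when the genes flanking gA and gB
# (up to `window` genes per side on the same chromosome) support it: a flank
# position counts when its gene has a reciprocal best BLAST hit inside the
# partner's flank. The pair kept for gA is the partner with the highest
# flank ratio (supported / min available flank), at or above
# `min_flank_ratio`, and the selection must be mutual.

#' Synteny parameters
#'
#' @param evalue_max homology cutoff for candidate pairs (default 1e-20).
#' @param window flank size, genes per side (default 10).
#' @param min_flank_ratio minimum supported-flank ratio (default 0.3).
#' @param require_best_hit_flanks count flank support only through
#'   reciprocal best hits (default TRUE; FALSE counts any hit).
#' @return list of class `synteny_params`.
#' @export
synteny_params <- function(evalue_max = 1e-20, window = 10L,
                           min_flank_ratio = 0.3,
                           require_best_hit_flanks = TRUE) {
  stopifnot(window >= 1L, min_flank_ratio >= 0, min_flank_ratio <= 1)
  structure(list(evalue_max = evalue_max, window = as.integer(window),
                 min_flank_ratio = min_flank_ratio,
                 require_best_hit_flanks = require_best_hit_flanks),
            class = "synteny_params")
}

# Best hit per query by bitscore (tie: lower evalue, then lexicographic
# subject), as a named character vector query -> subject.
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  o <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  keep <- !duplicated(h$query_id)
  stats::setNames(h$subject_id[keep], h$query_id[keep])
}

# Symmetrize a hit table so both directions are present.
symmetrize_hits <- function(hits) {
  rev <- hits
  rev$query_id <- hits$subject_id
  rev$subject_id <- hits$query_id
  rev$q_cov_pct <- NA_real_
  all <- rbind(hits, rev)
  all[!duplicated(paste(all$query_id, all$subject_id, all$evalue,
                        all$bitscore)), , drop = FALSE]
}

#' Pairwise syntenic orthologs between two genomes
#'
#' @param models_a,models_b gene_tables of the two genomes (collapse tandem
#'   arrays to representatives first with [collapse_to_loci()] so an array
#'   counts as one locus).
#' @param hits_ab BLAST hits between the genomes (either or both
#'   directions; the table is symmetrized internally).
#' @param params a [synteny_params()] object.
#' @param genome_a,genome_b genome labels for the output.
#' @param keep_all keep every partner with flank ratio at or above the
#'   threshold instead of the mutual best only (used by
#'   [synteny_depth()]).
#' @return tibble genome_a, genome_b, gene_a, gene_b, flank_ratio,
#'   n_flank_support, bitscore.
#' @export
pairwise_synteny <- function(models_a, models_b, hits_ab,
                             params = synteny_params(),
                             genome_a = "A", genome_b = "B",
                             keep_all = FALSE) {
  hits <- hits_ab[hits_ab$evalue <= params$evalue_max, , drop = FALSE]
  ids_a <- models_a$gene_id; ids_b <- models_b$gene_id
  hits <- symmetrize_hits(hits)
  ab <- hits[hits$query_id %in% ids_a & hits$subject_id %in% ids_b, ,
             drop = FALSE]
  ba <- hits[hits$query_id %in% ids_b & hits$subject_id %in% ids_a, ,
             drop = FALSE]
  best_ab <- best_hits(ab)
  best_ba <- best_hits(ba)
  if (params$require_best_hit_flanks) {
    # reciprocal best-hit partner map (NA when not reciprocal)
    rbh_ab <- best_ab[!is.na(best_ba[best_ab]) &
                        best_ba[best_ab] == names(best_ab)]
  } else {
    rbh_ab <- NULL
  }
  has_hit <- function(fa, fb_set) {
    # any-hit flank support (when require_best_hit_flanks = FALSE)
    sub <- ab[ab$query_id == fa, "subject_id", drop = TRUE]
    any(sub %in% fb_set)
  }

  flank_of <- function(models, idx_by_id, gid, window) {
    i <- idx_by_id[[gid]]
    g <- models[i, ]
    same <- which(models$chrom == g$chrom &
                    abs(models$ordinal - g$ordinal) <= window &
                    models$gene_id != gid)
    models$gene_id[same]
  }
  idx_a <- stats::setNames(as.list(seq_len(nrow(models_a))), ids_a)
  idx_b <- stats::setNames(as.list(seq_len(nrow(models_b))), ids_b)

  cand <- ab[order(ab$query_id, ab$subject_id), , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(tibble::tibble(genome_a = character(0), genome_b = character(0),
                          gene_a = character(0), gene_b = character(0),
                          flank_ratio = numeric(0),
                          n_flank_support = integer(0), bitscore = numeric(0)))
  }
  support <- integer(nrow(cand)); ratio <- numeric(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    fa <- flank_of(models_a, idx_a, cand$query_id[k], params$window)
    fb <- flank_of(models_b, idx_b, cand$subject_id[k], params$window)
    if (length(fa) == 0L || length(fb) == 0L) {
      support[k] <- 0L; ratio[k] <- 0; next
    }
    if (params$require_best_hit_flanks) {
      partners <- rbh_ab[fa]
      supp <- sum(!is.na(partners) & partners %in% fb)
    } else {
      supp <- sum(vapply(fa, has_hit, logical(1), fb_set = fb))
    }
    support[k] <- as.integer(supp)
    ratio[k] <- supp / min(length(fa), length(fb))
  }
  cand$n_flank_support <- support
  cand$flank_ratio <- ratio
  cand <- cand[cand$flank_ratio >= params$min_flank_ratio, , drop = FALSE]
  if (!keep_all && nrow(cand) > 0L) {
    pick <- function(df, key) {
      o <- order(df[[key]], -df$flank_ratio, -df$bitscore, df$evalue,
                 df$query_id, df$subject_id)
      df <- df[o, , drop = FALSE]
      df[!duplicated(df[[key]]), , drop = FALSE]
    }
    best_for_a <- pick(cand, "query_id")
    best_for_b <- pick(cand, "subject_id")
    key <- paste(cand$query_id, cand$subject_id)
    cand <- cand[key %in% paste(best_for_a$query_id, best_for_a$subject_id) &
                   key %in% paste(best_for_b$query_id, best_for_b$subject_id), ,
                 drop = FALSE]
  }
  tibble::tibble(genome_a = genome_a, genome_b = genome_b,
                 gene_a = cand$query_id, gene_b = cand$subject_id,
                 flank_ratio = cand$flank_ratio,
                 n_flank_support = cand$n_flank_support,
                 bitscore = cand$bitscore)
}

#' Build multi-genome syntenic families
#'
#' Connected components of the union graph of all pairwise syntenic pairs.
#' Loci listed in `loci_by_genome` but absent from every pair become
#' species-specific families of size one.
#'
#' @param pairs tibble rbind-ing [pairwise_synteny()] outputs over all
#'   genome pairs.
#' @param loci_by_genome named list: genome -> tibble with locus_id and
#'   optionally kind ("TD"/"singleton"), typically [to_r_loci()] output or
#'   any locus table.
#' @return tibble family_id, members (list of tibbles genome, locus_id,
#'   kind), n_genomes, species_specific, contains_td.
#' @export
build_families <- function(pairs, loci_by_genome) {
  node <- function(genome, locus) paste(genome, locus, sep = "\r")
  all_nodes <- unlist(lapply(names(loci_by_genome), function(g) {
    node(g, loci_by_genome[[g]]$locus_id)
  }))
  kind_of <- stats::setNames(
    unlist(lapply(loci_by_genome, function(t) {
      if ("kind" %in% names(t)) t$kind else rep(NA_character_, nrow(t))
    })),
    all_nodes)
  edges <- if (nrow(pairs) > 0L) {
    data.frame(from = node(pairs$genome_a, pairs$gene_a),
               to = node(pairs$genome_b, pairs$gene_b))
  } else data.frame(from = character(0), to = character(0))
  verts <- sort(unique(c(all_nodes, edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = verts))
  comp <- igraph::components(g)$membership
  fams <- split(names(comp), comp)
  fams <- fams[order(vapply(fams, min, character(1)))]
  rows <- lapply(seq_along(fams), function(i) {
    parts <- strsplit(fams[[i]], "\r", fixed = TRUE)
    genome <- vapply(parts, `[[`, character(1), 1L)
    locus <- vapply(parts, `[[`, character(1), 2L)
    kinds <- unname(kind_of[fams[[i]]])
    tibble::tibble(
      family_id = sprintf("FAM%05d", i),
      members = list(tibble::tibble(genome = genome, locus_id = locus,
                                    kind = kinds)),
      n_genomes = length(unique(genome)),
      species_specific = length(unique(genome)) == 1L,
      contains_td = any(kinds == "TD", na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Summarize cross-genome synteny of one genome's R loci
#'
#' For the reference genome: the share of R loci with a syntenic locus in
#' at least one other genome, overall and split by kind (TD array vs
#' singleton), plus the TD composition of shared vs species-specific
#' families (the 2x2 handed to the chi-square test).
#'
#' @param r_loci tibble from [to_r_loci()] for the reference genome.
#' @param families tibble from [build_families()].
#' @param genome reference genome label as used in the family members.
#' @return list: per-kind counts and percentages (2-decimal character), and
#'   `td_shared_specific` (2x2 integer matrix: rows shared/specific, cols
#'   with-TD/without-TD over all families).
#' @export
r_locus_synteny_summary <- function(r_loci, families, genome) {
  mem <- do.call(rbind, families$members)
  fam_id <- rep(families$family_id, vapply(families$members, nrow, integer(1)))
  shared_fams <- families$family_id[!families$species_specific]
  in_shared <- stats::setNames(fam_id %in% shared_fams, NULL)
  ref <- mem$genome == genome
  has_syn <- stats::setNames(in_shared[ref], mem$locus_id[ref])

  syn_of <- function(kind) {
    ids <- r_loci$locus_id[r_loci$kind == kind]
    n <- length(ids); s <- sum(has_syn[ids], na.rm = TRUE)
    list(n = n, n_syntenic = s, pct = fmt_pct2(s, n))
  }
  all_ids <- r_loci$locus_id
  n_all <- length(all_ids); s_all <- sum(has_syn[all_ids], na.rm = TRUE)

  shared <- families[!families$species_specific, , drop = FALSE]
  specific <- families[families$species_specific, , drop = FALSE]
  tab <- matrix(c(sum(shared$contains_td), sum(!shared$contains_td),
                  sum(specific$contains_td), sum(!specific$contains_td)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("shared", "specific"),
                                c("with_td", "without_td")))
  list(n_loci = n_all, n_syntenic = s_all, pct = fmt_pct2(s_all, n_all),
       td = syn_of("TD"), singleton = syn_of("singleton"),
       pct_shared_with_td = fmt_pct2(sum(shared$contains_td), nrow(shared)),
       pct_specific_with_td = fmt_pct2(sum(specific$contains_td),
                                       nrow(specific)),
       td_shared_specific = tab)
}

#' Per-chromosome synteny depth of a reference genome
#'
#' For each reference gene appearing in `pairs` (run [pairwise_synteny()]
#' with `keep_all = TRUE`), counts the distinct partner chromosomes
#' contributing a syntenic partner, then reports the modal depth per
#' reference chromosome: 1 looks diploid (1:1), 2 tetraploid-like.
#'
#' @param reference_models gene_table of the reference genome.
#' @param pairs tibble from [pairwise_synteny()] with the reference as
#'   genome A and all partners kept.
#' @param partner_models gene_table of the query genome (to resolve partner
#'   chromosomes).
#' @return tibble chrom, n_genes_with_partner, modal_depth, mean_depth.
#' @export
synteny_depth <- function(reference_models, pairs, partner_models) {
  pchrom <- stats::setNames(partner_models$chrom, partner_models$gene_id)
  depth <- vapply(split(pchrom[pairs$gene_b], pairs$gene_a),
                  function(ch) length(unique(ch)), integer(1))
  gchrom <- stats::setNames(reference_models$chrom, reference_models$gene_id)
  d <- tibble::tibble(chrom = unname(gchrom[names(depth)]), depth = depth)
  out <- lapply(split(d, d$chrom), function(s) {
    tibble::tibble(chrom = s$chrom[1L], n_genes_with_partner = nrow(s),
                   modal_depth = modal_value(s$depth),
                   mean_depth = mean(s$depth))
  })
  do.call(rbind, out)
}
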