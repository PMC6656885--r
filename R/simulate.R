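# Synthetic multi-genome and population data with planted ground truth.
#
# Genomes are permuted copies of one ancestral gene order evolved along a
# species tree. Tandem arrays are planted as adjacent homologous copies
# separated by up to `max_intervening` spacer genes. Coding sequences
# evolve codon-wise under an omega-thinned Jukes-Cantor scheme: proposed
# single-base changes are accepted with probability 1 when synonymous,
# omega when nonsynonymous, never when creating a stop. BLAST tables are
# emitted from true homology with e-values that are a deterministic
# monotone function of realized sequence identity, so the 1e-2 / 1e-20
# thresholds behave reproducibly. The population simulator is
# site-independent (no linkage): segregating sites arise from a Watterson
# process with E[S] = a1 * theta * L and frequencies from a (tiltable)
# neutral spectrum.

#' Simulation configuration
#'
#' Defaults define the toy study conditions the test-suite exercises: four
#' diploid-like genomes on a balanced tree, tandem arrays of 2-4 R-gene
#' copies, an omega contrast of 1.0 (TD R genes) vs 0.2 (R singletons) vs
#' 0.5 (background), and a 20-accession population at theta = 0.01/bp.
#'
#' @param seed integer RNG seed; every random draw flows from it.
#' @param species_tree Newick string with branch lengths in
#'   substitutions/site.
#' @param n_genes_per_genome ancestral genes per genome.
#' @param n_tandem_arrays planted tandem arrays.
#' @param array_size_range c(min, max) members per array.
#' @param max_intervening max spacer genes between adjacent array members.
#' @param frac_r_genes fraction of genes that are R genes (array members
#'   all are; singleton R genes top the fraction up).
#' @param dnds_by_class named omega per class (TD_R, singleton_R,
#'   background).
#' @param pop_n_accessions accessions in the simulated population (two
#'   haplotypes each).
#' @param theta_per_site Watterson theta per bp, in (0, 0.1].
#' @param gene_length_bp CDS length per gene (multiple of 3).
#' @param n_chromosomes chromosomes per genome.
#' @param insertion_frac fraction of species-specific inserted genes.
#' @param pop_theta_boost named per-class multiplier on theta (mutational
#'   density contrast; all 1 = neutral).
#' @param pop_spectrum_alpha named per-class tilt of the derived-allele
#'   spectrum P(i) proportional to 1/i^alpha (1 = neutral; < 1 shifts
#'   toward intermediate frequencies, > 1 toward rare alleles).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    species_tree = "((A:0.04,B:0.04):0.02,(C:0.04,D:0.04):0.02);",
    n_genes_per_genome = 60L,
    n_tandem_arrays = 3L,
    array_size_range = c(2L, 4L),
    max_intervening = 2L,
    frac_r_genes = 0.2,
    dnds_by_class = c(TD_R = 1.0, singleton_R = 0.2, background = 0.5),
    pop_n_accessions = 20L,
    theta_per_site = 0.01,
    gene_length_bp = 300L,
    n_chromosomes = 2L,
    insertion_frac = 0.05,
    pop_theta_boost = c(TD_R = 1, singleton_R = 1, background = 1),
    pop_spectrum_alpha = c(TD_R = 1, singleton_R = 1, background = 1)) {
  stopifnot(n_genes_per_genome > 0L, n_tandem_arrays >= 0L,
            all(array_size_range >= 2L), max_intervening >= 0L,
            frac_r_genes > 0, frac_r_genes < 1,
            all(dnds_by_class > 0),
            pop_n_accessions > 1L,
            theta_per_site >= 0, theta_per_site <= 0.1,
            gene_length_bp %% 3L == 0L, gene_length_bp > 0L)
  structure(as.list(environment()), class = "simulation_config")
}

# sample() treats a length-1 numeric vector as 1:x; always index instead
sample_vec <- function(x, n, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}

random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# omega-thinned mutation of a CDS: expected proposals = bl per site.
mutate_cds <- function(cds, bl, omega, gc = codon_table()) {
  n <- nchar(cds)
  n_prop <- stats::rpois(1L, bl * n)
  if (n_prop == 0L) return(cds)
  chars <- strsplit(cds, "")[[1L]]
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_prop)) {
    p <- sample.int(n, 1L)
    new <- sample(setdiff(bases, chars[p]), 1L)
    ci <- (p - 1L) %/% 3L
    idx <- ci * 3L + 1:3
    old_codon <- paste(chars[idx], collapse = "")
    mut <- chars; mut[p] <- new
    new_codon <- paste(mut[idx], collapse = "")
    if (gc[new_codon] == "*") next
    if (gc[new_codon] != gc[old_codon] && stats::runif(1L) > omega) next
    chars <- mut
  }
  paste(chars, collapse = "")
}

# deterministic monotone map: identity fraction -> e-value
identity_to_evalue <- function(id_frac) {
  10^(-pmax(5, pmin(300, 200 * id_frac - 20)))
}

seq_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
  mean(ca == cb)
}

# Lay out a chromosome's gene order as gene models (two exons, one intron,
# short UTRs); returns a gene_table chunk without ordinals.
layout_chromosome <- function(chrom, gene_ids, strands, cds_len) {
  utr <- 30L; intron <- 60L; gap <- 200L
  cds1 <- (cds_len %/% 2L)
  cds2 <- cds_len - cds1
  rows <- list()
  cursor <- 1L
  for (i in seq_along(gene_ids)) {
    s <- cursor
    e1_start <- s
    c1_start <- s + utr
    c1_end <- c1_start + cds1 - 1L
    e1_end <- c1_end
    i_start <- e1_end + 1L
    i_end <- i_start + intron - 1L
    c2_start <- i_end + 1L
    c2_end <- c2_start + cds2 - 1L
    e2_end <- c2_end + utr
    strand <- strands[i]
    if (strand == "+") {
      ph <- c(0L, (3L - cds1 %% 3L) %% 3L)
    } else {
      ph <- c((3L - cds2 %% 3L) %% 3L, 0L)
    }
    rows[[i]] <- tibble::tibble(
      gene_id = gene_ids[i], chrom = chrom, start = s, end = e2_end,
      strand = strand, transcript_id = paste0(gene_ids[i], ".1"),
      exons = list(cbind(start = c(e1_start, c2_start),
                         end = c(e1_end, e2_end))),
      cds = list(cbind(start = c(c1_start, c2_start),
                       end = c(c1_end, c2_end), phase = ph)))
    cursor <- e2_end + gap + 1L
  }
  do.call(rbind, rows)
}

#' Simulate related genomes with planted ground truth
#'
#' See the file header for the generative model. When `out_dir` is given,
#' per-species GFF3, CDS/protein FASTA, domain files (pfam_scan dialect
#' plus an NCOILS TSV) and within/cross-genome BLAST tables are written in
#' exactly the dialects the readers consume, plus a `truth.json`.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory.
#' @return list with `species`, `models` (gene_table per species), `cds`
#'   (named vector per species, keyed by gene id), `proteins`, `domains`
#'   (annotation tibble per species), `hits_within` (per species),
#'   `hits_cross` (per species pair "A|B"), `truth` (planted_arrays,
#'   syntenic_map, true_tree, classes, true_omega, r_genes, subgroups),
#'   and `files` when `out_dir` was given.
#' @export
simulate_genomes <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  tree <- ape::read.tree(text = config$species_tree)
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  species <- tree$tip.label
  n_codons <- config$gene_length_bp %/% 3L

  ## --- ancestral layout ------------------------------------------------
  sizes <- sample_vec(seq(config$array_size_range[1L],
                          config$array_size_range[2L]),
                      config$n_tandem_arrays, replace = TRUE)
  n_td <- sum(sizes)
  # spacers drawn per inter-member gap
  spacer_counts <- lapply(sizes, function(sz) {
    sample_vec(0:config$max_intervening, sz - 1L, replace = TRUE)
  })
  n_spacers <- sum(unlist(spacer_counts))
  n_single <- config$n_genes_per_genome - n_td
  if (n_single < n_spacers + config$n_tandem_arrays) {
    stop("array sizes exceed chromosome capacity: not enough singleton genes",
         " to host spacers")
  }
  single_ids <- sprintf("s%03d", seq_len(n_single))
  # ancestral locus ids; array members share a family
  array_members <- lapply(seq_len(config$n_tandem_arrays), function(a) {
    sprintf("f%02dm%d", a, seq_len(sizes[a]))
  })
  family_of <- c(stats::setNames(single_ids, single_ids),
                 stats::setNames(rep(sprintf("f%02d", seq_along(sizes)), sizes),
                                 unlist(array_members)))
  # compose blocks: members interleaved with spacers pulled off the queue
  spacer_queue <- single_ids
  used_spacers <- character(0)
  blocks <- lapply(seq_along(array_members), function(a) {
    mem <- array_members[[a]]
    out <- mem[1L]
    for (k in seq_len(length(mem) - 1L)) {
      ns <- spacer_counts[[a]][k]
      if (ns > 0L) {
        sp <- spacer_queue[seq_len(ns)]
        spacer_queue <<- spacer_queue[-seq_len(ns)]
        used_spacers <<- c(used_spacers, sp)
        out <- c(out, sp)
      }
      out <- c(out, mem[k + 1L])
    }
    out
  })
  free_singles <- spacer_queue
  # scatter blocks among the free singles, then cut into chromosomes
  units <- c(lapply(free_singles, identity), blocks)
  units <- units[sample.int(length(units))]
  chrom_of_unit <- sort(rep_len(seq_len(config$n_chromosomes), length(units)))
  anc_order <- split(units, chrom_of_unit)
  anc_order <- lapply(anc_order, unlist)
  names(anc_order) <- sprintf("chr%d", seq_along(anc_order))

  ## --- classes and R status -------------------------------------------
  classes <- stats::setNames(rep("background", config$n_genes_per_genome),
                             c(single_ids, unlist(array_members)))
  classes[unlist(array_members)] <- "TD_R"
  n_r_target <- round(config$frac_r_genes * config$n_genes_per_genome)
  n_extra_r <- max(0L, n_r_target - n_td)
  eligible <- setdiff(free_singles, used_spacers)
  singleton_r <- sample_vec(eligible, min(n_extra_r, length(eligible)))
  classes[singleton_r] <- "singleton_R"
  r_anc <- names(classes)[classes != "background"]
  # domain architectures for R genes; a decoy set of LRR-only candidates
  archs <- c("CC-NBS-LRR", "NBS-LRR", "NBS", "TIR-NBS", "NBS-NBS-LRR")
  arch_of <- stats::setNames(
    sample(archs, length(r_anc), replace = TRUE,
           prob = c(0.45, 0.3, 0.1, 0.05, 0.1)), r_anc)
  decoys <- sample_vec(setdiff(names(classes), r_anc),
                       max(1L, round(0.1 * config$n_genes_per_genome)))

  ## --- ancestral sequences and evolution along the tree ---------------
  fams <- unique(family_of)
  fam_seq <- stats::setNames(vapply(fams, function(f) random_cds(n_codons),
                                    character(1)), fams)
  omega_of <- stats::setNames(
    unname(config$dnds_by_class[classes[names(classes)]]), names(classes))
  # ancestral per-gene sequence: array members diverge slightly from the
  # family ancestor so copies are distinguishable
  anc_seq <- stats::setNames(vapply(names(classes), function(g) {
    base <- fam_seq[[family_of[[g]]]]
    if (startsWith(g, "f")) mutate_cds(base, 0.01, omega_of[[g]]) else base
  }, character(1)), names(classes))

  n_tips <- length(species)
  root <- n_tips + 1L
  node_seqs <- list()
  node_seqs[[root]] <- anc_seq
  tip_seqs <- list()
  # preorder edge walk
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    bl <- tree$edge.length[e]
    seqs <- node_seqs[[par]]
    evolved <- stats::setNames(vapply(names(seqs), function(g) {
      mutate_cds(seqs[[g]], bl, omega_of[[g]])
    }, character(1)), names(seqs))
    if (child <= n_tips) {
      tip_seqs[[tree$tip.label[child]]] <- evolved
    } else {
      node_seqs[[child]] <- evolved
    }
  }

  ## --- per-species models, insertions, domains, BLAST -----------------
  n_ins <- round(config$insertion_frac * config$n_genes_per_genome)
  models <- list(); cds_all <- list(); prot_all <- list()
  domains <- list(); gene_anc <- list()
  for (sp in species) {
    per_chrom <- list()
    anc_of_gene <- character(0)
    for (ch in names(anc_order)) {
      ord <- anc_order[[ch]]
      ids <- sprintf("%s_%s", sp, ord)
      anc_of_gene[ids] <- ord
      per_chrom[[ch]] <- ids
    }
    # species-specific insertions at random positions
    if (n_ins > 0L) {
      for (k in seq_len(n_ins)) {
        ch <- sample(names(per_chrom), 1L)
        id <- sprintf("%s_ins%02d", sp, k)
        pos <- sample.int(length(per_chrom[[ch]]) + 1L, 1L)
        per_chrom[[ch]] <- append(per_chrom[[ch]], id, after = pos - 1L)
        anc_of_gene[id] <- NA_character_
      }
    }
    chunks <- lapply(names(per_chrom), function(ch) {
      ids <- per_chrom[[ch]]
      strands <- sample(c("+", "-"), length(ids), replace = TRUE,
                        prob = c(0.8, 0.2))
      layout_chromosome(ch, ids, strands, config$gene_length_bp)
    })
    m <- recompute_ordinals(do.call(rbind, chunks))
    models[[sp]] <- m
    gene_anc[[sp]] <- anc_of_gene
    seqs <- tip_seqs[[sp]]
    cds_sp <- stats::setNames(
      vapply(m$gene_id, function(g) {
        a <- anc_of_gene[[g]]
        if (is.na(a)) random_cds(n_codons) else seqs[[a]]
      }, character(1)), m$gene_id)
    cds_all[[sp]] <- cds_sp
    prot_all[[sp]] <- stats::setNames(
      vapply(names(cds_sp), function(g) translate_cds(cds_sp[[g]], g),
             character(1)), names(cds_sp))

    # domain annotations keyed by transcript id
    dom_rows <- list()
    aa_len <- n_codons
    for (g in m$gene_id) {
      a <- anc_of_gene[[g]]
      tid <- paste0(g, ".1")
      if (!is.na(a) && a %in% r_anc) {
        doms <- strsplit(arch_of[[a]], "-", fixed = TRUE)[[1L]]
        width <- max(10L, aa_len %/% (length(doms) + 1L))
        for (d in seq_along(doms)) {
          st <- 1L + (d - 1L) * width
          dom_rows[[length(dom_rows) + 1L]] <- tibble::tibble(
            protein_id = tid, domain_name = doms[d],
            env_start = st, env_end = st + width - 1L,
            evalue = 1e-10, source = "synthetic")
        }
      } else if (!is.na(a) && a %in% decoys) {
        dom_rows[[length(dom_rows) + 1L]] <- tibble::tibble(
          protein_id = tid, domain_name = "LRR",
          env_start = 5L, env_end = 60L, evalue = 1e-8,
          source = "synthetic")
      }
    }
    domains[[sp]] <- do.call(rbind, dom_rows)
  }

  blast_tibble <- function(qid, sid, id_frac, len_aa) {
    tibble::tibble(query_id = qid, subject_id = sid,
                   identity_pct = round(100 * id_frac, 2),
                   aln_length = len_aa,
                   evalue = identity_to_evalue(id_frac),
                   bitscore = round(2 * id_frac * len_aa, 1),
                   q_cov_pct = 100)
  }
  # within-genome hits: all ordered pairs of same-family genes
  hits_within <- list()
  for (sp in species) {
    anc <- gene_anc[[sp]]
    fam <- family_of[anc[models[[sp]]$gene_id]]
    names(fam) <- models[[sp]]$gene_id
    rows <- list()
    for (f in unique(fam[!is.na(fam)])) {
      mem <- names(fam)[!is.na(fam) & fam == f]
      if (length(mem) < 2L) next
      for (i in mem) for (j in mem) {
        if (i == j) next
        idf <- seq_identity(cds_all[[sp]][[i]], cds_all[[sp]][[j]])
        rows[[length(rows) + 1L]] <- blast_tibble(i, j, idf, n_codons)
      }
    }
    hits_within[[sp]] <- if (length(rows)) do.call(rbind, rows) else
      blast_tibble(character(0), character(0), numeric(0), integer(0))
  }
  # cross-genome hits: same-family genes across each species pair
  hits_cross <- list()
  pairs <- utils::combn(species, 2L, simplify = FALSE)
  for (p in pairs) {
    a <- p[1L]; b <- p[2L]
    anc_a <- gene_anc[[a]]; anc_b <- gene_anc[[b]]
    fam_a <- family_of[anc_a[models[[a]]$gene_id]]
    names(fam_a) <- models[[a]]$gene_id
    fam_b <- family_of[anc_b[models[[b]]$gene_id]]
    names(fam_b) <- models[[b]]$gene_id
    rows <- list()
    for (f in intersect(unique(fam_a[!is.na(fam_a)]),
                        unique(fam_b[!is.na(fam_b)]))) {
      mem_a <- names(fam_a)[!is.na(fam_a) & fam_a == f]
      mem_b <- names(fam_b)[!is.na(fam_b) & fam_b == f]
      for (i in mem_a) for (j in mem_b) {
        idf <- seq_identity(cds_all[[a]][[i]], cds_all[[b]][[j]])
        rows[[length(rows) + 1L]] <- blast_tibble(i, j, idf, n_codons)
      }
    }
    hits_cross[[paste(a, b, sep = "|")]] <- if (length(rows))
      do.call(rbind, rows) else
        blast_tibble(character(0), character(0), numeric(0), integer(0))
  }

  ## --- ground truth ----------------------------------------------------
  planted_arrays <- lapply(stats::setNames(species, species), function(sp) {
    lapply(array_members, function(mem) sprintf("%s_%s", sp, mem))
  })
  syntenic_map <- list()
  singleton_anc <- names(classes)[!startsWith(names(classes), "f")]
  for (p in pairs) {
    syntenic_map[[paste(p[1L], p[2L], sep = "|")]] <- tibble::tibble(
      gene_a = sprintf("%s_%s", p[1L], singleton_anc),
      gene_b = sprintf("%s_%s", p[2L], singleton_anc))
  }
  truth <- list(planted_arrays = planted_arrays, syntenic_map = syntenic_map,
                true_tree = config$species_tree,
                classes = classes, true_omega = omega_of,
                r_genes = r_anc, subgroups = arch_of,
                family_of = family_of, gene_anc = gene_anc)

  out <- list(species = species, models = models, cds = cds_all,
              proteins = prot_all, domains = domains,
              hits_within = hits_within, hits_cross = hits_cross,
              truth = truth, config = config)
  if (!is.null(out_dir)) out$files <- write_simulated_genomes(out, out_dir)
  out
}

# Write all simulated per-species files in the dialects the readers parse.
write_simulated_genomes <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  fa <- function(x, path) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(x)), path)
    path
  }
  for (sp in sim$species) {
    base <- file.path(out_dir, sp)
    files[[sp]] <- list(
      gff3 = write_gff3(sim$models[[sp]], paste0(base, ".gff3")),
      cds = fa(sim$cds[[sp]], paste0(base, ".cds.fasta")),
      proteins = {
        p <- paste0(base, ".proteins.fasta")
        Biostrings::writeXStringSet(
          Biostrings::AAStringSet(unlist(sim$proteins[[sp]])), p)
        p
      },
      domains = {
        p <- paste0(base, ".domains.txt")
        d <- sim$domains[[sp]]
        d <- d[d$domain_name != "CC", , drop = FALSE]
        raw_name <- c(NBS = "NB-ARC", LRR = "LRR_8", TIR = "TIR")[d$domain_name]
        writeLines(sprintf(
          "%s %d %d %d %d PF_SYN.1 %s Domain 1 %d %d 100.0 %.2g 1 No_clan",
          d$protein_id, d$env_start, d$env_end, d$env_start, d$env_end,
          raw_name, d$env_end - d$env_start + 1L,
          d$env_end - d$env_start + 1L, d$evalue), p)
        p
      },
      ncoils = {
        p <- paste0(base, ".ncoils.tsv")
        d <- sim$domains[[sp]]
        d <- d[d$domain_name == "CC", , drop = FALSE]
        writeLines(sprintf("%s\t%d\t%d", d$protein_id, d$env_start,
                           d$env_end), p)
        p
      },
      blast_self = {
        p <- paste0(base, ".self.blast.tsv")
        write_blast_tab(sim$hits_within[[sp]], p)
        p
      })
  }
  for (key in names(sim$hits_cross)) {
    p <- file.path(out_dir, paste0(gsub("|", "_", key, fixed = TRUE),
                                   ".blast.tsv"))
    write_blast_tab(sim$hits_cross[[key]], p)
    files$cross[[key]] <- p
  }
  tp <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(planted_arrays = sim$truth$planted_arrays,
         true_tree = sim$truth$true_tree,
         classes = as.list(sim$truth$classes),
         r_genes = sim$truth$r_genes),
    tp, auto_unbox = TRUE, pretty = TRUE)
  files$truth <- tp
  files
}

#' Write hits in BLAST outfmt-6 (12 columns)
#' @param hits tibble as produced by [read_blast_tab()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_blast_tab <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f",
                   hits$query_id, hits$subject_id, hits$identity_pct,
                   hits$aln_length, 0L, 0L, 1L, hits$aln_length, 1L,
                   hits$aln_length, hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a population VCF over one reference genome
#'
#' Segregating sites arise per gene (and over intergenic space) from a
#' Watterson process with E[S] = a1 * theta * L; per-class theta
#' multipliers and spectrum tilts come from the config. Derived-allele
#' counts follow P(i) proportional to 1/i^alpha over i = 1..n-1 with n the
#' haplotype count (two per accession); carriers are sampled uniformly.
#' Genotypes are written as phased haploid pairs ("0|1").
#'
#' @param config a [simulation_config()].
#' @param gene_models gene_table of the reference species.
#' @param cds_seqs named CDS vector of the reference species (gene ids).
#' @param classes named class vector (TD_R / singleton_R / background) per
#'   gene id; missing genes are background.
#' @param out_path optional VCF output path.
#' @return list with `vs` (a `variant_set`), `truth` (true_theta,
#'   n_sites, per_gene tibble), and `vcf` path when written.
#' @export
simulate_population <- function(config, gene_models, cds_seqs,
                                classes = NULL, out_path = NULL) {
  set.seed(config$seed + 1000003L)
  n_hap <- 2L * config$pop_n_accessions
  a1 <- sum(1 / seq_len(n_hap - 1L))
  theta <- config$theta_per_site
  cls <- stats::setNames(rep("background", nrow(gene_models)),
                         gene_models$gene_id)
  if (!is.null(classes)) {
    hit <- intersect(names(classes), names(cls))
    cls[hit] <- classes[hit]
  }
  strs <- gene_structures(gene_models, cds_seqs)
  names(strs) <- gene_models$gene_id

  draw_count <- function(i_max, alpha) {
    w <- 1 / seq_len(i_max)^alpha
    sample.int(i_max, 1L, prob = w)
  }
  bases <- c("A", "C", "G", "T")
  site_rows <- list(); gt_rows <- list(); per_gene <- list()
  add_site <- function(chrom, pos, ref, alt, alpha) {
    i <- draw_count(n_hap - 1L, alpha)
    carriers <- sample.int(n_hap, i)
    hap <- integer(n_hap); hap[carriers] <- 1L
    gt <- sprintf("%d|%d", hap[seq(1L, n_hap, 2L)], hap[seq(2L, n_hap, 2L)])
    site_rows[[length(site_rows) + 1L]] <<- tibble::tibble(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      is_snp = TRUE, indel_length = 0L)
    gt_rows[[length(gt_rows) + 1L]] <<- gt
  }
  for (g in gene_models$gene_id) {
    str <- strs[[g]]
    L <- str$end - str$start + 1L
    th <- theta * (config$pop_theta_boost[cls[[g]]] %||% 1)
    alpha <- config$pop_spectrum_alpha[cls[[g]]] %||% 1
    if (is.na(th)) th <- theta
    if (is.na(alpha)) alpha <- 1
    lambda <- a1 * th * L
    if (lambda > L) stop("theta too large: expected segregating sites ",
                         "exceed gene length for ", g)
    S <- stats::rpois(1L, lambda)
    S <- min(S, L)
    pos <- sort(sample.int(L, S)) + str$start - 1L
    for (p in pos) {
      idx <- cds_index_of(str, p)
      if (!is.na(idx) && !is.null(str$cds_seq) && idx <= nchar(str$cds_seq)) {
        base_tx <- substr(str$cds_seq, idx, idx)
        ref <- if (str$strand == "+") base_tx else unname(comp_base(base_tx))
      } else {
        ref <- sample(bases, 1L)
      }
      alt <- sample(setdiff(bases, ref), 1L)
      add_site(str$chrom, p, ref, alt, alpha)
    }
    per_gene[[g]] <- tibble::tibble(gene_id = g, class = cls[[g]],
                                    length_bp = L, S_planted = S)
  }
  # intergenic sites over the gaps between genes
  for (ch in unique(gene_models$chrom)) {
    sub <- gene_models[gene_models$chrom == ch, , drop = FALSE]
    gaps <- cbind(c(1L, sub$end + 1L),
                  c(sub$start - 1L, max(sub$end) + 200L))
    gaps <- gaps[gaps[, 1L] <= gaps[, 2L], , drop = FALSE]
    glen <- sum(gaps[, 2L] - gaps[, 1L] + 1L)
    S <- stats::rpois(1L, a1 * theta * glen)
    if (S > 0L) {
      offs <- sort(sample.int(glen, min(S, glen)))
      flat <- unlist(apply(gaps, 1L, function(r) r[1L]:r[2L]))
      for (p in flat[offs]) {
        ref <- sample(bases, 1L)
        add_site(ch, p, ref, sample(setdiff(bases, ref), 1L), 1)
      }
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    tibble::tibble(chrom = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), is_snp = logical(0),
                   indel_length = integer(0))
  gt <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    matrix(character(0), nrow = 0L, ncol = config$pop_n_accessions)
  colnames(gt) <- sprintf("acc%03d", seq_len(config$pop_n_accessions))
  o <- order(sites$chrom, sites$pos)
  vs <- new_variant_set(sites[o, , drop = FALSE], gt[o, , drop = FALSE])
  res <- list(vs = vs,
              truth = list(true_theta = theta, n_sites = nrow(sites),
                           per_gene = do.call(rbind, per_gene)))
  if (!is.null(out_path)) {
    write_vcf(vs, out_path)
    res$vcf <- out_path
  }
  res
}

#' Write a variant set as a minimal VCF 4.2 text file
#' @param vs a `variant_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(vs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(vs$gt)), collapse = "\t")),
             con)
  if (nrow(vs$sites) > 0L) {
    body <- vapply(seq_len(nrow(vs$sites)), function(i) {
      paste(c(vs$sites$chrom[i], vs$sites$pos[i], ".", vs$sites$ref[i],
              vs$sites$alt[i], ".", "PASS", ".", "GT", vs$gt[i, ]),
            collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}
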