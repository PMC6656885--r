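# Statistical contrasts, genome summary tables, histogram exports, and
# end-to-end pipeline orchestration on simulated inputs.

#' 2x2 chi-square test of association
#'
#' Expected counts E = row x col / N; chi2 = sum((|O - E| - 0.5*yates)^2 /
#' E) with the continuity term floored at zero; p from the upper tail of
#' the chi-square distribution with 1 degree of freedom. Yates correction
#' is on by default.
#'
#' @param table 2x2 nonnegative matrix (or something coercible).
#' @param yates apply the continuity correction (default TRUE).
#' @return list of class `contingency_result`: table, chi2, dof, p_value,
#'   p_label (the TSV convention "<2.2e-16" below that bound), yates.
#' @export
chi2_2x2 <- function(table, yates = TRUE) {
  tab <- as.matrix(table)
  stopifnot(dim(tab) == c(2L, 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square undefined: a row or column margin is zero")
  }
  N <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / N
  adj <- if (yates) pmax(abs(tab - E) - 0.5, 0) else abs(tab - E)
  chi2 <- sum(adj^2 / E)
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  structure(list(table = tab, chi2 = chi2, dof = 1L, p_value = p,
                 p_label = if (p < 2.2e-16) "<2.2e-16" else
                   format(p, digits = 3),
                 yates = yates),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 chi-square", if (x$yates) "(Yates-corrected)" else "(uncorrected)",
      "\n  chi2 =", format(x$chi2, digits = 6),
      " df = 1  p =", x$p_label, "\n")
  invisible(x)
}

#' Genome summary table (R-gene and locus counts per genome)
#'
#' One row per genome with the catalog and locus counts and their ratios
#' to two decimals. Internal identities are enforced: TD R genes +
#' singletons = NBS R genes, and arrays + singletons = loci; a violation
#' aborts (it means a pipeline bug upstream).
#'
#' @param per_genome named list; each element a list with `catalog` (from
#'   [catalog_summary()]) and `loci` (from [r_locus_counts()]).
#' @return tibble with columns genome, n_candidates, n_nbs_r, nbs_r_pct,
#'   n_td_arrays, n_td_genes, td_over_nbs, n_singletons, n_loci.
#' @export
summarize_catalog <- function(per_genome) {
  rows <- lapply(names(per_genome), function(g) {
    x <- per_genome[[g]]
    cat <- x$catalog; loc <- x$loci
    if (loc$n_td_genes + loc$n_singletons != cat$n_r_genes ||
        loc$n_td_arrays + loc$n_singletons != loc$n_loci) {
      stop("summary identity violated for genome ", g,
           ": TD genes + singletons must equal NBS R genes")
    }
    tibble::tibble(genome = g,
                   n_candidates = x$n_candidates %||% NA_integer_,
                   n_nbs_r = cat$n_r_genes,
                   nbs_r_pct = cat$ratio_pct,
                   n_td_arrays = loc$n_td_arrays,
                   n_td_genes = loc$n_td_genes,
                   td_over_nbs = loc$td_over_nbs,
                   n_singletons = loc$n_singletons,
                   n_loci = loc$n_loci)
  })
  do.call(rbind, rows)
}

#' Export a histogram as fixed-width-bin proportions
#'
#' @param values finite numeric values; NA/NaN/Inf are excluded with a
#'   message.
#' @param bins number of bins.
#' @param range optional c(min, max); defaults to the data range.
#' @return tibble bin_lo, bin_hi, count, proportion (sums to 1).
#' @export
distribution_export <- function(values, bins = 20L, range = NULL) {
  bad <- !is.finite(values)
  if (any(bad)) message(sum(bad), " non-finite value(s) excluded")
  v <- values[!bad]
  if (length(v) == 0L) stop("no finite values to bin")
  r <- range %||% base::range(v)
  if (r[1L] == r[2L]) r <- r + c(-0.5, 0.5)
  breaks <- seq(r[1L], r[2L], length.out = bins + 1L)
  v <- pmin(pmax(v, r[1L]), r[2L])
  cnt <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  tibble::tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
                 count = cnt, proportion = cnt / sum(cnt))
}

#' Run the whole pipeline on a simulated dataset
#'
#' Generates genomes and a population from `config`, writes all external
#' files, reads them back through the format readers, and executes
#' classify -> tandem -> synteny -> families -> Ka/Ks -> species tree ->
#' population statistics -> report, writing every output TSV under
#' `out_dir`. Deterministic given the config seed.
#'
#' @param config a [simulation_config()] (or path to a YAML file with its
#'   fields).
#' @param out_dir output directory.
#' @param n_boot bootstrap replicates for the species tree.
#' @return (invisibly) list of in-memory results: sim, catalogs, loci,
#'   pairs, families, kaks, tree, diversity, burden, report paths.
#' @export
run_pipeline <- function(config, out_dir, n_boot = 100L) {
  if (is.character(config)) {
    cfgl <- yaml::read_yaml(config)
    cfgl$dnds_by_class <- unlist(cfgl$dnds_by_class)
    cfgl$pop_theta_boost <- unlist(cfgl$pop_theta_boost)
    cfgl$pop_spectrum_alpha <- unlist(cfgl$pop_spectrum_alpha)
    cfgl$array_size_range <- unlist(cfgl$array_size_range)
    config <- do.call(simulation_config, cfgl)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(out_dir, "simulated")
  sim <- simulate_genomes(config, out_dir = sim_dir)
  species <- sim$species

  # read everything back through the format layer
  models <- lapply(stats::setNames(species, species), function(sp) {
    read_gff3(sim$files[[sp]]$gff3)
  })
  doms <- lapply(stats::setNames(species, species), function(sp) {
    rbind(read_domains(sim$files[[sp]]$domains, "pfam_scan"),
          read_domains(sim$files[[sp]]$ncoils, "ncoils_tsv"))
  })

  per_genome <- list(); loci_by_genome <- list(); r_records <- list()
  arrays_all <- list()
  for (sp in species) {
    rr <- suppressMessages(select_nbs_genes(doms[[sp]], models[[sp]]))
    hits <- read_blast_tab(sim$files[[sp]]$blast_self, max_evalue = 1e-2)
    cl <- homology_clusters(hits, universe = rr$gene_id)
    r_models <- models[[sp]][models[[sp]]$gene_id %in% rr$gene_id, ,
                             drop = FALSE]
    arrays <- detect_tandem_arrays(r_models, cl, max_gap = 5L)
    loci <- to_r_loci(rr, arrays)
    per_genome[[sp]] <- list(
      catalog = catalog_summary(rr, nrow(models[[sp]])),
      loci = r_locus_counts(loci, nrow(rr)),
      n_candidates = length(unique(doms[[sp]]$protein_id)))
    loci_by_genome[[sp]] <- loci
    r_records[[sp]] <- rr
    arrays_all[[sp]] <- arrays
  }
  report_tbl <- summarize_catalog(per_genome)
  write_report_tsv(report_tbl, file.path(out_dir, "genome_summary.tsv"))

  # synteny on locus-collapsed models over every genome pair
  params <- synteny_params()
  pairs_all <- list()
  collapsed <- lapply(stats::setNames(species, species), function(sp) {
    collapse_to_loci(models[[sp]], arrays_all[[sp]])
  })
  for (key in names(sim$hits_cross)) {
    sp <- strsplit(key, "|", fixed = TRUE)[[1L]]
    hits <- read_blast_tab(sim$files$cross[[key]], max_evalue = 1e-20)
    pairs_all[[key]] <- pairwise_synteny(collapsed[[sp[1L]]],
                                         collapsed[[sp[2L]]], hits, params,
                                         genome_a = sp[1L],
                                         genome_b = sp[2L])
  }
  pairs <- do.call(rbind, pairs_all)
  # map array representatives back to their locus ids for family building
  locus_tables <- lapply(stats::setNames(species, species), function(sp) {
    loci <- loci_by_genome[[sp]]
    rep_to_locus <- stats::setNames(loci$locus_id, loci$representative_id)
    all_genes <- collapsed[[sp]]$gene_id
    tibble::tibble(
      locus_id = ifelse(is.na(rep_to_locus[all_genes]), all_genes,
                        rep_to_locus[all_genes]),
      kind = ifelse(is.na(rep_to_locus[all_genes]), NA_character_,
                    loci$kind[match(rep_to_locus[all_genes],
                                    loci$locus_id)]))
  })
  pairs_loci <- pairs
  for (side in c("a", "b")) {
    gcol <- paste0("gene_", side); ncol_ <- paste0("genome_", side)
    for (sp in species) {
      lt <- locus_tables[[sp]]
      map <- stats::setNames(lt$locus_id, collapsed[[sp]]$gene_id)
      sel <- pairs_loci[[ncol_]] == sp
      pairs_loci[[gcol]][sel] <- map[pairs_loci[[gcol]][sel]]
    }
  }
  families <- build_families(pairs_loci, locus_tables)
  write_report_tsv(
    tibble::tibble(family_id = families$family_id,
                   n_genomes = families$n_genomes,
                   species_specific = families$species_specific,
                   contains_td = families$contains_td),
    file.path(out_dir, "families.tsv"))
  ref <- species[1L]
  syn_summary <- r_locus_synteny_summary(loci_by_genome[[ref]], families, ref)

  # Ka/Ks between syntenic R-locus representatives, split TD vs singleton
  kaks <- kaks_on_r_pairs(pairs, loci_by_genome, sim$cds, species)
  write_report_tsv(kaks, file.path(out_dir, "kaks.tsv"))
  for (kind in c("TD", "singleton")) {
    vals <- kaks$ratio[kaks$kind == kind & is.finite(kaks$ratio)]
    if (length(vals) > 0L) {
      write_report_tsv(distribution_export(vals, bins = 20L,
                                           range = c(0, 2)),
                       file.path(out_dir, sprintf("kaks_hist_%s.tsv", kind)))
    }
  }

  # species tree from concatenated synonymous loci of clean 1:1 families
  fams_cds <- one_per_genome_families(sim, species)
  tree_res <- species_tree_from_ks(fams_cds, n_boot = n_boot,
                                   seed = config$seed)
  write_newick(tree_res$tree, file.path(out_dir, "species_tree.nwk"))

  # population statistics on the reference genome
  pop <- simulate_population(config, models[[ref]], sim$cds[[ref]],
                             classes = class_map(sim, ref),
                             out_path = file.path(sim_dir,
                                                  paste0(ref, ".vcf")))
  vs <- read_vcf(pop$vcf)
  vs <- suppressMessages(filter_sites(vs, maf_min = 0.05))
  effects <- classify_variants(vs, models[[ref]], sim$cds[[ref]])
  cls <- class_map(sim, ref)
  sets <- list(
    all = models[[ref]]$gene_id,
    R = names(cls)[cls != "background"],
    R_TD = names(cls)[cls == "TD_R"],
    R_singleton = names(cls)[cls == "singleton_R"])
  burden <- functional_burden(effects, sets)
  div <- gene_diversity(vs, models[[ref]], effects)
  write_report_tsv(div, file.path(out_dir, "diversity.tsv"))
  write_report_tsv(effects, file.path(out_dir, "effects.tsv"))
  write_report_tsv(burden$summary, file.path(out_dir, "burden.tsv"))
  pi_r <- div$pi[div$gene_id %in% sets$R]
  write_report_tsv(distribution_export(pi_r[is.finite(pi_r)], bins = 20L,
                                       range = c(0, 1)),
                   file.path(out_dir, "pi_hist_R.tsv"))

  chi <- chi2_2x2(syn_summary$td_shared_specific)
  write_report_tsv(
    tibble::tibble(comparison = "TD composition, shared vs specific families",
                   chi2 = chi$chi2, p_value = chi$p_value,
                   p_label = chi$p_label),
    file.path(out_dir, "chi2.tsv"))

  invisible(list(sim = sim, models = models, per_genome = per_genome,
                 report = report_tbl, pairs = pairs, families = families,
                 syn_summary = syn_summary, kaks = kaks, tree = tree_res,
                 diversity = div, burden = burden, out_dir = out_dir))
}

# Per-gene class map (TD_R / singleton_R / background) for one species.
class_map <- function(sim, sp) {
  anc <- sim$truth$gene_anc[[sp]]
  cls <- sim$truth$classes[anc]
  cls[is.na(cls)] <- "background"
  stats::setNames(unname(cls), names(anc))
}

# Ka/Ks rows for syntenic R-locus pairs, labeled TD/singleton by the
# reference-side locus kind.
kaks_on_r_pairs <- function(pairs, loci_by_genome, cds, species) {
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    sa <- pairs$genome_a[k]; sb <- pairs$genome_b[k]
    ga <- pairs$gene_a[k]; gb <- pairs$gene_b[k]
    la <- loci_by_genome[[sa]]
    kind <- la$kind[la$representative_id == ga]
    if (length(kind) == 0L) next  # not an R locus
    res <- nei_gojobori(codon_align(cds[[sa]][[ga]], cds[[sb]][[gb]],
                                    ids = c(ga, gb)))
    res$kind <- kind
    res$genome_a <- sa; res$genome_b <- sb
    rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(gene_a = character(0), gene_b = character(0),
                          Ka = numeric(0), Ks = numeric(0),
                          ratio = numeric(0), kind = character(0)))
  }
  do.call(rbind, rows)
}

# Ungapped multi-species codon alignments of families present once per
# genome (the species-tree input).
one_per_genome_families <- function(sim, species) {
  anc_sets <- lapply(species, function(sp) {
    a <- sim$truth$gene_anc[[sp]]
    a[!is.na(a)]
  })
  singletons <- names(sim$truth$classes)[!startsWith(names(sim$truth$classes),
                                                     "f")]
  lapply(singletons, function(anc) {
    cds <- stats::setNames(vapply(species, function(sp) {
      gid <- names(anc_sets[[match(sp, species)]])[anc_sets[[match(sp, species)]] == anc]
      sim$cds[[sp]][[gid[1L]]]
    }, character(1)), species)
    codon_align_ungapped(cds)
  })
}
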