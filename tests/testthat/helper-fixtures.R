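# Fixture builders used across test files. Everything is generated in code;
# no stored data files.

# A minimal gene_table: n genes on one chromosome, two exons with a 60-bp
# intron, 30-bp UTRs, CDS length cds_len (multiple of 3).
make_gene_table <- function(n, chrom = "chr1", cds_len = 90L,
                            strand = rep("+", n), gap = 200L,
                            prefix = "g") {
  utr <- 30L; intron <- 60L
  cds1 <- cds_len %/% 2L
  cds2 <- cds_len - cds1
  rows <- list()
  cursor <- 1L
  for (i in seq_len(n)) {
    s <- cursor
    c1s <- s + utr; c1e <- c1s + cds1 - 1L
    is_ <- c1e + 1L; ie <- is_ + intron - 1L
    c2s <- ie + 1L; c2e <- c2s + cds2 - 1L
    e2e <- c2e + utr
    rows[[i]] <- tibble::tibble(
      gene_id = sprintf("%s%03d", prefix, i), chrom = chrom,
      start = s, end = e2e, strand = strand[i],
      transcript_id = sprintf("%s%03d.1", prefix, i),
      exons = list(cbind(start = c(s, c2s), end = c(c1e, e2e))),
      cds = list(cbind(start = c(c1s, c2s), end = c(c1e, c2e),
                       phase = c(0L, (3L - cds1 %% 3L) %% 3L))))
    cursor <- e2e + gap + 1L
  }
  recompute_ordinals(do.call(rbind, rows))
}

# Random CDS without stop codons.
random_sense_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# A hit tibble in read_blast_tab() shape.
make_hits <- function(query, subject, evalue = 1e-30, bitscore = 200,
                      identity = 95) {
  tibble::tibble(query_id = query, subject_id = subject,
                 identity_pct = identity, aln_length = 100L,
                 evalue = evalue, bitscore = bitscore, q_cov_pct = 100)
}

# A variant_set from explicit haplotype allele rows (sites x haplotypes,
# 0/1 integers); haplotypes are written as haploid GT strings so every
# haplotype is one "sample".
vs_from_haplotypes <- function(hap, chrom = "chr1",
                               pos = seq_len(nrow(hap)) * 10L,
                               ref = "A", alt = "T") {
  gt <- matrix(as.character(hap), nrow = nrow(hap),
               dimnames = list(NULL, sprintf("h%02d", seq_len(ncol(hap)))))
  rgenevol:::new_variant_set(
    tibble::tibble(chrom = chrom, pos = as.integer(pos),
                   ref = ref, alt = alt,
                   is_snp = TRUE, indel_length = 0L),
    gt)
}

# Allele-count table (the popgen input) from a haplotype 0/1 matrix.
stats_from_haplotypes <- function(hap) {
  tibble::tibble(n_called = rep(ncol(hap), nrow(hap)),
                 n_alt = rowSums(hap))
}

# Memoized default-config simulations (several tests share one).
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed) {
  key <- as.character(seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_genomes(simulation_config(seed = seed))
  }
  .sim_cache[[key]]
}

# Random additive distance matrix: build a random binary tree with positive
# edge lengths and return its path-length matrix plus the tree.
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2))
  tree$tip.label <- sort(tree$tip.label)
  d <- ape::cophenetic.phylo(tree)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tree, d = d)
}
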