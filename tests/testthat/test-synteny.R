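# Flanking-gene synteny detection, families, and synteny depth.

# Two toy genomes: B is A with optional inserted genes and/or duplication.
toy_pair_hits <- function(ids_a, ids_b, map) {
  # map: named vector a-id -> b-id (true orthologs, strong hits)
  make_hits(names(map), unname(map), evalue = 1e-60, bitscore = 300)
}

test_that("identical genomes pair every gene with its copy at ratio 1", {
  a <- make_gene_table(20, prefix = "a")
  b <- make_gene_table(20, prefix = "b")
  map <- stats::setNames(b$gene_id, a$gene_id)
  pairs <- pairwise_synteny(a, b, toy_pair_hits(a, b, map),
                            synteny_params(), "A", "B")
  expect_equal(nrow(pairs), 20L)
  expect_equal(stats::setNames(pairs$gene_b, pairs$gene_a), map[pairs$gene_a])
  expect_true(all(pairs$flank_ratio == 1))
})

test_that("inserted unrelated genes lower but do not break synteny", {
  a <- make_gene_table(20, prefix = "a")
  b <- make_gene_table(25, prefix = "x")
  # five unrelated genes occupy interior positions of genome B
  ins_pos <- c(4L, 9L, 13L, 18L, 22L)
  ids <- character(25)
  ids[ins_pos] <- sprintf("ins%02d", 1:5)
  ids[-ins_pos] <- sprintf("b%03d", 1:20)
  b$gene_id <- ids
  b$transcript_id <- paste0(ids, ".1")
  map <- stats::setNames(sprintf("b%03d", 1:20), a$gene_id)
  pairs <- pairwise_synteny(a, b, toy_pair_hits(a, b, map),
                            synteny_params(), "A", "B")
  expect_equal(nrow(pairs), 20L)  # full recall at window 10
  expect_true(all(pairs$flank_ratio >= 0.3))
  expect_true(any(pairs$flank_ratio < 1))
})

test_that("synteny is symmetric in the two genomes", {
  sim <- cached_sim(9)
  pa <- pairwise_synteny(sim$models$A, sim$models$B,
                         sim$hits_cross[["A|B"]], synteny_params(),
                         "A", "B")
  pb <- pairwise_synteny(sim$models$B, sim$models$A,
                         sim$hits_cross[["A|B"]], synteny_params(),
                         "B", "A")
  expect_setequal(paste(pa$gene_a, pa$gene_b), paste(pb$gene_b, pb$gene_a))
})

test_that("a tandem array collapsed to its representative yields one pair", {
  sim <- cached_sim(9)
  sp <- "A"; sq <- "B"
  rr_a <- suppressMessages(select_nbs_genes(sim$domains[[sp]],
                                            sim$models[[sp]]))
  cl_a <- homology_clusters(sim$hits_within[[sp]], universe = rr_a$gene_id)
  arr_a <- detect_tandem_arrays(
    sim$models[[sp]][sim$models[[sp]]$gene_id %in% rr_a$gene_id, ], cl_a)
  rr_b <- suppressMessages(select_nbs_genes(sim$domains[[sq]],
                                            sim$models[[sq]]))
  cl_b <- homology_clusters(sim$hits_within[[sq]], universe = rr_b$gene_id)
  arr_b <- detect_tandem_arrays(
    sim$models[[sq]][sim$models[[sq]]$gene_id %in% rr_b$gene_id, ], cl_b)
  ca <- collapse_to_loci(sim$models[[sp]], arr_a)
  cb <- collapse_to_loci(sim$models[[sq]], arr_b)
  pairs <- pairwise_synteny(ca, cb, sim$hits_cross[["A|B"]],
                            synteny_params(), sp, sq)
  for (k in seq_len(nrow(arr_a))) {
    rep_a <- arr_a$representative_id[k]
    expect_equal(sum(pairs$gene_a == rep_a), 1L)
    # the partner is the representative of the corresponding B array
    expect_true(pairs$gene_b[pairs$gene_a == rep_a] %in%
                  arr_b$representative_id)
  }
})

test_that("families are transitive components plus singleton leftovers", {
  pairs <- tibble::tibble(
    genome_a = c("A", "B"), genome_b = c("B", "C"),
    gene_a = c("a1", "b1"), gene_b = c("b1", "c1"),
    flank_ratio = 1, n_flank_support = 10L, bitscore = 300)
  loci <- list(
    A = tibble::tibble(locus_id = c("a1", "a2"),
                       kind = c("singleton", "TD")),
    B = tibble::tibble(locus_id = "b1", kind = "singleton"),
    C = tibble::tibble(locus_id = "c1", kind = "singleton"))
  fams <- build_families(pairs, loci)
  expect_equal(nrow(fams), 2L)
  big <- fams[fams$n_genomes == 3, ]
  expect_equal(nrow(big), 1L)
  expect_false(big$species_specific)
  lone <- fams[fams$n_genomes == 1, ]
  expect_equal(lone$members[[1]]$locus_id, "a2")
  expect_true(lone$species_specific)
  expect_true(lone$contains_td)
  # families partition all loci
  all_members <- do.call(rbind, fams$members)
  expect_equal(nrow(all_members), 4L)
  expect_false(anyDuplicated(paste(all_members$genome,
                                   all_members$locus_id)) > 0)
})

test_that("planted orthogroups are recovered as families across 4 genomes", {
  sim <- cached_sim(9)
  params <- synteny_params()
  pairs <- do.call(rbind, lapply(names(sim$hits_cross), function(key) {
    sp <- strsplit(key, "|", fixed = TRUE)[[1]]
    pairwise_synteny(sim$models[[sp[1]]], sim$models[[sp[2]]],
                     sim$hits_cross[[key]], params, sp[1], sp[2])
  }))
  loci <- lapply(sim$models, function(m) tibble::tibble(locus_id = m$gene_id))
  fams <- build_families(pairs, loci)
  full <- fams[fams$n_genomes == 4, ]
  # every ancestral singleton present in all four genomes forms one family
  singles <- names(sim$truth$classes)[!startsWith(names(sim$truth$classes),
                                                  "f")]
  expect_gte(nrow(full), length(singles) * 0.95)
})

test_that("synteny depth separates diploid-like from duplicated genomes", {
  a <- make_gene_table(15, prefix = "a")
  b <- make_gene_table(15, prefix = "b")
  map <- stats::setNames(b$gene_id, a$gene_id)
  # depth profiling keeps all partners; with duplicated copies the flank
  # support must count any hit, not only reciprocal-best ones
  params <- synteny_params(require_best_hit_flanks = FALSE)
  p1 <- pairwise_synteny(a, b, toy_pair_hits(a, b, map), params,
                         "A", "B", keep_all = TRUE)
  d1 <- synteny_depth(a, p1, b)
  expect_equal(d1$modal_depth, 1)
  # whole-genome duplication of the query: two chromosomes of copies
  b2 <- make_gene_table(15, chrom = "chr9", prefix = "c")
  bdup <- recompute_ordinals(rbind(b, b2))
  hits <- rbind(toy_pair_hits(a, b, map),
                make_hits(a$gene_id, b2$gene_id, evalue = 1e-55,
                          bitscore = 290))
  p2 <- pairwise_synteny(a, bdup, hits, params, "A", "B",
                         keep_all = TRUE)
  d2 <- synteny_depth(a, p2, bdup)
  expect_equal(d2$modal_depth, 2)
})
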