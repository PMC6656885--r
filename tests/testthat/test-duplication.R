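# Homology clusters, the tandem gap rule, and R-locus reduction.

test_that("homology clusters are single-linkage components", {
  hits <- make_hits(c("a", "b"), c("b", "c"))
  cl <- homology_clusters(hits)
  expect_equal(length(unique(cl[c("a", "b", "c")])), 1L)
  # no hits: every gene its own cluster
  cl2 <- homology_clusters(make_hits(character(0), character(0)),
                           universe = c("x", "y", "z"))
  expect_equal(length(unique(cl2)), 3L)
  # the e-value threshold severs weak edges
  hits3 <- rbind(make_hits("a", "b", evalue = 1e-30),
                 make_hits("b", "c", evalue = 1e-1))
  cl3 <- homology_clusters(hits3, universe = c("a", "b", "c"),
                           evalue_max = 1e-2)
  expect_equal(cl3[["a"]], cl3[["b"]])
  expect_false(cl3[["b"]] == cl3[["c"]])
})

test_that("gap rule joins across small gaps and splits at large ones", {
  gm <- make_gene_table(12)
  ids <- gm$gene_id
  # cluster {g1, g3, g10}: gap 1 joins g1-g3, gap 6 splits off g10
  cl <- stats::setNames(rep(1L, 3), ids[c(1, 3, 10)])
  arr <- detect_tandem_arrays(gm, cl, max_gap = 5L)
  expect_equal(nrow(arr), 1L)
  expect_setequal(arr$member_gene_ids[[1]], ids[c(1, 3)])
})

test_that("exactly max_gap intervening genes still joins (inclusive bound)", {
  gm <- make_gene_table(10)
  ids <- gm$gene_id
  cl <- stats::setNames(rep(1L, 2), ids[c(1, 7)])  # 5 intervening genes
  arr <- detect_tandem_arrays(gm, cl, max_gap = 5L)
  expect_equal(nrow(arr), 1L)
  cl2 <- stats::setNames(rep(1L, 2), ids[c(1, 8)])  # 6 intervening genes
  expect_equal(nrow(detect_tandem_arrays(gm, cl2, max_gap = 5L)), 0L)
})

test_that("arrays never span chromosomes and partition their members", {
  gm1 <- make_gene_table(6, chrom = "chr1", prefix = "a")
  gm2 <- make_gene_table(6, chrom = "chr2", prefix = "b")
  gm <- recompute_ordinals(rbind(gm1, gm2))
  cl <- stats::setNames(rep(1L, 4), c("a001", "a002", "b001", "b002"))
  arr <- detect_tandem_arrays(gm, cl)
  expect_equal(nrow(arr), 2L)
  expect_equal(sort(arr$chrom), c("chr1", "chr2"))
  expect_false(anyDuplicated(unlist(arr$member_gene_ids)) > 0)
})

test_that("increasing max_gap never increases the number of arrays", {
  set.seed(31)
  for (rep in 1:5) {
    gm <- make_gene_table(30)
    members <- sort(sample(gm$gene_id, 12))
    cl <- stats::setNames(rep(1L, 12), members)
    n_prev <- Inf
    for (gap in c(0L, 1L, 3L, 5L, 10L)) {
      n <- nrow(detect_tandem_arrays(gm, cl, max_gap = gap))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("detection is invariant to input record order", {
  set.seed(13)
  gm <- make_gene_table(20)
  members <- sort(sample(gm$gene_id, 8))
  cl <- stats::setNames(rep(1L, 8), members)
  arr1 <- detect_tandem_arrays(gm, cl)
  perm <- sample(nrow(gm))
  arr2 <- detect_tandem_arrays(recompute_ordinals(gm[perm, ]),
                               cl[sample(8)])
  expect_equal(arr1$member_gene_ids, arr2$member_gene_ids)
})

test_that("planted arrays are recovered exactly from simulated genomes", {
  sim <- cached_sim(21)
  for (sp in sim$species) {
    rr <- suppressMessages(select_nbs_genes(sim$domains[[sp]],
                                            sim$models[[sp]]))
    cl <- homology_clusters(sim$hits_within[[sp]], universe = rr$gene_id)
    r_models <- sim$models[[sp]][sim$models[[sp]]$gene_id %in% rr$gene_id, ]
    arr <- detect_tandem_arrays(r_models, cl)
    got <- sort(vapply(arr$member_gene_ids,
                       function(x) paste(sort(x), collapse = ","),
                       character(1)))
    want <- sort(vapply(sim$truth$planted_arrays[[sp]],
                        function(x) paste(sort(x), collapse = ","),
                        character(1)))
    expect_equal(got, want)
  }
})

test_that("R loci counts satisfy the summary identities", {
  gm <- make_gene_table(10)
  ann <- do.call(rbind, lapply(gm$transcript_id[1:5], function(tid) {
    tibble::tibble(protein_id = tid, domain_name = "NBS",
                   env_start = 1L, env_end = 100L, evalue = 1e-10,
                   source = "test")
  }))
  rr <- suppressMessages(select_nbs_genes(ann, gm))
  cl <- stats::setNames(rep(1L, 4), gm$gene_id[1:4])
  arr <- detect_tandem_arrays(gm[gm$gene_id %in% rr$gene_id, ], cl)
  loci <- to_r_loci(rr, arr)
  cnt <- r_locus_counts(loci, nrow(rr))
  expect_equal(cnt$n_td_arrays, 1L)
  expect_equal(cnt$n_td_genes, 4L)
  expect_equal(cnt$n_singletons, 1L)
  expect_equal(cnt$n_loci, 2L)
  expect_equal(cnt$td_over_nbs, "0.80")
  # no arrays: loci are exactly the singletons
  loci0 <- to_r_loci(rr, detect_tandem_arrays(gm[0, ], cl))
  expect_equal(nrow(loci0), nrow(rr))
  expect_true(all(loci0$kind == "singleton"))
})

test_that("array representative has the longest CDS, ties by position", {
  gm <- make_gene_table(3)
  # enlarge the CDS of the middle gene
  gm$cds[[2]][2, "end"] <- gm$cds[[2]][2, "end"] + 30L
  gm$exons[[2]][2, "end"] <- gm$exons[[2]][2, "end"] + 30L
  cl <- stats::setNames(rep(1L, 3), gm$gene_id)
  arr <- detect_tandem_arrays(gm, cl)
  expect_equal(arr$representative_id, gm$gene_id[2])
})
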