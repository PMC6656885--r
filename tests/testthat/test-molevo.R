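# Codon alignment, Nei-Gojobori Ka/Ks, synonymous loci, NJ, bootstrap.

test_that("codon alignment propagates protein gaps as gap codons", {
  # proteins MA-K vs MAGK: row a gains a "---" at column 3
  cds_a <- "ATGGCTAAA"        # M A K
  cds_b <- "ATGGCTGGTAAA"     # M A G K
  ca <- codon_align(cds_a, cds_b, protein_aln = c("MA-K", "MAGK"))
  expect_equal(ca$codons[1, ], c("ATG", "GCT", "---", "AAA"))
  expect_equal(ca$codons[2, ], c("ATG", "GCT", "GGT", "AAA"))
  # ungapped identical proteins: side-by-side CDS
  ca2 <- codon_align(cds_a, cds_a)
  expect_equal(ca2$codons[1, ], ca2$codons[2, ])
})

test_that("codon alignment round-trips through translation", {
  set.seed(19)
  gc <- Biostrings::GENETIC_CODE
  for (i in 1:5) {
    cds_a <- random_sense_cds(40)
    cds_b <- random_sense_cds(40)
    aln <- align_proteins(rgenevol:::translate_cds(cds_a),
                          rgenevol:::translate_cds(cds_b))
    ca <- codon_align(cds_a, cds_b, protein_aln = aln)
    for (r in 1:2) {
      cod <- ca$codons[r, ]
      aa <- unname(ifelse(cod == "---", "-", gc[cod]))
      expect_equal(paste(aa, collapse = ""), aln[r])
    }
  }
  # internal stop is rejected with the codon position
  expect_error(codon_align("ATGTAAAAG", "ATGGCTAAG"), "stop codon")
})

test_that("Nei-Gojobori reproduces the hand-worked example", {
  res <- nei_gojobori(codon_align("TTTGATGCC", "TTCGATGCC",
                                  ids = c("x", "y")))
  expect_equal(res$Sd, 1)
  expect_equal(res$Nd, 0)
  expect_equal(res$S_sites, 5 / 3, tolerance = 1e-12)
  expect_equal(res$Ks, -0.75 * log(1 - (4 / 3) * (3 / 5)), tolerance = 1e-9)
  expect_equal(res$Ka, 0)
  # identical sequences
  res0 <- nei_gojobori(codon_align("TTTGATGCC", "TTTGATGCC"))
  expect_equal(c(res0$Ka, res0$Ks, res0$Nd, res0$Sd), c(0, 0, 0, 0))
})

test_that("Nei-Gojobori is symmetric and conserves sites", {
  set.seed(23)
  for (i in 1:5) {
    a <- random_sense_cds(30)
    b <- random_sense_cds(30)
    r1 <- nei_gojobori(codon_align(a, b))
    r2 <- nei_gojobori(codon_align(b, a))
    expect_equal(r1$Ka, r2$Ka, tolerance = 1e-12)
    expect_equal(r1$Ks, r2$Ks, tolerance = 1e-12)
    expect_equal(r1$N_sites + r1$S_sites, 3 * r1$n_codons,
                 tolerance = 1e-12)
  }
})

test_that("pathway-averaged differences match exhaustive enumeration", {
  # spot-check random codon pairs here; the full 61x61 sweep runs in the
  # acceptance suite
  set.seed(29)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (i in 1:40) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    got <- rgenevol:::ng_codon_diffs(c1, c2)
    want <- oracle_ng_diffs(c1, c2)
    expect_equal(unname(got["sd"]), unname(want["sd"]), tolerance = 1e-12)
    expect_equal(unname(got["nd"]), unname(want["nd"]), tolerance = 1e-12)
  }
})

test_that("simulated omega is recovered by Ka/Ks on long sequences", {
  set.seed(37)
  anc <- random_sense_cds(4000)
  lo <- rgenevol:::mutate_cds(anc, 0.05, 0.2)
  hi <- rgenevol:::mutate_cds(anc, 0.05, 1.0)
  r_lo <- nei_gojobori(codon_align_ungapped(c(a = anc, b = lo)))
  r_hi <- nei_gojobori(codon_align_ungapped(c(a = anc, b = hi)))
  expect_lt(r_lo$ratio, r_hi$ratio)
  expect_lt(abs(r_lo$ratio - 0.2), 0.1)
})

test_that("Ks-locus extraction keeps synonymous variant columns only", {
  ca <- codon_align_ungapped(c(s1 = "TTTAAAGGT", s2 = "TTCAAAGGT",
                               s3 = "TTTAAAGGT"))
  cols <- extract_ks_loci(ca)
  expect_equal(ncol(cols), 1L)             # TTT/TTC third position
  expect_equal(unname(cols[, 1]), c("T", "C", "T"))
  # nonsynonymous variation excludes the whole codon column
  ca2 <- codon_align_ungapped(c(s1 = "TTTAAA", s2 = "TTAAAA"))  # Phe/Leu
  expect_equal(ncol(extract_ks_loci(ca2)), 0L)
  # invariant columns are not loci
  ca3 <- codon_align_ungapped(c(s1 = "TTTAAA", s2 = "TTTAAA"))
  expect_equal(ncol(extract_ks_loci(ca3)), 0L)
})

test_that("NJ recovers an additive tree exactly", {
  d <- matrix(c(0, 2, 4, 5,
                2, 0, 4, 5,
                4, 4, 0, 5,
                5, 5, 5, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  # the AB|CD split is present
  expect_true(any(vapply(ape::prop.part(tr), function(p) {
    setequal(tr$tip.label[p], c("A", "B")) ||
      setequal(tr$tip.label[p], c("C", "D"))
  }, logical(1))))
})

test_that("NJ reproduces random additive matrices up to n = 12", {
  for (n in c(4, 6, 9, 12)) {
    fix <- random_additive_matrix(n, seed = 100 + n)
    tr <- nj_tree(fix$d)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(fix$d), colnames(fix$d)],
                 fix$d, tolerance = 1e-8)
    # independent cross-check: ape's own NJ finds the same topology
    ref <- ape::nj(fix$d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(ref))), 0)
  }
})

test_that("three taxa give the closed-form star", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  el <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["A"]], (3 + 5 - 6) / 2)
  expect_equal(el[["B"]], (3 + 6 - 5) / 2)
  expect_equal(el[["C"]], (5 + 6 - 3) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("bootstrap gives full support on cleanly separated clades", {
  cols <- rbind(A = rep(c("A", "C"), each = 10),
                B = rep(c("A", "C"), each = 10),
                C = rep(c("G", "T"), each = 10),
                D = rep(c("G", "T"), each = 10))
  tr <- bootstrap_support(cols, n_reps = 50, seed = 7)
  sup <- as.integer(tr$node.label)
  expect_true(all(sup == 100))
  # determinism given the seed
  tr2 <- bootstrap_support(cols, n_reps = 50, seed = 7)
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))
  expect_error(bootstrap_support(cols, n_reps = 0), "n_reps")
})

test_that("identity and coverage behave at the boundaries", {
  p <- "MKVLAAGHSTWQERTYIPAS"
  expect_equal(unname(pair_identity_coverage(p, p)), c(100, 100))
  half <- substr(p, 1, 10)
  expect_equal(unname(pair_identity_coverage(half, p)[["coverage"]]), 100)
  expect_equal(unname(pair_identity_coverage(p, half)[["coverage"]]), 50)
  # 3 mismatches over 100 aligned columns -> 97
  a <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  b <- a
  substr(b, 1, 1) <- "W"; substr(b, 50, 50) <- "W"; substr(b, 99, 99) <- "W"
  expect_equal(unname(pair_identity_coverage(a, b)[["identity"]]), 97)
  expect_error(pair_identity_coverage("", p), "empty")
})
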