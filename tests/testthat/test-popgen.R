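# Variant filtering, effect classification, burden, pi, Tajima's D.

test_that("MAF filter keeps the boundary and drops triallelic sites", {
  # 10 diploid samples = 20 alleles; site 1 has exactly 1 alt (MAF 0.05)
  gt1 <- c("0|1", rep("0|0", 9))
  gt2 <- rep("0|0", 10)                      # monomorphic, MAF 0
  gt3 <- c(rep("0|1", 5), rep("0|0", 5))     # MAF 0.25
  sites <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                          ref = "A", alt = c("T", "T", "T", "T,G"),
                          is_snp = c(TRUE, TRUE, TRUE, FALSE),
                          indel_length = 0L)
  gt <- rbind(gt1, gt2, gt3, gt3)
  colnames(gt) <- sprintf("s%02d", 1:10)
  vs <- rgenevol:::new_variant_set(sites, gt)
  kept <- filter_sites(vs, maf_min = 0.05)
  expect_equal(kept$sites$pos, c(10L, 30L))  # boundary kept, triallelic out
  # literal low-frequency reading via maf_max
  rare <- filter_sites(vs, maf_min = 0, maf_max = 0.05)
  expect_equal(rare$sites$pos, c(10L, 20L))
})

test_that("sites with zero called alleles are dropped with a message", {
  sites <- tibble::tibble(chrom = "chr1", pos = 10L, ref = "A", alt = "T",
                          is_snp = TRUE, indel_length = 0L)
  gt <- matrix("./.", 1, 4, dimnames = list(NULL, sprintf("s%d", 1:4)))
  vs <- rgenevol:::new_variant_set(sites, gt)
  expect_message(kept <- filter_sites(vs), "no called alleles")
  expect_equal(nrow(kept$sites), 0L)
})

# One gene: exon1 31-75 (CDS 31-75), intron 76-135, exon2 136-225
# (CDS 136-180, UTR to 225). CDS length 90.
toy_gene_with_cds <- function(strand = "+") {
  gm <- make_gene_table(1, cds_len = 90L, strand = strand)
  cds <- random_sense_cds(30)
  list(gm = gm, cds = stats::setNames(cds, gm$transcript_id))
}

vs_single <- function(pos, ref, alt, gm) {
  is_snp <- nchar(ref) == 1 & nchar(alt) == 1
  rgenevol:::new_variant_set(
    tibble::tibble(chrom = gm$chrom[1], pos = as.integer(pos), ref = ref,
                   alt = alt, is_snp = is_snp,
                   indel_length = as.integer(nchar(alt) - nchar(ref))),
    matrix("0|1", length(pos), 2, dimnames = list(NULL, c("s1", "s2"))))
}

test_that("variant regions and splice boundaries classify correctly", {
  set.seed(3)
  fix <- toy_gene_with_cds()
  gm <- fix$gm
  intron_start <- gm$exons[[1]][1, "end"] + 1L
  intron_end <- gm$exons[[1]][2, "start"] - 1L
  vs <- vs_single(c(intron_start + 1L,  # donor +2 -> splice
                    intron_start + 2L,  # intron position 3 -> not splice
                    intron_end,         # acceptor -1 -> splice
                    5L,                 # inside gene span, 5' UTR
                    gm$end + 500L),     # intergenic
                  "A", "T", gm)
  eff <- classify_variants(vs, gm, fix$cds)
  expect_equal(eff$effect[1], "splice")
  expect_true(eff$functional[1])
  expect_equal(eff$effect[2], "non_coding")
  expect_false(eff$functional[2])
  expect_equal(eff$effect[3], "splice")
  expect_equal(eff$region[4], "UTR")
  expect_equal(eff$region[5], "intergenic")
  expect_true(is.na(eff$gene_id[5]))
})

test_that("coding SNPs split into synonymous and non-synonymous", {
  gm <- make_gene_table(1, cds_len = 90L)
  cds <- paste(rep("AAA", 30), collapse = "")  # poly-Lys
  cds_map <- stats::setNames(cds, gm$transcript_id)
  c1s <- gm$cds[[1]][1, "start"]
  # third codon position: AAA -> AAG is Lys -> Lys
  vs <- vs_single(c(c1s + 2L, c1s), c("A", "A"), c("G", "T"), gm)
  eff <- classify_variants(vs, gm, cds_map)
  expect_equal(eff$effect, c("synonymous", "non_synonymous"))
  expect_equal(eff$functional, c(FALSE, TRUE))
})

test_that("minus-strand codons are read in transcript orientation", {
  gm <- make_gene_table(1, cds_len = 90L, strand = "-")
  cds <- paste(rep("AAA", 30), collapse = "")
  cds_map <- stats::setNames(cds, gm$transcript_id)
  # last base of the genomic CDS = first base of the transcript (codon 1
  # position 1); genomic alt C = transcript G -> AAA->GAA (Lys->Glu)
  c2e <- gm$cds[[1]][2, "end"]
  eff1 <- classify_variants(vs_single(c2e, "T", "C", gm), gm, cds_map)
  expect_equal(eff1$effect, "non_synonymous")
  # genomic alt T = transcript A at a third codon position stays Lys
  c1s <- gm$cds[[1]][1, "start"]
  eff2 <- classify_variants(vs_single(c1s, "T", "C", gm), gm, cds_map)
  # first genomic CDS base = transcript position 90 (third position)
  expect_equal(eff2$effect, "synonymous")
})

test_that("coding InDels are functional, frameshift when length % 3 != 0", {
  gm <- make_gene_table(1, cds_len = 90L)
  cds <- stats::setNames(random_sense_cds(30), gm$transcript_id)
  c1s <- gm$cds[[1]][1, "start"]
  vs <- vs_single(c(c1s, c1s + 3L), c("A", "A"), c("AT", "ATTT"), gm)
  eff <- classify_variants(vs, gm, cds)
  expect_equal(eff$effect, c("frameshift_indel", "inframe_indel"))
  expect_true(all(eff$functional))
})

test_that("functional burden reproduces per-set means", {
  effects <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3", NA),
    functional = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  b <- functional_burden(effects, list(all = c("g1", "g2", "g3"),
                                       set1 = "g1"))
  expect_equal(b$summary$n_functional, c(3L, 2L))
  expect_equal(b$summary$per_gene, c("1.00", "2.00"))
  expect_equal(b$per_gene$n_functional[b$per_gene$gene_id == "g3"], 0L)
})

test_that("pi matches the closed form and the pairwise-count oracle", {
  # one site, 4 alleles, p = 0.5 -> h = (4/3)(1 - .25 - .25) = 2/3
  st <- tibble::tibble(n_called = 4L, n_alt = 2L)
  expect_equal(gene_pi(st), (4 / 3) * 0.5, tolerance = 1e-12)
  # fixed sites give no loci
  expect_true(is.na(gene_pi(tibble::tibble(n_called = 4L, n_alt = 0L))))
  set.seed(41)
  for (i in 1:20) {
    hap <- matrix(rbinom(8 * 15, 1, runif(1, 0.1, 0.9)), nrow = 15)
    st <- stats_from_haplotypes(hap)
    expect_equal(gene_pi(st), oracle_pi(hap), tolerance = 1e-12)
  }
})

test_that("Tajima's D agrees with the straight-from-the-formulas oracle", {
  # fully listed 4-haplotype toy gene with 3 segregating sites
  hap <- rbind(c(0, 0, 1, 1),
               c(0, 1, 1, 1),
               c(1, 0, 0, 0))
  st <- stats_from_haplotypes(hap)
  expect_equal(gene_tajimas_d(st), oracle_tajimas_d(hap), tolerance = 1e-12)
  expect_true(is.na(gene_tajimas_d(
    tibble::tibble(n_called = integer(0), n_alt = integer(0)))))
  set.seed(43)
  for (i in 1:20) {
    n_hap <- sample(c(6, 10, 20), 1)
    hap <- matrix(rbinom(n_hap * 12, 1, runif(1, 0.1, 0.9)), nrow = 12)
    st <- stats_from_haplotypes(hap)
    expect_equal(gene_tajimas_d(st), oracle_tajimas_d(hap),
                 tolerance = 1e-12)
  }
})

test_that("Tajima constants satisfy their defining identities", {
  for (n in c(4, 10, 40)) {
    k <- tajima_constants(n)
    expect_equal(k$a1, sum(1 / seq_len(n - 1)))
    expect_equal(k$e1, k$c1 / k$a1)
    expect_equal(k$e2, k$c2 / (k$a1^2 + k$a2))
  }
})

test_that("diversity statistics are invariant to accession order", {
  set.seed(47)
  gm <- make_gene_table(3)
  cds <- stats::setNames(vapply(1:3, function(i) random_sense_cds(30),
                                character(1)), gm$transcript_id)
  cfg <- simulation_config(seed = 47, pop_n_accessions = 8)
  pop <- simulate_population(cfg, gm, cds)
  vs <- pop$vs
  perm <- sample(ncol(vs$gt))
  vs2 <- rgenevol:::new_variant_set(vs$sites, vs$gt[, perm, drop = FALSE])
  d1 <- gene_diversity(vs, gm)
  d2 <- gene_diversity(vs2, gm)
  expect_equal(d1$pi, d2$pi)
  expect_equal(d1$tajimas_d, d2$tajimas_d)
  expect_equal(d1$S, d2$S)
})
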