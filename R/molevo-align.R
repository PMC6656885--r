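# Protein-guided codon alignment and pairwise identity/coverage.

#' Globally align two proteins (free end gaps)
#'
#' BLOSUM62 with affine gaps (open 11, extend 1) via
#' [Biostrings::pairwiseAlignment()]; "overlap" type leaves terminal gaps
#' free. Any aligner producing two gapped strings can substitute.
#'
#' @param protein_a,protein_b amino-acid strings.
#' @return character vector of the two aligned (gapped) strings.
#' @export
align_proteins <- function(protein_a, protein_b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    substitutionMatrix = get("BLOSUM62"), gapOpening = 11, gapExtension = 1,
    type = "overlap")
  c(as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Each aligned amino-acid column becomes the corresponding codon of its
#' CDS; protein gaps become `"---"` codons. CDS lengths must equal three
#' times the ungapped protein lengths (strip terminal stop codons first);
#' internal stop codons are an error naming the codon position.
#'
#' @param cds_a,cds_b unaligned CDS strings.
#' @param protein_aln optional character vector of two aligned protein
#'   strings; computed with [align_proteins()] when omitted.
#' @param ids sequence ids for the result.
#' @return a `codon_alignment`: list with `ids` and `codons`, a 2 x ncol
#'   character matrix of codons ("---" for gaps).
#' @export
codon_align <- function(cds_a, cds_b, protein_aln = NULL,
                        ids = c("seq_a", "seq_b")) {
  prot_a <- translate_cds(cds_a, ids[1L])
  prot_b <- translate_cds(cds_b, ids[2L])
  # drop a trailing stop codon if present
  strip <- function(cds, prot) substr(cds, 1L, 3L * nchar(prot))
  cds_a <- strip(cds_a, prot_a); cds_b <- strip(cds_b, prot_b)
  if (is.null(protein_aln)) protein_aln <- align_proteins(prot_a, prot_b)
  row_codons <- function(aln_row, cds, prot, id) {
    chars <- strsplit(aln_row, "")[[1L]]
    ungapped <- paste(chars[chars != "-"], collapse = "")
    # free-end-gap aligners may clip overhangs: locate the aligned block
    off <- regexpr(ungapped, prot, fixed = TRUE)[1L]
    if (off < 1L) {
      stop("protein alignment row does not match translation of ", id)
    }
    n <- nchar(cds)
    codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
    out <- rep("---", length(chars))
    out[chars != "-"] <- codons[seq(off, length.out = nchar(ungapped))]
    out
  }
  codons <- rbind(row_codons(protein_aln[1L], cds_a, prot_a, ids[1L]),
                  row_codons(protein_aln[2L], cds_b, prot_b, ids[2L]))
  structure(list(ids = ids, codons = codons), class = "codon_alignment")
}

#' Multi-sequence codon alignment from equal-length CDS
#'
#' For sequences evolved without indels (one per genome of a syntenic
#' family) the codon alignment is the side-by-side codon matrix.
#'
#' @param cds named character vector of equal-length CDS strings.
#' @return a `codon_alignment` with one row per sequence.
#' @export
codon_align_ungapped <- function(cds) {
  stopifnot(length(unique(nchar(cds))) == 1L, nchar(cds[1L]) %% 3L == 0L)
  n <- nchar(cds[1L])
  codons <- t(vapply(cds, function(s) {
    substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  }, character(n / 3L)))
  structure(list(ids = names(cds), codons = codons),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$ids), "sequences x",
      ncol(x$codons), "codons\n")
  invisible(x)
}

#' Pairwise protein identity and coverage
#'
#' Identity is matches over aligned columns (columns where both sequences
#' have a residue), as a percentage; coverage is the aligned span of the
#' query over its full length.
#'
#' @param protein_a query protein string.
#' @param protein_b subject protein string.
#' @return named numeric vector c(identity, coverage), both percentages.
#' @export
pair_identity_coverage <- function(protein_a, protein_b) {
  if (nchar(protein_a) == 0L || nchar(protein_b) == 0L) {
    stop("empty sequence")
  }
  aln <- align_proteins(protein_a, protein_b)
  a <- strsplit(aln[1L], "")[[1L]]
  b <- strsplit(aln[2L], "")[[1L]]
  both <- a != "-" & b != "-"
  identity <- if (any(both)) 100 * sum(a[both] == b[both]) / sum(both) else 0
  # aligned span of the query: residues of a inside the aligned region
  q_res <- which(a != "-")
  span <- sum(a[min(which(both)):max(which(both))] != "-")
  coverage <- 100 * span / nchar(protein_a)
  c(identity = identity, coverage = coverage)
}
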