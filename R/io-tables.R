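# Tabular inputs: BLAST outfmt 6, domain annotations, VCF, TSV reports.

#' Read BLAST tabular (outfmt 6) homology hits
#'
#' Reads the standard 12 columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), drops self-hits and
#' hits with `evalue > max_evalue`. Query coverage is computed from
#' `query_lengths` when provided, else left `NA`.
#'
#' @param path path to a 12-column BLAST tabular file.
#' @param max_evalue keep hits with evalue at or below this (default `Inf`).
#' @param query_lengths optional named integer vector of query sequence
#'   lengths used to compute `q_cov_pct`.
#' @return tibble with columns query_id, subject_id, identity_pct,
#'   aln_length, evalue, bitscore, q_cov_pct.
#' @export
read_blast_tab <- function(path, max_evalue = Inf, query_lengths = NULL) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) > 0L && any(nf != 12L)) {
    stop("line ", which(nf != 12L)[1L], " of ", path,
         " has ", nf[nf != 12L][1L], " columns; expected 12 (outfmt 6)")
  }
  cols <- c("query_id", "subject_id", "identity_pct", "aln_length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  if (length(nf) == 0L) {
    hits <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = 12)), cols)
    hits$query_id <- character(0); hits$subject_id <- character(0)
  } else {
    hits <- utils::read.table(path, sep = "\t", quote = "",
                              col.names = cols,
                              colClasses = c("character", "character",
                                             rep("numeric", 10)))
  }
  hits <- hits[hits$query_id != hits$subject_id & hits$evalue <= max_evalue, ,
               drop = FALSE]
  qcov <- rep(NA_real_, nrow(hits))
  if (!is.null(query_lengths)) {
    ql <- unname(query_lengths[hits$query_id])
    qcov <- 100 * (abs(hits$qend - hits$qstart) + 1) / ql
  }
  tibble::tibble(
    query_id = hits$query_id, subject_id = hits$subject_id,
    identity_pct = hits$identity_pct, aln_length = as.integer(hits$aln_length),
    evalue = hits$evalue, bitscore = hits$bitscore, q_cov_pct = qcov
  )
}

#' Default domain-name alias map
#'
#' Loads the YAML alias map shipped with the package (e.g. NB-ARC -> NBS,
#' LRR_1/LRR_4/LRR_8 -> LRR, PF01582/TIR -> TIR). Users can supply their own
#' map of the same shape to [read_domains()].
#'
#' @return named character vector: raw name -> normalized name.
#' @export
default_domain_aliases <- function() {
  path <- system.file("extdata", "domain_aliases.yaml", package = "rgenevol")
  m <- yaml::read_yaml(path)
  unlist(m)
}

#' Read protein domain annotations
#'
#' Unifies three tabular dialects into one annotation stream:
#' \describe{
#'   \item{pfam_scan}{default `pfam_scan.pl` text output (15 whitespace
#'     columns; envelope coords in columns 4-5, HMM name in column 7).}
#'   \item{domtblout}{HMMER3 `hmmsearch --domtblout` (target sequence in
#'     column 1, query HMM in column 4, envelope coords in columns 20-21).}
#'   \item{ncoils_tsv}{a 3-column TSV `protein_id start end` of coiled-coil
#'     segments, all labeled CC.}
#' }
#' Domain names are normalized through `aliases`; unmapped names are kept
#' verbatim (with a message).
#'
#' @param path annotation file.
#' @param dialect one of `"pfam_scan"`, `"domtblout"`, `"ncoils_tsv"`.
#' @param aliases named character vector mapping raw names to normalized
#'   names; defaults to [default_domain_aliases()].
#' @return tibble protein_id, domain_name, env_start, env_end, evalue, source.
#' @export
read_domains <- function(path, dialect, aliases = default_domain_aliases()) {
  dialect <- match.arg(dialect, c("pfam_scan", "domtblout", "ncoils_tsv"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(protein_id = character(0), domain_name = character(0),
                          env_start = integer(0), env_end = integer(0),
                          evalue = numeric(0), source = character(0)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  grab <- function(k) vapply(fields, `[[`, character(1), k)
  if (dialect == "pfam_scan") {
    ann <- tibble::tibble(protein_id = grab(1), domain_name = grab(7),
                          env_start = as.integer(grab(4)),
                          env_end = as.integer(grab(5)),
                          evalue = as.numeric(grab(13)))
  } else if (dialect == "domtblout") {
    ann <- tibble::tibble(protein_id = grab(1), domain_name = grab(4),
                          env_start = as.integer(grab(20)),
                          env_end = as.integer(grab(21)),
                          evalue = as.numeric(grab(13)))
  } else {
    ann <- tibble::tibble(protein_id = grab(1), domain_name = "CC",
                          env_start = as.integer(grab(2)),
                          env_end = as.integer(grab(3)),
                          evalue = NA_real_)
  }
  mapped <- aliases[ann$domain_name]
  unmapped <- is.na(mapped)
  if (any(unmapped)) {
    message(sum(unmapped), " domain name(s) not in alias map; kept verbatim: ",
            paste(unique(ann$domain_name[unmapped]), collapse = ", "))
  }
  ann$domain_name <- unname(ifelse(unmapped, ann$domain_name, mapped))
  ann$source <- dialect
  ann
}

#' Read a VCF into a variant set
#'
#' Thin wrapper over [vcfR::read.vcfR()] producing the site table and
#' genotype matrix the population-genetics functions consume. Missing
#' genotypes (`./.`) stay missing; they are never recoded as reference.
#'
#' @param path VCF 4.x file (plain text or gzipped) with GT fields.
#' @return a `variant_set`: list with `sites` (tibble chrom, pos, ref, alt,
#'   is_snp, indel_length) and `gt` (character matrix, sites x samples, of
#'   GT strings like `"0|1"` or `"./."`).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0L || !"FORMAT" %in% colnames(v@gt)) {
    stop("VCF ", path, " has no genotype (GT) data")
  }
  fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  if (!all(vapply(fmt, function(f) "GT" %in% f, logical(1)))) {
    stop("VCF ", path, " records lack a GT field")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[is.na(gt)] <- "./."
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  indel_len <- ifelse(is_snp, 0L, nchar(alt) - nchar(ref))
  new_variant_set(
    tibble::tibble(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                   ref = ref, alt = alt, is_snp = is_snp,
                   indel_length = as.integer(indel_len)),
    matrix(gt, nrow = nrow(fix),
           dimnames = list(NULL, colnames(gt)))
  )
}

new_variant_set <- function(sites, gt) {
  stopifnot(nrow(sites) == nrow(gt))
  structure(list(sites = sites, gt = gt), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$sites), "sites x", ncol(x$gt), "samples\n")
  invisible(x)
}

#' Write a tree in Newick format
#'
#' Branch lengths are kept at full precision; integer bootstrap supports, if
#' present as node labels, are written on internal nodes.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a report table as UTF-8 TSV with a header row
#' @param table data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV report written by [write_report_tsv()]
#' @param path TSV file.
#' @return tibble.
#' @export
read_report_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      quote = "", comment.char = "",
                                      stringsAsFactors = FALSE))
}
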