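# GFF3 gene-model I/O.
#
# Gene models are held in a tibble ("gene_table") with one row per gene and
# the primary transcript's structure in list columns:
#   gene_id, chrom, start, end (1-based inclusive, as in GFF3), strand,
#   transcript_id, ordinal (0-based rank by start within its chromosome),
#   exons (list of n x 2 integer matrices, genomic order),
#   cds   (list of n x 3 integer matrices: start, end, phase).

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features and reduces each gene to its primary
#' transcript, defined as the transcript with the longest total CDS (ties
#' broken by lexicographically smallest transcript id). Ordinals (0-based
#' rank of each gene by start coordinate within its chromosome, ties broken
#' by gene id) are assigned on read and are invariant to record order in the
#' file.
#'
#' An mRNA without a `Parent` gene gets a synthesized gene container (with a
#' message); a gene without any CDS is kept with empty `cds` and a warning.
#'
#' @param path path to a GFF3 file.
#' @return a gene_table tibble (see file header for columns).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    stop("malformed GFF3 line ", body[which(nfield != 9L)[1L]], " in ", path,
         ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$ID <- as.character(df$ID)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))
  df$type <- as.character(df$type)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (!"phase" %in% names(df)) df$phase <- NA_integer_

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  # orphan transcripts: synthesize a gene container
  orphan <- is.na(mrnas$Parent) | !(mrnas$Parent %in% genes$ID)
  if (any(orphan)) {
    message(sum(orphan), " transcript(s) without a Parent gene; gene containers synthesized")
    synth <- mrnas[orphan, , drop = FALSE]
    mrnas$Parent[orphan] <- paste0("gene:", synth$ID)
    synth$Parent <- NA_character_
    synth$ID <- paste0("gene:", synth$ID)
    synth$type <- "gene"
    genes <- rbind(genes, synth)
  }

  exons <- df[df$type == "exon", , drop = FALSE]
  cdss <- df[df$type == "CDS", , drop = FALSE]
  seg_mat <- function(sub, with_phase = FALSE) {
    o <- order(sub$start)
    m <- cbind(start = sub$start[o], end = sub$end[o])
    if (with_phase) {
      ph <- suppressWarnings(as.integer(as.character(sub$phase[o])))
      ph[is.na(ph)] <- 0L
      m <- cbind(m, phase = ph)
    }
    storage.mode(m) <- "integer"
    m
  }

  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tx <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == g$ID, , drop = FALSE]
    if (nrow(tx) == 0L) {
      # gene used directly as the feature carrying exons/CDS
      tx <- g
      tx$Parent <- NA_character_
    }
    tx_cds_len <- vapply(tx$ID, function(tid) {
      sub <- cdss[!is.na(cdss$Parent) & cdss$Parent == tid, , drop = FALSE]
      if (nrow(sub) == 0L) 0L else sum(sub$end - sub$start + 1L)
    }, integer(1))
    ord <- order(-tx_cds_len, tx$ID)
    primary <- tx[ord[1L], ]
    ex <- exons[!is.na(exons$Parent) & exons$Parent == primary$ID, , drop = FALSE]
    cd <- cdss[!is.na(cdss$Parent) & cdss$Parent == primary$ID, , drop = FALSE]
    if (nrow(cd) == 0L) {
      warning("gene ", g$ID, " has no CDS; kept with empty cds_segments", call. = FALSE)
    }
    tibble::tibble(
      gene_id = g$ID, chrom = g$seqnames,
      start = as.integer(g$start), end = as.integer(g$end),
      strand = g$strand, transcript_id = primary$ID,
      exons = list(seg_mat(ex)), cds = list(seg_mat(cd, with_phase = TRUE))
    )
  })
  out <- do.call(rbind, rows)
  recompute_ordinals(out)
}

#' Recompute per-chromosome gene ordinals
#'
#' Ordinals are the 0-based rank of a gene by start coordinate on its
#' chromosome (ties by gene id), a bijection onto 0..n-1 per chromosome.
#'
#' @param genes a gene_table.
#' @return the gene_table sorted by (chrom, start, gene_id) with a fresh
#'   `ordinal` column.
#' @export
recompute_ordinals <- function(genes) {
  o <- order(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  genes$ordinal <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                              FUN = function(i) seq_along(i) - 1L)
  genes$ordinal <- as.integer(genes$ordinal)
  genes
}

#' Total CDS length (bp) per gene
#' @param genes a gene_table.
#' @return integer vector named by gene_id.
#' @export
cds_length <- function(genes) {
  stats::setNames(vapply(genes$cds, function(m) {
    if (is.null(m) || nrow(m) == 0L) 0L else sum(m[, 2L] - m[, 1L] + 1L)
  }, integer(1)), genes$gene_id)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features with ID/Parent attributes in the
#' dialect [read_gff3()] consumes, so write-then-read round-trips the table.
#'
#' @param genes a gene_table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ln <- function(type, s, e, phase, attrs) {
      sprintf("%s\trgenevol\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$chrom, type, s, e, g$strand, phase, attrs)
    }
    out <- c(
      ln("gene", g$start, g$end, ".", sprintf("ID=%s", g$gene_id)),
      ln("mRNA", g$start, g$end, ".",
         sprintf("ID=%s;Parent=%s", g$transcript_id, g$gene_id))
    )
    ex <- g$exons[[1L]]
    for (j in seq_len(nrow(ex))) {
      out <- c(out, ln("exon", ex[j, 1L], ex[j, 2L], ".",
                       sprintf("ID=%s.exon%d;Parent=%s", g$transcript_id, j,
                               g$transcript_id)))
    }
    cd <- g$cds[[1L]]
    if (!is.null(cd) && nrow(cd) > 0L) {
      for (j in seq_len(nrow(cd))) {
        out <- c(out, ln("CDS", cd[j, 1L], cd[j, 2L], as.character(cd[j, 3L]),
                         sprintf("ID=%s.cds;Parent=%s", g$transcript_id,
                                 g$transcript_id)))
      }
    }
    writeLines(out, con)
  }
  invisible(path)
}
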