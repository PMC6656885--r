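# Shared small helpers: formatting, genetic code, interval membership.

#' Format a ratio as a percentage with two decimals
#'
#' All report tables print percentages rounded to two decimal places
#' (`sprintf("%.2f")` semantics).
#'
#' @param num numerator count.
#' @param den denominator count (> 0 unless `num` is 0 too, then "0.00").
#' @return character scalar, e.g. `"93.20"`.
#' @export
fmt_pct2 <- function(num, den) {
  if (den == 0) return("0.00")
  sprintf("%.2f", 100 * num / den)
}

#' Format a ratio with two decimals
#' @param num numerator.
#' @param den denominator.
#' @return character scalar, e.g. `"2.29"`.
#' @export
fmt_ratio2 <- function(num, den) {
  if (den == 0) return("0.00")
  sprintf("%.2f", num / den)
}

# Standard genetic code keyed by DNA codon; "*" marks stops.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

# The 61 sense codons.
sense_codons <- function() {
  gc <- codon_table()
  names(gc)[gc != "*"]
}

translate_codon <- function(codon, gc = codon_table()) {
  aa <- gc[codon]
  ifelse(is.na(aa), "X", aa)
}

# Translate an unaligned CDS string; errors on internal stops.
translate_cds <- function(cds, id = "sequence") {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length of ", id, " is not a multiple of 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- translate_codon(codons)
  stops <- which(aa == "*")
  if (length(stops) > 0L && any(stops < length(codons))) {
    stop("internal stop codon in ", id, " at codon ", stops[stops < length(codons)][1L])
  }
  paste(aa[aa != "*"], collapse = "")
}

comp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}

revcomp <- function(s) {
  paste(rev(unname(comp_base(strsplit(s, "")[[1L]]))), collapse = "")
}

# TRUE when pos falls in any [start,end] row of a 2+ column matrix.
in_intervals <- function(pos, ivs) {
  if (is.null(ivs) || nrow(ivs) == 0L) return(FALSE)
  any(pos >= ivs[, 1L] & pos <= ivs[, 2L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

modal_value <- function(x) {
  tx <- table(x)
  as.numeric(names(tx)[which.max(tx)])
}
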