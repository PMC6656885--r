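# Nei-Gojobori (1986) Ka/Ks on pairwise codon alignments.
#
# Site counting: each codon position contributes one site, split into a
# synonymous fraction s = (# synonymous single-base changes) / (# single-
# base changes not creating a stop) and a nonsynonymous fraction 1 - s, so
# N + S = 3 x (codons compared) always. Mutations to stop codons are
# excluded from numerator and denominator alike. Site totals are averaged
# over the two sequences.
#
# Difference counting: codons differing at k positions are resolved by
# averaging synonymous/nonsynonymous step counts over all k! orderings of
# the positions; orderings passing through a stop codon are excluded (if
# every ordering is blocked, the average falls back to all orderings).
#
# Proportions are Jukes-Cantor corrected: d = -(3/4) ln(1 - (4/3) p);
# p >= 3/4 flags the comparison saturated.

# Cache of per-codon synonymous site fractions.
ng_sites_env <- new.env(parent = emptyenv())

# Synonymous site count (0..3) of one codon.
ng_syn_sites <- function(codon) {
  if (is.null(ng_sites_env$tab)) {
    gc <- codon_table()
    bases <- c("A", "C", "G", "T")
    tab <- vapply(sense_codons(), function(cd) {
      ch <- strsplit(cd, "")[[1L]]
      total <- 0
      for (p in 1:3) {
        syn <- 0L; ok <- 0L
        for (b in setdiff(bases, ch[p])) {
          mut <- ch; mut[p] <- b
          aa <- gc[paste(mut, collapse = "")]
          if (aa == "*") next
          ok <- ok + 1L
          if (aa == gc[cd]) syn <- syn + 1L
        }
        if (ok > 0L) total <- total + syn / ok
      }
      total
    }, numeric(1))
    ng_sites_env$tab <- tab
  }
  ng_sites_env$tab[[codon]]
}

# Pathway-averaged (syn, nonsyn) differences between two codons.
ng_codon_diffs <- function(c1, c2, gc = codon_table()) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  a <- strsplit(c1, "")[[1L]]
  b <- strsplit(c2, "")[[1L]]
  pos <- which(a != b)
  paths <- if (length(pos) == 1L) list(pos) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(p) c(v[i], p))
      }))
    }
    perms(pos)
  }
  walk <- function(path) {
    cur <- a; sd <- 0L; nd <- 0L
    for (p in path) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- gc[paste(cur, collapse = "")]
      aa2 <- gc[paste(nxt, collapse = "")]
      if (aa2 == "*" || aa1 == "*") return(NULL)
      if (aa1 == aa2) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, walk))
  if (length(res) == 0L) {
    # all pathways pass through a stop: average without the exclusion
    walk_any <- function(path) {
      cur <- a; sd <- 0L; nd <- 0L
      for (p in path) {
        nxt <- cur; nxt[p] <- b[p]
        if (gc[paste(cur, collapse = "")] ==
            gc[paste(nxt, collapse = "")]) sd <- sd + 1L else nd <- nd + 1L
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    res <- lapply(paths, walk_any)
  }
  colMeans(do.call(rbind, res))
}

#' Nei-Gojobori Ka and Ks for a pairwise codon alignment
#'
#' Columns containing a gap or an ambiguous base are skipped (pairwise
#' deletion). `ratio` is `NA` when Ks is 0 or either proportion is
#' saturated (p >= 3/4); the `saturated` flag marks the latter.
#'
#' @param alignment a two-sequence `codon_alignment` from [codon_align()].
#' @return one-row tibble: gene_a, gene_b, Ka, Ks, ratio, N_sites, S_sites,
#'   Nd, Sd, n_codons, saturated.
#' @export
nei_gojobori <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"),
            nrow(alignment$codons) == 2L)
  ca <- alignment$codons[1L, ]
  cb <- alignment$codons[2L, ]
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  gc <- codon_table()
  # skip stop codons (terminal or artifactual)
  clean <- clean & gc[ca] != "*" & gc[cb] != "*"
  ca <- ca[clean]; cb <- cb[clean]
  n_codons <- length(ca)
  if (n_codons == 0L) stop("no comparable codon columns")
  s_a <- sum(vapply(ca, ng_syn_sites, numeric(1)))
  s_b <- sum(vapply(cb, ng_syn_sites, numeric(1)))
  S <- (s_a + s_b) / 2
  N <- 3 * n_codons - S
  diffs <- vapply(seq_len(n_codons), function(i) {
    ng_codon_diffs(ca[i], cb[i], gc)
  }, numeric(2))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(ps); Ka <- jc(pn)
  saturated <- is.na(Ks) || is.na(Ka)
  ratio <- if (saturated || Ks == 0) NA_real_ else Ka / Ks
  tibble::tibble(gene_a = alignment$ids[1L], gene_b = alignment$ids[2L],
                 Ka = Ka, Ks = Ks, ratio = ratio, N_sites = N, S_sites = S,
                 Nd = Nd, Sd = Sd, n_codons = n_codons,
                 saturated = saturated)
}

#' Ka/Ks for many CDS pairs
#'
#' Convenience wrapper: protein-aligns, back-translates and runs
#' [nei_gojobori()] for each row of `pair_table`.
#'
#' @param pair_table tibble/data.frame with columns gene_a, gene_b.
#' @param cds named character vector of CDS strings covering all ids.
#' @return tibble of [nei_gojobori()] rows.
#' @export
kaks_pairs <- function(pair_table, cds) {
  rows <- lapply(seq_len(nrow(pair_table)), function(i) {
    a <- pair_table$gene_a[i]; b <- pair_table$gene_b[i]
    ca <- codon_align(cds[[a]], cds[[b]], ids = c(a, b))
    nei_gojobori(ca)
  })
  do.call(rbind, rows)
}
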