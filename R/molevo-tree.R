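# Synonymous-locus extraction, distances, Saitou-Nei neighbor joining, and
# column-resampling bootstrap support.

#' Extract synonymous ("Ks") nucleotide columns from a codon alignment
#'
#' Keeps nucleotide columns that (a) belong to a codon column with no gap
#' or ambiguity in any sequence, (b) vary in at least one sequence, and
#' (c) sit in a codon column whose observed codon variants all translate
#' to the same amino acid. Concatenating such columns across families gives
#' a near-neutral signal for species-tree building.
#'
#' @param alignment a multi-sequence `codon_alignment`.
#' @return character matrix (sequences x kept nucleotide columns), possibly
#'   with zero columns; rownames are sequence ids.
#' @export
extract_ks_loci <- function(alignment) {
  codons <- alignment$codons
  gc <- codon_table()
  keep_cols <- list()
  for (j in seq_len(ncol(codons))) {
    col <- codons[, j]
    if (!all(grepl("^[ACGT]{3}$", col))) next
    aas <- gc[col]
    if (any(aas == "*") || length(unique(aas)) != 1L) next
    m <- do.call(rbind, strsplit(col, ""))
    for (p in 1:3) {
      if (length(unique(m[, p])) > 1L) {
        keep_cols[[length(keep_cols) + 1L]] <- m[, p]
      }
    }
  }
  out <- if (length(keep_cols) == 0L) {
    matrix(character(0), nrow = length(alignment$ids), ncol = 0L)
  } else do.call(cbind, keep_cols)
  rownames(out) <- alignment$ids
  out
}

#' Normalized Hamming distance matrix from aligned columns
#' @param columns character matrix (sequences x columns).
#' @return symmetric numeric matrix of mismatch proportions.
#' @export
hamming_distance <- function(columns) {
  n <- nrow(columns)
  d <- matrix(0, n, n, dimnames = list(rownames(columns), rownames(columns)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      p <- mean(columns[i, ] != columns[j, ])
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Jukes-Cantor corrected distance matrix from aligned columns
#' @param columns character matrix (sequences x columns).
#' @return symmetric numeric matrix; mismatch proportions p are corrected
#'   as -(3/4) log(1 - 4p/3).
#' @export
jc_distance <- function(columns) {
  p <- hamming_distance(columns)
  if (any(p >= 0.75)) stop("saturated distance (p >= 3/4); JC undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Saitou-Nei neighbor-joining tree
#'
#' Classic NJ on a symmetric distance matrix. Ties on the minimal Q value
#' are broken by (i, j) index order. A negative branch length is clamped to
#' zero with the excess moved to its sister edge (their sum, the joined
#' distance contribution, is preserved). The root is the conventional
#' trifurcation, so an additive matrix is reproduced exactly as a tree
#' metric.
#'
#' @param distances symmetric numeric matrix with zero diagonal and
#'   rownames, or a `dist` object; at least 3 taxa.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(distances) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  stopifnot(isTRUE(all.equal(d, t(d))), all(diag(d) == 0))
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  # each active node is a list(children = list(list(node, length)) | leaf)
  nodes <- lapply(labels, function(l) list(leaf = l))
  while (length(nodes) > 2L) {
    r <- length(nodes)
    R <- rowSums(d)
    best <- NULL; best_q <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in seq(i + 1L, r)) {
        q <- (r - 2) * d[i, j] - R[i] - R[j]
        if (q < best_q - 1e-12) { best_q <- q; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- d[i, j]; li <- 0 }
    if (lj < 0) { li <- d[i, j]; lj <- 0 }
    new_node <- list(children = list(list(node = nodes[[i]], length = li),
                                     list(node = nodes[[j]], length = lj)))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], list(new_node))
    d <- d2
  }
  # join the last two nodes: hang one on the other's root (trifurcation)
  a <- nodes[[1L]]; b <- nodes[[2L]]; dab <- d[1L, 2L]
  root <- if (!is.null(b$children)) {
    list(children = c(b$children, list(list(node = a, length = dab))))
  } else if (!is.null(a$children)) {
    list(children = c(a$children, list(list(node = b, length = dab))))
  } else stop("neighbor joining needs at least 3 taxa")
  to_newick <- function(node) {
    if (!is.null(node$leaf)) return(node$leaf)
    inner <- vapply(node$children, function(ch) {
      sprintf("%s:%.12g", to_newick(ch$node), ch$length)
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(to_newick(root), ";"))
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with [nj_tree()] on `dist_fun` distances, and labels each
#' internal bipartition of the point-estimate tree with the percentage of
#' replicates containing it. Deterministic given `seed`.
#'
#' @param columns character matrix (sequences x columns).
#' @param n_reps number of replicates (>= 1).
#' @param seed integer RNG seed.
#' @param dist_fun distance function on a column matrix (default
#'   [hamming_distance()]).
#' @return the point-estimate [ape::phylo] tree with integer percentage
#'   supports in `node.label`.
#' @export
bootstrap_support <- function(columns, n_reps = 100L, seed = 1L,
                              dist_fun = hamming_distance) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  point <- nj_tree(dist_fun(columns))
  set.seed(seed)
  reps <- lapply(seq_len(n_reps), function(i) {
    idx <- sample.int(ncol(columns), replace = TRUE)
    nj_tree(dist_fun(columns[, idx, drop = FALSE]))
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- n_reps  # trivial (root) partition
  point$node.label <- as.character(as.integer(round(100 * counts / n_reps)))
  point
}

#' Concatenate Ks-locus columns across syntenic families and build the
#' species tree
#'
#' @param alignments list of multi-sequence `codon_alignment`s sharing the
#'   same ordered sequence ids (one per genome).
#' @param n_boot bootstrap replicates (0 skips support labels).
#' @param seed RNG seed for the bootstrap.
#' @return list with `tree` ([ape::phylo], JC distances), `n_columns`
#'   concatenated, and `columns` (the matrix).
#' @export
species_tree_from_ks <- function(alignments, n_boot = 100L, seed = 1L) {
  ids <- alignments[[1L]]$ids
  cols <- lapply(alignments, function(a) {
    stopifnot(identical(a$ids, ids))
    extract_ks_loci(a)
  })
  columns <- do.call(cbind, cols)
  if (ncol(columns) == 0L) stop("no synonymous variant columns found")
  tree <- if (n_boot > 0L) {
    bootstrap_support(columns, n_reps = n_boot, seed = seed,
                      dist_fun = jc_distance)
  } else {
    nj_tree(jc_distance(columns))
  }
  list(tree = tree, n_columns = ncol(columns), columns = columns)
}
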