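# Independent oracle implementations. These deliberately use a different
# algorithmic route than the package (exhaustive enumeration / brute-force
# pairwise counting) and exist only to cross-check results.

# --- Nei-Gojobori differences: exhaustive mutation-path enumeration ------
# Enumerates every step-by-step path between two codons by recursively
# applying one remaining differing position at a time, tracking the actual
# intermediate codon; paths visiting a stop are discarded (all-blocked
# falls back to including them).
oracle_ng_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  paths <- list()
  recurse <- function(cur, remaining, sd, nd, through_stop) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- c(sd = sd, nd = nd,
                                       blocked = as.numeric(through_stop))
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- gc[paste(cur, collapse = "")]
      aa2 <- gc[paste(nxt, collapse = "")]
      recurse(nxt, setdiff(remaining, p),
              sd + as.numeric(aa1 == aa2),
              nd + as.numeric(aa1 != aa2),
              through_stop || aa2 == "*" || aa1 == "*")
    }
  }
  if (identical(a, b)) return(c(sd = 0, nd = 0))
  recurse(a, which(a != b), 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, "blocked"] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

# --- brute-force per-gene pi: explicit average over haplotype pairs ------
# hap: sites x haplotypes 0/1 matrix (NA = missing). Per site, the mean
# difference over all called pairs; pi is the mean over sites.
oracle_pi <- function(hap) {
  per_site <- apply(hap, 1, function(row) {
    row <- row[!is.na(row)]
    n <- length(row)
    if (n < 4 || length(unique(row)) < 2) return(NA_real_)
    diffs <- 0; pairs <- 0
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        diffs <- diffs + as.numeric(row[i] != row[j])
        pairs <- pairs + 1
      }
    }
    diffs / pairs
  })
  per_site <- per_site[!is.na(per_site)]
  if (length(per_site) == 0) return(NA_real_)
  mean(per_site)
}

# --- brute-force Tajima's D straight from the 1989 formulas --------------
oracle_tajimas_d <- function(hap) {
  seg <- apply(hap, 1, function(row) {
    row <- row[!is.na(row)]
    length(row) >= 4 && length(unique(row)) == 2
  })
  hap <- hap[seg, , drop = FALSE]
  S <- nrow(hap)
  if (S == 0) return(NA_real_)
  n <- ncol(hap)
  # mean pairwise difference count over all haplotype pairs, whole gene
  k_sum <- 0; n_pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      k_sum <- k_sum + sum(hap[, i] != hap[, j], na.rm = TRUE)
      n_pairs <- n_pairs + 1
    }
  }
  Pi <- k_sum / n_pairs * n_pairs / choose(n, 2)  # = k_sum / C(n,2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (Pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- textbook 2x2 chi-square (independent formula route) ----------------
oracle_chi2_2x2 <- function(tab, yates = TRUE) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- max(num - N / 2, 0)
  chi2 <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
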