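# rgenevol

Comparative and population genomics of plant **NBS resistance (R) genes**, as
a tested, reusable R pipeline. Plant genomes hold hundreds of
disease-resistance genes built around a nucleotide-binding-site (NBS) domain,
and they evolve along two contrasting routes: copies in **tandem-duplication
(TD) arrays** diversify rapidly, while **singletons** are conserved under
purifying selection. `rgenevol` implements every stage needed to quantify
that contrast across related genomes and within a resequenced population:

- **R-gene catalog** — select genes with ≥1 NBS domain from pfam_scan /
  HMMER `--domtblout` / NCOILS annotations and label domain-order subgroups
  (`CC-NBS-LRR`, `NBS-NBS-LRR`, ...; TIR wins the major class, else CC,
  else plain NBS).
- **Tandem arrays** — single-linkage homology clusters (BLASTP E ≤ 1e-2)
  scanned along gene order; consecutive members separated by at most
  `max_gap = 5` intervening genes form one array; an **R locus** is an
  array's representative or a singleton.
- **Synteny** — a homologous pair (E ≤ 1e-20) is a syntenic ortholog when
  the genes flanking both sides (window 10/side) support it through
  reciprocal best hits; families are connected components across genomes.
- **Molecular evolution** — Nei–Gojobori (1986) Ka/Ks on protein-guided
  codon alignments: per-codon synonymous site fractions (stop mutations
  excluded), pathway-averaged differences, Jukes–Cantor correction
  d = −(3/4)·ln(1 − 4p/3); synonymous-column ("Ks locus") extraction,
  concatenation, Saitou–Nei neighbor joining with column-resampling
  bootstrap.
- **Population genetics** — variant effect classes (synonymous /
  non-synonymous / splice within 2 bp of an intron boundary / CDS InDels),
  functional-variant burden, per-variant-locus diversity
  π = mean over sites of n/(n−1)·(1 − p² − q²), and Tajima's D
  = (Π − S/a₁) / √(e₁S + e₂S(S−1)).
- **Synthetic data** — genomes evolved along a species tree with planted
  tandem arrays, syntenic maps, per-class dN/dS, and a Watterson-process
  population simulator with known θ, so every stage is testable offline.

## Worked example

```r
library(rgenevol)
res <- run_pipeline(simulation_config(seed = 5), "pipe_out", n_boot = 50)
res$report
#> # A tibble: 4 x 9
#>   genome n_candidates n_nbs_r nbs_r_pct n_td_arrays n_td_genes td_over_nbs
#> 1 A                18      12 19.05               3          9 0.75
#> 2 B                18      12 19.05               3          9 0.75
#> 3 C                18      12 19.05               3          9 0.75
#> 4 D                18      12 19.05               3          9 0.75
ape::write.tree(res$tree$tree)
#> "(C:0.255...,D:0.305...,(A:0.327...,B:0.328...)100:0.664...)100;"
mean(res$kaks$ratio[res$kaks$kind == "TD"], na.rm = TRUE)        # 0.83
mean(res$kaks$ratio[res$kaks$kind == "singleton"], na.rm = TRUE) # 0.19
```

Each simulated genome carries 12 NBS R genes (of 63 annotated genes,
19.05%), 3 planted tandem arrays holding 9 of them (`td_over_nbs` 0.75),
and 6 R loci. The species tree recovers the generating topology AB|CD with
full bootstrap support, and the Ka/Ks contrast separates the TD class
(simulated at ω = 1.0) from singletons (ω = 0.2). Per-stage outputs
(`genome_summary.tsv`, `families.tsv`, `kaks.tsv`, `diversity.tsv`,
`burden.tsv`, `chi2.tsv`, histogram TSVs, `species_tree.nwk`) land in
`pipe_out/`.

A single statistical contrast, as used for the burden comparison between
232 R singletons (2,734 functional variants) and 303 TD R genes (6,272):

```r
chi2_2x2(matrix(c(232, 2734, 303, 6272), 2, byrow = TRUE))
#> 2x2 chi-square (Yates-corrected)
#>   chi2 = 39.3812  df = 1  p = 3.68e-10
```

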