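---
title: "Methods: models, parameters and design choices in rgenevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in rgenevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rgenevol)
```

`rgenevol` quantifies how plant NBS resistance (R) genes evolve along two
routes — rapid diversification inside tandem-duplication (TD) arrays versus
conservation as singletons — using comparative genomics across related
genomes and population genetics within one resequenced species. This
vignette is the package's own account of each method, the tunable
parameters that matter, the synthetic-data generator behind the test
suite, and the places where the design was genuinely open.

## Coordinates and gene models

All coordinates are 1-based and inclusive throughout, the native
convention of GFF3, VCF and Bioconductor's IRanges/GRanges. Because every
external format and every internal container already agree, there is no
conversion boundary at all — the cheapest way to avoid off-by-one drift in
an R package (a 0-based half-open internal convention would buy nothing
here and cost a conversion at every I/O call).

Each gene is reduced to one **primary transcript**: the isoform with the
longest total CDS, ties broken by lexicographically smallest transcript
id. Annotation sources rarely say which isoform represented a gene in any
given analysis; longest-CDS is the common, deterministic choice and is
applied uniformly on read. A gene's **ordinal** is its 0-based rank by
start coordinate on its chromosome (ties by gene id) — a bijection onto
0..n−1 that is invariant to record order and the unit in which all
gene-gap arithmetic is done.

## R-gene catalog

A gene is an R gene when its protein carries at least one NBS domain
after normalization of raw annotation names through an editable YAML alias
map (`NB-ARC` → NBS, the `LRR_*` family → LRR, `TIR`/`PF01582` → TIR,
NCOILS segments → CC). Coiled-coil and TIR calls are consumed from the
annotation inputs; no predictor is re-implemented.

Domains are sorted by envelope start (ties: longer domain first, then
name). Annotations overlapping a better one by more than half of the
shorter domain's length are dropped, keeping the lower-e-value (then
earlier-start) call; annotation tools frequently emit stacked overlapping
hits for repeat domains and some de-duplication rule is unavoidable. The
**subgroup** label is the plain hyphen-join of the ordered domains with
multiplicity preserved — `NBS-NBS-LRR` is deliberately distinct from
`NBS-LRR`, since repeated-domain architectures are a real and separately
counted class. The **major class** is TIR-NBS when TIR is present
(monocots carry almost none, which the catalog output makes visible),
else CC-NBS when a coiled-coil is, else NBS.

## Tandem arrays and R loci

Homology for tandem detection is deliberately permissive: single-linkage
components of the BLASTP graph at E ≤ 1e-2 (`evalue_max`). Within one
chromosome and one cluster, members are scanned in ordinal order and
joined while consecutive members are separated by at most `max_gap`
intervening genes; runs of ≥2 become arrays. The bound is inclusive —
exactly `max_gap` intervening genes still joins — and defaults to 5.
Every array names a representative (longest CDS, ties by leftmost start),
and the **R loci** of a genome are its R-gene arrays plus its R
singletons. Increasing `max_gap` can only merge runs, so the array count
is non-increasing in it; this monotonicity is property-tested.

## Flanking-gene synteny

Candidate ortholog pairs are BLASTP hits at E ≤ 1e-20. For a pair
(g_A, g_B), up to `window` genes (default 10) on each side of both genes
are collected; a flank position supports the pair when its gene has a
reciprocal best hit (by bitscore, ties by e-value then id) inside the
partner's flank. The **flank ratio** is supported positions over the
smaller available flank, and a pair is syntenic when the ratio reaches
`min_flank_ratio` (default 0.3) and each side is the other's best-ratio
partner. Requiring the selection to be *mutual* makes the output
symmetric in the two genomes by construction, which the tests verify.
Window size, ratio threshold and best-hit reciprocity are conventional
collinearity practice rather than settings dictated by any one source;
on clean fixtures the results are insensitive to them, and all three are
exposed.

Tandem arrays are collapsed to their representative **before** flanking
analysis, so an array counts as one locus and cannot support itself
through its own copies. Families are connected components of the union of
all pairwise syntenic pairs across genomes; loci in no pair become
species-specific families of size one. For ploidy checks,
`synteny_depth()` re-runs the pairwise stage keeping *all* partners above
the ratio threshold (and counting any-hit flank support, since duplicated
copies tie under best-hit reciprocity) and reports the modal number of
distinct partner chromosomes per reference gene: 1 reads diploid-like,
2 tetraploid-like.

## Ka/Ks (Nei–Gojobori 1986)

Codon alignments are back-translations of protein alignments (built-in:
Biostrings global alignment with free end gaps, BLOSUM62, gap open 11 /
extend 1; any aligner producing two gapped strings can be plugged in).
Columns with gaps or ambiguity are skipped pairwise.

Sites: each codon position contributes one site split into a synonymous
fraction s = (synonymous single-base changes)/(changes not creating a
stop) and nonsynonymous 1 − s, so N + S = 3 × codons holds exactly on
every call (an asserted invariant). Mutations to stops are excluded from
numerator and denominator alike — one of the mainstream NG86 conventions.
Differences: codons differing at k positions are averaged over all k!
orderings; orderings that pass through a stop are excluded, and in the
degenerate case where every ordering is blocked the average falls back to
all orderings. Proportions are Jukes–Cantor corrected,
d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 flags the pair saturated. Ka/Ks is
undefined (NA, never infinity) when Ks = 0 or either side saturates, and
such pairs are excluded from ratio histograms with a logged count.
The pathway-averaged (Sd, Nd) are checked against an exhaustive
path-enumeration oracle over all 61×61 sense-codon pairs to 1e-12.

## Synonymous loci and the species tree

A **Ks locus** is a nucleotide column of a multi-genome codon alignment
that (a) sits in a codon column free of gaps and ambiguity in every
sequence, (b) varies in at least one sequence, and (c) belongs to a codon
column whose observed variants all translate to the same amino acid.
Requiring variation follows from treating these as *variant* loci;
invariant columns carry no signal and would only dilute bootstrap
resampling. Columns are concatenated across families and distances are
Jukes–Cantor-corrected mismatch proportions — the simplest standard
distance family, chosen because nothing in the analysis depends on a
richer model.

Neighbor joining is the classic Saitou–Nei agglomeration with two
deterministic choices: ties on the minimal Q value break by (i, j) index
order, and a negative branch length is clamped to zero with the excess
moved to its sister edge so their sum (the joined distance contribution)
is preserved. On any additive matrix NJ reproduces the tree metric
exactly (tested on random additive matrices up to n = 12 and
cross-checked against an independent NJ implementation). Bootstrap
support resamples alignment columns with replacement, rebuilds each
replicate tree, and labels each internal bipartition of the point
estimate with its replicate percentage; everything is deterministic given
the seed.

## Population statistics

Sites are filtered to biallelic loci with minor-allele frequency over
*called* alleles at least `maf_min` (default 0.05, boundary inclusive).
The package also exposes `maf_max` because the opposite reading —
keeping only rare alleles — is occasionally wanted; the default keeps
common polymorphism, the only reading consistent with per-locus
diversities that peak far above zero.

Variant effects follow the region hierarchy CDS > UTR > intron inside a
gene span, else intergenic. Coding SNPs are translated against the
primary transcript's CDS (minus-strand genes are read in transcript
orientation via complementation); intronic positions within 2 bp of
either intron boundary are splice variants; coding InDels are frameshift
when length mod 3 ≠ 0, else inframe. **Functional** means: a
non-synonymous SNP, a splice variant, or *any* coding InDel (inframe
included — the definition follows what alters the final protein, while
the frameshift/inframe split remains reportable through the effect
label). Multi-base variants classify by their leftmost base; overlapping
genes resolve to the first by position.

π is **per variant locus**, not per bp: at each segregating site the
unbiased heterozygosity ĥ = n/(n−1)·(1 − p² − q²) over the n called
alleles, and a gene's π is the mean of ĥ over its variant loci — a
dimensionless 0–1 quantity. Sites with fewer than four called alleles are
dropped. Tajima's D uses Π = Σ ĥ (exactly the mean pairwise difference
count) with the 1989 constants evaluated at the modal per-site n when
sites differ in missingness (logged). S = 0 leaves D undefined (NA). Both
statistics agree with brute-force pairwise-counting oracles to 1e-12 and
are invariant to accession order.

The 2×2 chi-square applies the Yates continuity correction by default
(flag to disable); with 1 degree of freedom the correction is standard,
and it is what reproduces published burden-contrast p-values from their
cell counts. p-values below 2.2e-16 are additionally reported with the
conventional "<2.2e-16" label.

## The synthetic-data generator

Genomes are copies of one ancestral gene order evolved along a Newick
species tree. The defaults define the toy study conditions used
throughout the tests: four genomes on a balanced tree with 0.04/0.02
substitutions-per-site branches, 60 genes per genome on 2 chromosomes,
3 planted tandem arrays of 2–4 copies separated by ≤2 spacer genes, 20%
R genes, ω (dN/dS) of 1.0 for TD R genes vs 0.2 for R singletons vs 0.5
background, 5% species-specific gene insertions, 300-bp CDS per gene,
and a 20-accession population at θ = 0.01/bp. These sizes keep the full
suite comfortably fast while leaving every contrast detectable; the
neutral-calibration runs use 1,000 small genes and 80 replicate
populations for the same reason.

Codon evolution is an ω-thinned Jukes–Cantor scheme: proposed single-base
changes are accepted with probability 1 when synonymous, ω when
nonsynonymous, never when creating a stop. This is deliberately simpler
than a full codon model — it produces the Ka/Ks contrast the analysis
measures without free parameters beyond ω itself. Emitted BLAST e-values
are a deterministic monotone map of realized sequence identity, so the
1e-2 / 1e-20 threshold behavior is reproducible; within-family hits land
far below 1e-2 and cross-genome ortholog hits far below 1e-20.

The population simulator is site-independent (no linkage, no
recombination): per gene, segregating sites arrive as a Poisson draw with
E[S] = a₁·θ·L, derived-allele counts follow P(i) ∝ 1/i^α over
i = 1..n−1, and carriers are sampled uniformly; genotypes are written as
phased haploid pairs. With α = 1 and no density boost this is the
standard neutral frequency spectrum, under which E[Π] = S/a₁ — so
Tajima's D is centred on zero per gene on average, which is exactly what
the calibration tests assert. The selection-contrast scenario raises θ
per class (TD 3×, singleton 1.8×) to reproduce the observed burden
ordering, and tilts the spectrum (α = 0.6 for TD, 1.4 for singletons)
to reproduce the π ordering — a tilt is required because π here is
per-variant-locus and therefore insensitive to site density alone.

What the generator does **not** emulate: recombination and linkage
disequilibrium, selective sweeps, structural variants, gene loss and
translocation, polyploid subgenomes, alignment error, and annotation
noise beyond simple decoy domains. Passing tests therefore demonstrate
the correctness of the algorithms under clean, known-truth conditions —
not robustness of the biological conclusions to the messiness of real
genomes.

## Degenerate inputs and numerical corner cases

- Genes without CDS are kept (warning) with empty CDS structure; orphan
  transcripts get synthesized gene containers (message).
- Sites with zero called alleles are dropped; triallelic sites never pass
  the biallelic filter.
- `chi2_2x2` refuses zero margins; `distribution_export` refuses empty
  input and excludes non-finite values with a count.
- NJ requires n ≥ 3; n = 3 returns the closed-form star.
- JC distances refuse p ≥ 3/4 (saturation) rather than returning NaN.
- Summary tables enforce their internal identities (TD genes + singletons
  = R genes; arrays + singletons = loci) and abort on violation, since a
  violation can only be an upstream bug.

## Known limitations

- The flanking-window parameters are heuristics; very small chromosomes
  (< 2 genes) yield ratios over whatever flank exists.
- Ka/Ks pathway averaging weights all non-stop orderings equally (no
  transition/transversion weighting).
- The species-tree distance ignores rate heterogeneity across sites; for
  deeply diverged genomes a richer model would be preferable.
- Per-variant-locus π is not comparable to per-bp π from other tools
  without rescaling by variant density.
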