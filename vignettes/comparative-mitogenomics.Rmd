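---
title: "Comparative mitogenomics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

# The analysis

`mitocomp` implements the standard comparative workflow for annotated circular
mitochondrial genomes, exercised here on the avian (passerine) system: a
~16–17 kb circular molecule carrying 13 protein-coding genes (PCGs), 22 tRNAs,
2 rRNAs and one non-coding control region (D-loop), with 28 genes on the heavy
strand and 9 (eight tRNAs plus *ND6*) on the light strand in the ancestral
avian arrangement. The stages are:

1. **Structure** — parse gene tables or GenBank flat files, cross-check printed
   lengths against coordinate arithmetic, census strands, verify the cyclic
   gene order.
2. **Codon usage** — split coding sequences into codons under the vertebrate
   mitochondrial code (NCBI table 2), classify start/stop codons including
   truncated stops, count usage and compute RSCU.
3. **Composition** — base composition, AT/GC content, AT-skew
   $(A-T)/(A+T)$ and GC-skew $(G-C)/(G+C)$, per gene and per genome, plus the
   content-vs-skew Pearson correlation across genomes.
4. **Divergence** — nucleotide diversity ($\pi$), variable-site percentages and
   Nei–Gojobori Ka/Ks from per-gene multi-taxon alignments.
5. **Supermatrix** — concatenation with partition files for external tree
   inference.
6. **Simulation** — a generator producing annotated genomes and alignments
   with *known* parameters, so every estimator is validated against ground
   truth.

# Coordinate and strand conventions

Coordinates are 1-based and fully inclusive (the GenBank convention). A
feature with `end < start` wraps the origin; its length is
`(L - start + 1) + end`. No gene in the bundled *Tarsiger* annotations wraps,
but wrap support is implemented and tested because circular genomes need it in
general. Light-strand genes are stored in reference orientation; extraction
returns their reverse complement, i.e. the reading frame. Overlapping genes
(e.g. *ATP8*/*ATP6*) are legal and never de-overlapped.

Skews are measured on the reference (heavy) strand for every row by default,
which keeps per-gene skews comparable regardless of coding strand; a
`"coding"` orientation is available and simply negates light-strand gene
skews. The skew of a reverse complement is the negated skew — an exact
identity the tests enforce.

# Codon-level conventions

Three choices matter and are deliberately explicit:

* **Stop codons and the headline total.** Mitochondrial "total codon" figures
  conventionally equal $\sum_g \lfloor \mathrm{len}_g/3 \rfloor$ over the 13
  PCGs, which includes complete stop triplets and never counts the 1–2 nt
  remnants of truncated stops. `count_codons(include_stops = TRUE)` reproduces
  that (3797 for the bundled annotation). RSCU families and amino-acid usage
  always *exclude* stops, the standard practice.
* **Truncated stops.** Genes whose annotated length is not a multiple of 3
  (*ND2*, *COX3*, *ND4* here) end on `TA`/`T`, completed to `TAA` by mRNA
  polyadenylation. The remnant is reported as the stop token and treated as
  annotation metadata, never as a codon.
* **Families under code 2.** Leu is one six-codon family (pooling CUN and
  UUR) — with the published Leu counts (CUA 347 of 664) this yields
  RSCU(CUA) $= 6 \times 347/664 = 3.14$, confirming the pooled convention.
  Ser is six-fold (UCN + AGU/AGC) because AGA/AGG are stops; Met is two-fold
  (AUG/AUA); Trp is two-fold (UGG/UGA). RSCU of a single- or $k$-codon family
  sums to $k$ exactly; zero-usage families get RSCU 0 and a flag rather than
  NaN.

# Divergence statistics

**Nucleotide diversity** is the mean over all unordered sequence pairs of the
per-site proportion of differences. The default site filter is *complete
deletion*: any column containing a gap or ambiguity in any row is dropped for
all pairs (DnaSP's default); a pairwise-deletion mode exists but is not the
default. Variable sites are counted on the same filtered columns.

**Ka/Ks** follows Nei & Gojobori (1986) with equal pathway weighting and
Jukes–Cantor correction, the classic counting method:

* Synonymous sites per codon: at each position, the fraction of synonymous
  changes among the single-nucleotide mutations, with mutations *to stop
  codons dropped from the denominator*. Each position still contributes one
  site, so $N + S = 3 \times$ codons exactly — asserted against an
  enumeration oracle in the tests.
* Codon pairs differing at 2–3 positions are averaged over all orderings of
  the changes; pathways through stop codons are discarded (if every pathway is
  blocked, all pathways are used as a fallback so the pair still contributes).
* $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; saturation ($p \ge 3/4$) yields
  an explicit NA, never a clamped value.
* The per-gene ratio is pooled as $\bar{K_a}/\bar{K_s}$ (mean Ka over mean Ks
  across pairs) rather than the mean of pairwise ratios, so pairs with
  $K_s = 0$ cannot dominate; the mean-of-ratios variant is available.

A consequence of pathway averaging worth knowing: when two synonymous changes
hit the same codon, some pathways pass through a non-synonymous intermediate,
so a small fractional non-synonymous count can appear even under a process
that accepted only synonymous changes. This is inherent to the counting
method, not an implementation artifact; the near-zero-omega test asserts
amino-acid identity directly and bounds the estimated ratio instead of
demanding an exact zero.

# The simulator

The generator's defaults are the study conditions, chosen once:

* **Layout**: the bundled *T. indicus* template — order, strands and lengths.
  Real annotations overlap slightly (e.g. *ATP8*/*ATP6* share 10 bp); a random
  sequence cannot satisfy two overlapping reading frames, so the simulator
  lays genes out without overlap at the annotated lengths and lets the D-loop
  absorb the slack to hit the 16,723 bp target — mirroring the observation
  that real congeners differ in size almost entirely through the control
  region.
* **Composition**: A 29.63 / C 32.88 / G 14.73 / T 22.75 %, the C/A-biased
  heavy-strand composition typical of these birds. Realized composition
  converges to the target with sequence length (within 1% at 100 kb); ORF
  constraints (no internal stops, fixed start/stop codons) distort it by a few
  tenths of a percent.
* **Codon model**: at each codon site, single-nucleotide changes are accepted
  with relative rate 1 (synonymous), $\omega$ (non-synonymous) or 0 (to a
  stop), times $\kappa = 2$ for transitions. Sites evolve independently by
  exponential waiting times (a per-site Gillespie simulation — exact for this
  process and simpler than matrix exponentiation at these sizes). Branch
  lengths are calibrated so one unit equals one expected substitution per
  nucleotide site at the root composition.
* **Tree**: a star tree with tip branches of 0.05 substitutions/site
  (pairwise distance ~0.1, typical intra-family mitochondrial divergence);
  any `ape::phylo` with edge lengths can be supplied instead.
* **Per-gene omega**: defaults span the purifying range reported for
  mitochondrial PCGs, with *ATP8* highest (0.13) and *COX1* lowest (0.015).
  rRNAs evolve under a plain HKY-like nucleotide process at 0.35× the PCG
  rate (slow-evolving, as observed).
* **Panel size**: 25 taxa, a typical family-level comparative panel.
* **Seeding**: one global seed drives every draw; fixtures are byte-identical
  across runs (GenBank LOCUS date stamps aside).

**What the simulator does not emulate**: indels (alignments are gap-free, so
gap handling is exercised only by hand-built fixtures), recombination,
heteroplasmy, among-site rate variation, and base-composition heterogeneity
along the genome. Passing recovery tests therefore show estimator
correctness under a well-specified generating process — not robustness to
alignment error or model misspecification in real data.

**Calibration accuracy.** Nei–Gojobori with equal pathway weights slightly
underestimates $\omega$ under transition bias (by roughly 10–20% at
$\kappa = 2$ in our conditions) because synonymous transitions inflate the
observed synonymous proportion relative to the unweighted site counts. The
recovery check (mean estimate within 25% of truth for
$\omega \in \{0.05, 0.1, 0.5\}$, 100 replicates of 10 taxa × 500 codons)
passes with this bias included, and rank recovery across genes is
essentially perfect (Spearman ≥ 0.95 on 25-taxon panels).

# Numerical and degenerate-input policy

* Undefined quantities are NA markers, never silent zeros: zero-denominator
  skews, $\pi$ with no usable columns, Ka/Ks with $K_s = 0$, saturated
  distances, zero-variance correlations.
* Percentages are rounded (2 dp) and rates formatted (5 dp) only in the
  TSV reporting layer; all upstream values keep full precision.
* IUPAC ambiguity codes are excluded from composition denominators, never
  fractionally allocated; alignment columns containing them are filtered like
  gaps.
* Empty inputs error early with the offending row or column named.

# Problem sizes

The bundled analyses and tests run at desk scale by design: 25-taxon panels
with full-length genes for the end-to-end stages, 10 taxa × 500 codons ×
100 replicates per omega for estimator recovery, and 100 kb genomes for
composition convergence. These sizes give sampling errors comfortably inside
the asserted tolerances while keeping the whole suite under a minute.

# Known limitations

* The Ka/Ks implementation is classic Nei–Gojobori; modified-NG
  (transition-weighted sites) and ML codon models are out of scope, so
  estimates on real, strongly transition-biased data will sit slightly below
  ML-based $\omega$.
* The GenBank reader handles the minimal LOCUS/FEATURES/ORIGIN dialect with
  single-interval (possibly origin-wrapping, possibly complemented)
  locations — enough for mitogenome records; multi-interval joins and fuzzy
  coordinates are rejected explicitly.
* Alignment and trimming are consumed, not produced: results on real data
  inherit whatever the upstream aligner (MAFFT/MACSE) and trimmer (Gblocks)
  did.
* Published panel-level values (e.g. per-gene Ka/Ks from a specific set of
  GenBank genomes) depend on the exact genome set and the original software's
  algorithm variants; this package reproduces the *method* and validates it
  on ground truth, and treats such values as directional expectations
  (ordering, purifying bound) rather than exact targets.
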