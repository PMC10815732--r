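# mitocomp

Comparative mitogenomics of annotated circular mitochondrial genomes, built
around the 37-gene avian arrangement (13 protein-coding genes, 22 tRNAs,
2 rRNAs, one control region). The package is aimed at researchers
characterizing a newly sequenced mitogenome against its relatives: it parses
existing annotations, reproduces the standard descriptive statistics, screens
genes for selection, and prepares the concatenated input for phylogenetic
inference.

What it computes:

* **Genome structure** — gene tables from TSV or GenBank flat files with
  1-based inclusive (circular) coordinates; strand-correct gene extraction;
  strand census; verification of the ancestral avian gene order
  (trnF, rrnS, …, Cytb, trnT, trnP, ND6, trnE, D-loop), cyclically.
* **Codon usage** — codon splitting with truncated-stop handling (`T`/`TA`
  completed by polyadenylation), start/stop classification (ATG vs GTG
  starts; TAA/TAG/AGA/AGG stops under the vertebrate mitochondrial code),
  codon and amino-acid counts, and relative synonymous codon usage
  RSCU(c) = k·n_c / Σ_family n, which sums to the family degeneracy k.
* **Composition and skew** — %A/C/G/T, AT/GC content,
  AT-skew = (A−T)/(A+T), GC-skew = (G−C)/(G+C), per gene, per concatenated
  class and per genome, plus the content-vs-skew Pearson correlation across
  genomes.
* **Divergence** — nucleotide diversity π (mean pairwise difference per site,
  complete deletion), variable-site percentages, and Nei–Gojobori (1986)
  Ka/Ks with Jukes–Cantor correction, pooled per gene as mean(Ka)/mean(Ks).
* **Supermatrix** — concatenation of per-gene alignments with RAxML/NEXUS
  partition files, FASTA/PHYLIP output and a JSON manifest.
* **Simulation** — annotated mitogenomes and multi-taxon alignments evolved
  under a codon model with known per-gene dN/dS (ω), used as ground truth for
  every estimator.

The bundled annotations of *Tarsiger indicus* (GenBank OR459825, 16,723 bp)
and *T. cyanurus* (KF997864, 16,803 bp) drive the desk-scale analyses.

## Worked example

```r
library(mitocomp)

tb <- tarsiger_gene_table("indicus")
genome_length_of(tb)              # 16723
strand_census(tb)$heavy           # 28
strand_census(tb)$light           # 9
validate_avian_order(tb)$is_ancestral_avian   # TRUE
sum(tb$length[tb$category == "PCG"] %/% 3)    # 3797 codons in the 13 PCGs

# RSCU of CUA from the published Leu family counts (347 of 664)
leu <- c(CTA = 347, TTA = 120, TTG = 40, CTT = 77, CTC = 55, CTG = 25)
rscu <- compute_rscu(count_codons(list(paste(rep(names(leu), leu), collapse = ""))))
round(rscu$rscu[rscu$codon == "CTA"], 2)      # 3.14

# ground-truth validation: simulate a 25-taxon panel, estimate Ka/Ks
fx  <- generate_study_fixture(sim_config(seed = 103, n_taxa = 25))
div <- divergence_table(fx$alignments)
```

Running the full workflow (`analysis/01_structure.R` … `05_supermatrix.R`)
prints, among others:

```
T_indicus: 16723 bp, 37 genes (28 heavy / 9 light), D-loop 1150 bp, ancestral avian order: TRUE
Total codons, stop triplets included: 3797
RSCU(CUA) from printed Leu counts: 3.14 (6 x 347 / 664)
All 13 PCGs purifying (Ka/Ks < 1): TRUE; highest ATP8 (0.09847), lowest COX1 (0.01443)
Spearman rank agreement of estimated Ka/Ks with true omega: 0.971
Supermatrix: 25 taxa x 13972 bp in 15 partitions
```

i.e. the structural table is reproduced exactly from coordinates; on the
simulated panel every protein-coding gene is detected as purifying with the
estimated Ka/Ks ordered like the generating ω (ATP8 fastest, COX1 most
constrained), matching the biological expectation for mitochondrial PCGs.

## The analysis workflow

Numbered drivers under `analysis/` run the stages end to end and write TSV /
JSON artifacts under `results/`:

| script | what it does |
| --- | --- |
| `01_structure.R` | gene tables, lengths, strand census, order check |
| `02_codon_usage.R` | codon totals, start/stop classification, RSCU |
| `03_composition_skew.R` | composition, skews, content-skew correlation |
| `04_divergence.R` | π, variable sites, Ka/Ks vs ground truth |
| `05_supermatrix.R` | concatenation + partition files |

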