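#!/usr/bin/env Rscript

# Genome structure and organization of the two Tarsiger mitogenomes.
#
# Parses the bundled annotations (T. indicus OR459825, T. cyanurus KF997864),
# cross-checks every printed gene length against coordinate arithmetic,
# tallies the strand census and verifies the ancestral avian gene order.
# Writes normalized gene tables and a JSON summary under results/structure/.

suppressMessages(library(mitocomp))

out_dir <- "results/structure"
tabs <- list(
  T_indicus = tarsiger_gene_table("indicus"),
  T_cyanurus = tarsiger_gene_table("cyanurus")
)
summaries <- run_structure(tabs, out_dir)

for (nm in names(summaries)) {
  s <- summaries[[nm]]
  cat(sprintf(
    "%s: %d bp, %d genes (%d heavy / %d light), D-loop %d bp, ancestral avian order: %s\n",
    nm, s$genome_length, s$heavy_strand + s$light_strand,
    s$heavy_strand, s$light_strand, s$dloop_length, s$is_ancestral_avian
  ))
  cat(sprintf(
    "  light-strand genes: %s\n  printed-length discrepancies: %d\n",
    paste(s$light_genes, collapse = ", "), s$length_discrepancies
  ))
}

# interspecific size difference is carried by the control region
dl <- vapply(tabs, function(t) t$length[t$category == "control-region"], 1L)
cat(sprintf(
  "\nGenome size difference: %d bp; D-loop difference: %d bp\n",
  abs(diff(vapply(tabs, genome_length_of, 1L))), abs(diff(dl))
))
cat("Reports written to", out_dir, "\n")
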