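test_that("nucleotide diversity: trivial cases and brute-force agreement", {
  aln0 <- gene_alignment("g", c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(nucleotide_diversity(aln0)$pi, 0)

  aln1 <- gene_alignment("g", c(a = "ACGTACGTAC", b = "ACGTACGTAT"))
  expect_equal(nucleotide_diversity(aln1)$pi, 0.1)

  set.seed(20)
  for (rep in 1:10) {
    aln <- random_alignment("g", 4, 30, gap_frac = 0.05)
    got <- nucleotide_diversity(aln)
    expect_equal(got$pi, pi_oracle(unname(aln$seqs)), tolerance = 1e-12)
  }

  gappy <- gene_alignment("g", c(a = "---", b = "AC-"))
  expect_true(is.na(nucleotide_diversity(gappy)$pi))
  expect_error(nucleotide_diversity(gene_alignment("g", c(a = "ACGT"))), "at least 2")
})

test_that("pi is invariant to row order and taxon relabeling", {
  set.seed(21)
  aln <- random_alignment("g", 5, 40, gap_frac = 0.1)
  shuffled <- aln$seqs[sample(length(aln$seqs))]
  names(shuffled) <- sprintf("zz%02d", seq_along(shuffled))
  aln2 <- gene_alignment("g", shuffled)
  expect_equal(nucleotide_diversity(aln)$pi, nucleotide_diversity(aln2)$pi)
})

test_that("variable sites: trivial extremes and column-scan agreement", {
  same <- gene_alignment("g", c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC"))
  expect_equal(variable_sites(same)$count, 0L)
  expect_equal(variable_sites(same)$percent, 0)

  alldiff <- gene_alignment("g", c(a = "AAAA", b = "CCCC"))
  expect_equal(variable_sites(alldiff)$percent, 100)

  set.seed(22)
  for (rep in 1:10) {
    aln <- random_alignment("g", 4, 50, gap_frac = 0.05)
    got <- variable_sites(aln)
    want <- varsites_oracle(unname(aln$seqs))
    expect_equal(got$count, want$count)
    expect_equal(got$percent, want$percent, tolerance = 1e-12)
  }
})

test_that("Nei-Gojobori matches the enumeration oracle on single-codon changes", {
  # one synonymous third-position change among 100 Ala codons
  c1 <- strrep("GCT", 100)
  c2 <- paste0(strrep("GCT", 99), "GCC")
  got <- nei_gojobori(c1, c2)
  want <- ng_single_oracle(c1, c2)
  expect_equal(got$ka, 0)
  expect_gt(got$ks, 0)
  expect_equal(got$S_sites, want$S, tolerance = 1e-12)
  expect_equal(got$N_sites, want$N, tolerance = 1e-12)
  expect_equal(got$ks, want$ks, tolerance = 1e-12)

  # one non-synonymous change (GCT -> GTT)
  c3 <- paste0(strrep("GCT", 99), "GTT")
  got2 <- nei_gojobori(c1, c3)
  want2 <- ng_single_oracle(c1, c3)
  expect_equal(got2$ks, 0)
  expect_gt(got2$ka, 0)
  expect_equal(got2$ka, want2$ka, tolerance = 1e-12)

  expect_equal(nei_gojobori(c1, c1)$ka, 0)
  expect_equal(nei_gojobori(c1, c1)$ks, 0)
})

test_that("NG site counts match the oracle across random ORFs and N+S = 3n", {
  set.seed(23)
  for (rep in 1:10) {
    orf <- random_orf(sample(20:60, 1))
    got <- nei_gojobori(orf, orf)
    n_sense <- nchar(orf) / 3 - 1 # terminal stop trimmed
    expect_equal(got$N_sites + got$S_sites, 3 * n_sense, tolerance = 1e-9)
    want <- ng_single_oracle(substr(orf, 1, nchar(orf) - 3), substr(orf, 1, nchar(orf) - 3))
    expect_equal(got$S_sites, want$S, tolerance = 1e-12)
  }
})

test_that("NG guards: frame violation, internal stops, saturation", {
  expect_error(nei_gojobori("ATGAAA", "ATGAAATTT"), "codon count")
  expect_error(nei_gojobori("ATGTAAAAA", "ATGTACAAA"), "internal stop")
  # saturated pair: every third position differs synonymously is impossible
  # at pd >= 3/4, so force it with maximally different codons
  c1 <- strrep("GGG", 30)
  c2 <- strrep("CCC", 30)
  got <- nei_gojobori(c1, c2)
  expect_true(is.na(got$ka)) # pn = 1 >= 3/4 -> undefined, never clamped
})

test_that("gene-level summary equals the single pairwise computation for 2 taxa", {
  set.seed(24)
  orf <- random_orf(60)
  mut <- sub("GCT", "GCC", orf) # introduce at most one codon change
  aln <- gene_alignment("g", c(t1 = substr(orf, 1, nchar(orf) - 3),
    t2 = substr(mut, 1, nchar(mut) - 3)), codon_aware = TRUE)
  s <- gene_divergence_summary(aln)
  pw <- nei_gojobori(substr(orf, 1, nchar(orf) - 3), substr(mut, 1, nchar(mut) - 3))
  expect_equal(s$ka, pw$ka)
  expect_equal(s$ks, pw$ks)
  expect_equal(s$pi, nucleotide_diversity(aln)$pi)
})

test_that("identical alignments give pi 0 and undefined ka_ks", {
  orf <- strrep("GCTGAA", 30)
  aln <- gene_alignment("g", c(a = orf, b = orf, c = orf), codon_aware = TRUE)
  s <- gene_divergence_summary(aln)
  expect_equal(s$pi, 0)
  expect_true(is.na(s$ka_ks)) # ks = 0 -> undefined marker
})
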