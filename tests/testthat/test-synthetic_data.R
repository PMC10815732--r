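test_that("simulated genomes honour the template structure deterministically", {
  cfg <- sim_config(seed = 1)
  g <- generate_mitogenome(cfg)
  expect_equal(nchar(g$sequence), 16723)
  cen <- strand_census(g$table)
  expect_equal(cen$heavy, 28)
  expect_equal(cen$light, 9)
  expect_true(validate_avian_order(g$table)$is_ancestral_avian)
  expect_identical(generate_mitogenome(cfg)$sequence, g$sequence)
})

test_that("every simulated PCG is a valid ORF under the mito code", {
  code <- genetic_code(2)
  g <- generate_mitogenome(sim_config(seed = 2))
  for (p in g$table$gene[g$table$category == "PCG"]) {
    cds <- extract_gene_sequence(g, p)
    sp <- split_codons(cds)
    aa <- unname(code$aa[sp$codons])
    expect_false(any(aa[-length(aa)] == "*"), info = p)
    d <- detect_start_stop(cds, code)
    expect_true(d$start %in% c("ATG", "GTG"), info = p)
    expect_true(d$stop_is_valid, info = p)
  }
  # annotated truncated stops are reproduced
  expect_true(detect_start_stop(extract_gene_sequence(g, "ND2"), code)$stop_truncated)
  expect_true(detect_start_stop(extract_gene_sequence(g, "COX3"), code)$stop_truncated)
  expect_true(detect_start_stop(extract_gene_sequence(g, "ND4"), code)$stop_truncated)
  expect_equal(detect_start_stop(extract_gene_sequence(g, "COX1"), code)$start, "GTG")
})

test_that("realized composition converges to the target", {
  cfg <- sim_config(
    seed = 40,
    composition = c(A = 25, C = 25, G = 25, T = 25),
    genome_length_target = 100000
  )
  # scale the template's control region to absorb the extra length
  g <- generate_mitogenome(cfg)
  b <- base_composition(g$sequence)
  expect_lt(max(abs(c(b$pct_a, b$pct_c, b$pct_g, b$pct_t) - 25)), 1)

  biased <- generate_mitogenome(sim_config(seed = 41, genome_length_target = 100000))
  bb <- base_composition(biased$sequence)
  expect_lt(abs(bb$pct_c - 32.88), 1.5) # C-rich target, slight ORF distortion
  expect_gt(bb$at_skew, 0) # A over T, as on real heavy strands
  expect_lt(bb$gc_skew, 0) # C over G
})

test_that("branch length zero reproduces the root; omega <= 0 is rejected", {
  set.seed(42)
  root <- random_orf(50)
  cfg0 <- sim_config(seed = 43, n_taxa = 4, branch_length = 0, omega = c(g = 0.1))
  aln <- evolve_alignment(root, cfg0, "g")
  expect_true(all(aln$seqs == substr(root, 1, nchar(root))))
  expect_error(sim_config(omega = c(g = 0)), "omega")
  expect_error(sim_config(omega = c(g = -1)), "omega")
})

test_that("near-zero omega yields only synonymous differences", {
  set.seed(44)
  root <- random_orf(200)
  cfg <- sim_config(seed = 45, n_taxa = 6, omega = c(g = 1e-9))
  aln <- evolve_alignment(root, cfg, "g")
  # every evolved codon still translates to the root's amino acid
  root_aa <- vapply(split_codons(root)$codons, translate2, "")
  for (row in aln$seqs) {
    aa <- vapply(split_codons(row)$codons, translate2, "")
    expect_equal(unname(aa), unname(root_aa))
  }
  s <- gene_divergence_summary(aln)
  expect_gt(s$ks, 0)
  # pathway averaging may allocate fractional nonsynonymous counts to
  # multiple-hit codons, so ka is near zero rather than exactly zero
  expect_lt(s$ka_ks, 0.01)
})

test_that("fixed seeds give byte-identical fixtures; two-taxon mode works", {
  dir1 <- tempfile()
  dir2 <- tempfile()
  cfg <- sim_config(seed = 46, n_taxa = 2)
  generate_study_fixture(cfg, dir1)
  generate_study_fixture(cfg, dir2)
  f1 <- list.files(dir1)
  expect_true(all(c("truth_manifest.json", "ND1.aln.fasta", "sim_t01.gb") %in% f1))
  for (f in setdiff(f1, "")) {
    # GenBank headers carry a date stamp; compare everything else byte-wise
    l1 <- readLines(file.path(dir1, f))
    l2 <- readLines(file.path(dir2, f))
    keep <- !grepl("^LOCUS", l1)
    expect_identical(l1[keep], l2[keep], label = f)
  }
  fx <- generate_study_fixture(cfg)
  div <- gene_divergence_summary(fx$alignments[["ND2"]])
  expect_equal(div$n_taxa, 2)
})

test_that("pi recovery on a star tree matches the branch-length calibration", {
  # star tree with tip branch b: expected pairwise distance 2b; compare on the
  # Jukes-Cantor corrected scale to absorb multiple hits
  b <- 0.02
  ds <- vapply(1:8, function(i) {
    cfg <- sim_config(
      seed = 4700 + i, n_taxa = 4, branch_length = b,
      rate_scale = c(none = 1)
    )
    set.seed(4800 + i)
    root <- random_seq(5000, probs = c(0.2963, 0.3288, 0.1473, 0.2275))
    p <- nucleotide_diversity(evolve_nucleotide_alignment(root, cfg, "rna"))$pi
    -0.75 * log(1 - 4 * p / 3)
  }, 1)
  se <- stats::sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - 2 * b), 3 * se + 0.002)
})

test_that("infeasible compositions are rejected", {
  expect_error(sim_config(composition = c(A = 0, C = 50, G = 25, T = 25)), "infeasible")
  expect_error(sim_config(composition = c(A = 40, C = 40, G = 10, T = 20)), "sum")
})
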