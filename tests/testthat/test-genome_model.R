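test_that("feature rows parse from both TSV dialects, with separators stripped", {
  tb <- parse_feature_table(
    "gene\tlocation\nATP8\t7852–8019: +\nD-loop\t15,574–16,723: +\n",
    genome_length = 16723
  )
  expect_equal(tb$gene, c("ATP8", "D-loop"))
  expect_equal(tb$start, c(7852L, 15574L))
  expect_equal(tb$end, c(8019L, 16723L))
  expect_equal(tb$strand, c("+", "+"))
  expect_equal(tb$category, c("PCG", "control-region"))

  tb2 <- parse_feature_table("gene\tstart\tend\tstrand\nND5\t11851\t13668\t+\n")
  expect_equal(tb2$length, 1818L)
})

test_that("empty input yields an empty table; malformed rows name the culprit", {
  tb <- parse_feature_table("")
  expect_s3_class(tb, "gene_table")
  expect_equal(nrow(tb), 0)

  expect_error(
    parse_feature_table("gene\tstart\tend\tstrand\nND1\tabc\t10\t+\n"),
    "malformed coordinates"
  )
  expect_error(
    parse_feature_table("gene\tstart\tend\tstrand\nND1\t1\t10\t*\n"),
    "strand"
  )
  expect_error(
    parse_feature_table(
      "gene\tstart\tend\tstrand\nND1\t1\t10\t+\nND1\t20\t30\t+\n"
    ),
    "duplicate"
  )
})

test_that("printed-length cross-check records discrepancies without resolving them", {
  tb <- parse_feature_table(
    "gene\tstart\tend\tstrand\tlength\ntrnS1\t11714\t11780\t+\t69\nND5\t11851\t13668\t+\t1818\n"
  )
  disc <- length_discrepancies(tb)
  expect_equal(nrow(disc), 1)
  expect_equal(disc$gene, "trnS1")
  expect_equal(disc$printed_length, 69L)
  expect_equal(tb$length[tb$gene == "trnS1"], 67L) # coordinates win in the table
})

test_that("gene_length handles inclusive coordinates and origin wrap", {
  expect_equal(gene_length(11851, 13668, 16723), 1818L)
  expect_equal(gene_length(1, 1, 10), 1L)
  expect_equal(gene_length(16720, 5, 16723), 9L)
  expect_error(gene_length(0, 5, 10), "outside")
  expect_error(gene_length(2, 11, 10), "outside")
})

test_that("extraction is strand-correct and circular", {
  g <- mitogenome(
    "toy", "AAACGT",
    gene_table(data.frame(gene = "g1", start = 2, end = 4, strand = "+"), 6)
  )
  expect_equal(extract_gene_sequence(g, data.frame(start = 2, end = 4, strand = "+")), "AAC")
  expect_equal(extract_gene_sequence(g, data.frame(start = 2, end = 4, strand = "-")), "GTT")
  expect_equal(extract_gene_sequence(g, data.frame(start = 6, end = 2, strand = "+")), "TAA")
})

test_that("extracted length equals gene_length for random tables incl. wraps", {
  set.seed(11)
  for (rep in 1:20) {
    L <- sample(50:200, 1)
    seq <- random_seq(L)
    s <- sample(L, 1)
    e <- sample(L, 1)
    st <- sample(c("+", "-"), 1)
    g <- mitogenome("r", seq, gene_table(data.frame(gene = "g1", start = s, end = e, strand = st), L))
    extracted <- extract_gene_sequence(g, data.frame(start = s, end = e, strand = st))
    expect_equal(nchar(extracted), gene_length(s, e, L))
  }
})

test_that("gene tables round-trip through the writer and parser", {
  tb <- tarsiger_gene_table("indicus")
  tmp <- tempfile(fileext = ".tsv")
  write_feature_table(tb, tmp)
  tb2 <- parse_feature_table(tmp, genome_length = genome_length_of(tb))
  expect_equal(as.data.frame(tb)[, c("gene", "start", "end", "strand", "length")],
    as.data.frame(tb2)[, c("gene", "start", "end", "strand", "length")])
})

test_that("strand census matches the published 28 heavy / 9 light split", {
  tb <- tarsiger_gene_table("indicus")
  cen <- strand_census(tb)
  expect_equal(cen$heavy, 28)
  expect_equal(cen$light, 9)
  expect_setequal(
    cen$light_genes,
    c("trnQ", "trnA", "trnN", "trnC", "trnY", "trnS2", "trnE", "trnP", "ND6")
  )
  expect_equal(cen$heavy + cen$light, 37)

  empty <- gene_table(data.frame())
  expect_equal(strand_census(empty), list(heavy = 0L, light = 0L, light_genes = character(0)))

  one <- gene_table(data.frame(gene = "trnQ", start = 1, end = 70, strand = "-"), 100)
  expect_equal(strand_census(one)$light, 1)
  expect_equal(strand_census(one)$heavy, 0)
})

test_that("avian order check is rotation-invariant and localizes swaps", {
  tb <- tarsiger_gene_table("indicus")
  expect_true(validate_avian_order(tb)$is_ancestral_avian)

  df <- as.data.frame(tb)
  k <- which(df$gene == "rrnS")
  rotated <- gene_table(rbind(df[k:nrow(df), ], df[1:(k - 1), ]), genome_length_of(tb))
  expect_true(validate_avian_order(rotated)$is_ancestral_avian)

  swapped <- df
  i <- which(df$gene == "ND5")
  j <- which(df$gene == "Cytb")
  swapped$gene[c(i, j)] <- df$gene[c(j, i)]
  swapped$start_codon <- swapped$stop_codon <- NULL
  chk <- validate_avian_order(gene_table(swapped, genome_length_of(tb)))
  expect_false(chk$is_ancestral_avian)
  expect_equal(nrow(chk$mismatches), 2)

  incomplete <- gene_table(df[df$gene != "trnA", ], genome_length_of(tb))
  expect_error(validate_avian_order(incomplete), "trnA")
})

test_that("gene name synonyms normalize onto canonical names", {
  expect_equal(
    normalize_gene_name(c("COI", "CYTB", "12S", "16S", "tRNA-Phe", "trnA", "ND4L", "D-LOOP")),
    c("COX1", "Cytb", "rrnS", "rrnL", "trnF", "trnA", "ND4L", "D-loop")
  )
  expect_equal(gene_category(c("COX1", "trnF", "rrnS", "D-loop", "orfX")),
    c("PCG", "tRNA", "rRNA", "control-region", "other"))
})

test_that("GenBank flat files round-trip annotation and sequence", {
  cfg <- sim_config(seed = 3, n_taxa = 2)
  g <- generate_mitogenome(cfg, id = "RT1")
  tmp <- tempfile(fileext = ".gb")
  write_genbank(g, tmp)
  g2 <- read_genbank(tmp)
  expect_equal(g2$sequence, g$sequence)
  expect_equal(g2$id, "RT1")
  expect_equal(as.data.frame(g2$table)[, c("gene", "start", "end", "strand")],
    as.data.frame(g$table)[, c("gene", "start", "end", "strand")])
})

test_that("per-gene FASTA export writes strand-correct records", {
  cfg <- sim_config(seed = 4, n_taxa = 2)
  g <- generate_mitogenome(cfg, id = "FX")
  tmp <- tempfile(fileext = ".fasta")
  seqs <- genes_to_fasta(g, tmp)
  back <- Biostrings::readDNAStringSet(tmp)
  expect_equal(length(back), nrow(g$table))
  expect_equal(names(back)[1], paste0("FX|", g$table$gene[1]))
  nd6 <- as.character(back[[paste0("FX|ND6")]])
  expect_equal(nd6, extract_gene_sequence(g, "ND6"))
  expect_equal(substr(nd6, 1, 3), "ATG") # light-strand gene read as its ORF
})
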