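test_that("codon splitting returns in-frame triplets plus the trailing remnant", {
  expect_equal(split_codons("ATGTAA"), list(codons = c("ATG", "TAA"), remnant = ""))
  expect_equal(split_codons("ATGC"), list(codons = "ATG", remnant = "C"))
  expect_error(split_codons(""), "empty")

  # an ND2-like CDS of length 1040 splits into 346 codons + "TA"
  set.seed(2)
  cds <- paste0(random_seq(1038), "TA")
  sp <- split_codons(cds)
  expect_length(sp$codons, 346)
  expect_equal(sp$remnant, "TA")
})

test_that("start/stop detection classifies ATG, GTG and truncated stops", {
  d <- detect_start_stop("ATGAAATAA")
  expect_equal(d$start, "ATG")
  expect_equal(d$start_class, "canonical-ATG")
  expect_equal(d$stop, "TAA")
  expect_false(d$stop_truncated)
  expect_true(d$stop_is_valid)

  d2 <- detect_start_stop(paste0("GTG", strrep("GCA", 10), "AGG"))
  expect_equal(d2$start_class, "alternative")
  expect_equal(d2$stop, "AGG")
  expect_true(d2$stop_is_valid) # AGG is a stop only under the mito code

  # COX3-like: length 784 = 261 codons + 1, truncated "T"
  set.seed(3)
  cds <- paste0("ATG", random_seq(780), "T")
  d3 <- detect_start_stop(cds)
  expect_equal(d3$stop, "T")
  expect_true(d3$stop_truncated)

  expect_error(detect_start_stop("ATG"), "shorter")
})

test_that("remnant is consistent between split_codons and detect_start_stop", {
  set.seed(4)
  for (len in c(30, 31, 32, 99, 100)) {
    cds <- paste0("ATG", random_seq(len))
    sp <- split_codons(cds)
    d <- detect_start_stop(cds)
    if (nzchar(sp$remnant)) {
      expect_equal(d$stop, sp$remnant)
      expect_true(d$stop_truncated)
    } else {
      expect_false(d$stop_truncated)
    }
  }
})

test_that("codon counting follows the stop-inclusion convention and is additive", {
  u <- count_codons(list("ATGTAA"), include_stops = FALSE)
  expect_equal(u$total_codons, 1L)
  u2 <- count_codons(list("ATGTAA"), include_stops = TRUE)
  expect_equal(u2$total_codons, 2L)
  u3 <- count_codons(list("ATGCTACTA"))
  expect_equal(unname(u3$counts[["CTA"]]), 2L)

  set.seed(5)
  a <- random_orf(20)
  b <- random_orf(30)
  both <- count_codons(list(a, b))
  solo <- count_codons(list(a))$counts + count_codons(list(b))$counts
  expect_equal(both$counts, solo)
  expect_equal(both$total_codons, 50L) # = sum floor(len/3), remnants never counted
})

test_that("amino-acid usage pools synonymous codons and isolates stops", {
  u <- count_codons(list(paste(c("ATG", "ATA", "CTA", "TTA", "CTG", "TAA"), collapse = "")))
  aa <- amino_acid_usage(u)
  expect_equal(unname(aa[["M"]]), 2L) # ATA is Met under the mito code
  expect_equal(unname(aa[["L"]]), 3L) # six-fold Leu family pooled
  expect_equal(attr(aa, "Ter"), 1L)
  expect_false("*" %in% names(aa))

  empty <- amino_acid_usage(count_codons(list("AAA"), include_stops = FALSE))
  expect_equal(sum(empty), 1L)
})

test_that("RSCU follows count * degeneracy / family total and flags zero families", {
  # printed Leu counts: CTA 347 of a 664-strong six-codon family
  counts <- c(CTA = 347, TTA = 100, TTG = 50, CTT = 80, CTC = 60, CTG = 27)
  cds <- paste(rep(names(counts), counts), collapse = "")
  rscu <- compute_rscu(count_codons(list(cds)))
  expect_equal(rscu$rscu[rscu$codon == "CTA"], 6 * 347 / 664, tolerance = 1e-12)
  expect_equal(round(rscu$rscu[rscu$codon == "CTA"], 2), 3.14)

  # a four-fold family with uniform usage is flat at 1
  gly <- compute_rscu(count_codons(list(strrep("GGAGGCGGGGGT", 3))))
  expect_equal(gly$rscu[gly$aa == "G"], rep(1, 4))

  # unused families: RSCU 0, flagged
  expect_true(all(rscu$rscu[rscu$zero_family] == 0))
  expect_true(any(rscu$zero_family))
})

test_that("RSCU family sums equal degeneracy for random usages", {
  set.seed(6)
  for (rep in 1:20) {
    u <- count_codons(list(random_orf(sample(50:200, 1))), include_stops = FALSE)
    rscu <- compute_rscu(u)
    sums <- tapply(rscu$rscu, rscu$aa, sum)
    sizes <- tapply(rscu$family_size, rscu$aa, unique)
    nonzero <- !tapply(rscu$zero_family, rscu$aa, any)
    expect_equal(as.numeric(sums[nonzero]), as.numeric(sizes[nonzero]),
      tolerance = 1e-12)
  }
})

test_that("the vertebrate mitochondrial code drives stop and family structure", {
  code <- genetic_code(2)
  expect_setequal(code$stops, c("TAA", "TAG", "AGA", "AGG"))
  expect_equal(unname(code$aa["TGA"]), "W")
  expect_equal(unname(code$aa["ATA"]), "M")
  expect_length(code$families[["L"]], 6)
  expect_length(code$families[["S"]], 6) # TCN + AGT/AGC: AGA/AGG are stops
  expect_length(code$families[["M"]], 2)
})
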