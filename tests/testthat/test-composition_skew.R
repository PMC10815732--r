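test_that("base composition counts, percentages and boundary skews", {
  b <- base_composition("ACGT")
  expect_equal(c(b$pct_a, b$pct_c, b$pct_g, b$pct_t), rep(25, 4))
  expect_equal(b$at_skew, 0)
  expect_equal(b$gc_skew, 0)
  expect_equal(b$at_content + b$gc_content, 100)

  b2 <- base_composition("AAAA")
  expect_equal(b2$pct_a, 100)
  expect_equal(b2$at_skew, 1)
  expect_true(is.na(b2$gc_skew)) # zero denominator -> undefined, not 0

  expect_error(base_composition(""), "empty")
  expect_error(base_composition("NNN"), "unambiguous")

  amb <- base_composition("ACGTN")
  expect_equal(amb$n_effective, 4L)
  expect_equal(amb$pct_a, 25) # ambiguity excluded from denominators
})

test_that("skew formula, undefined marker and error path", {
  expect_equal(skew(29.63, 22.75), (29.63 - 22.75) / (29.63 + 22.75))
  expect_equal(round(skew(29.63, 22.75), 4), 0.1313)
  expect_equal(skew(5, 5), 0)
  expect_true(is.na(skew(0, 0)))
  expect_error(skew(-1, 2), "negative")
})

test_that("skews negate under reverse complement for any sequence", {
  set.seed(7)
  for (rep in 1:25) {
    s <- random_seq(sample(20:300, 1), probs = c(0.4, 0.3, 0.1, 0.2))
    b <- base_composition(s)
    br <- base_composition(revcomp_oracle(s))
    expect_equal(br$at_skew, -b$at_skew, tolerance = 1e-12)
    expect_equal(br$gc_skew, -b$gc_skew, tolerance = 1e-12)
  }
})

test_that("composition of a concatenation is the count-weighted merge of parts", {
  set.seed(8)
  parts <- replicate(4, random_seq(sample(50:150, 1)))
  whole <- base_composition(paste(parts, collapse = ""))
  counts <- rowSums(vapply(parts, function(p) {
    b <- base_composition(p)
    c(b$a, b$c, b$g, b$t)
  }, numeric(4)))
  expect_equal(c(whole$a, whole$c, whole$g, whole$t), unname(counts))
})

test_that("per-gene composition rows agree with direct computation", {
  cfg <- sim_config(seed = 9, n_taxa = 2)
  g <- generate_mitogenome(cfg)
  comp <- per_gene_composition(g)

  whole <- comp[comp$region == "genome", ]
  direct <- base_composition(g$sequence)
  expect_equal(whole$gc_content, direct$gc_content)
  expect_equal(whole$at_skew, direct$at_skew)

  # concatenated-PCG row equals composition of the brute-force concatenation
  # (reference orientation: light-strand ND6 contributes its heavy-strand face)
  pcgs <- g$table$gene[g$table$category == "PCG"]
  concat <- paste(vapply(pcgs, function(p) {
    s <- extract_gene_sequence(g, p)
    if (g$table$strand[g$table$gene == p] == "-") s <- revcomp_oracle(s)
    s
  }, ""), collapse = "")
  expect_equal(
    comp[comp$region == "PCGs", "gc_content"],
    base_composition(concat)$gc_content
  )
  expect_equal(
    comp[comp$region == "PCGs", "at_skew"],
    base_composition(concat)$at_skew
  )

  # coding orientation flips the sign of light-strand gene skews
  comp_cod <- per_gene_composition(g, orientation = "coding")
  expect_equal(
    comp_cod[comp_cod$region == "ND6", "at_skew"],
    -comp[comp$region == "ND6", "at_skew"],
    tolerance = 1e-12
  )
})

test_that("content-skew correlation matches the closed-form Pearson r", {
  x <- 1:10
  expect_equal(content_skew_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(content_skew_correlation(x, -0.5 * x)$r, -1)
  expect_true(is.na(content_skew_correlation(rep(1, 5), rnorm(5))$r))
  expect_error(content_skew_correlation(1:2, 1:2), "at least 3")

  set.seed(10)
  a <- runif(50)
  b <- runif(50)
  r_formula <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  got <- content_skew_correlation(a, b)
  expect_equal(got$r, r_formula, tolerance = 1e-12)
  expect_equal(got$n, 50L)
  expect_lt(abs(got$r), 0.35)
})
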