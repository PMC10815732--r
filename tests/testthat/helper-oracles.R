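# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: translation goes through seqinr (numcode = 2),
# pairwise counting is naive brute force.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n, probs = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = probs), collapse = "")
}

revcomp_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

translate2 <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]], numcode = 2)
}

# brute-force average pairwise diversity with complete deletion
pi_oracle <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(mat, 2, function(col) all(col %in% BASES))
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat) == 0) return(NA_real_)
  n <- nrow(mat)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      vals <- c(vals, mean(mat[i, ] != mat[j, ]))
    }
  }
  mean(vals)
}

varsites_oracle <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(mat, 2, function(col) all(col %in% BASES))
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat) == 0) return(list(count = 0L, percent = NA_real_))
  v <- sum(apply(mat, 2, function(col) length(unique(col)) > 1))
  list(count = v, percent = 100 * v / ncol(mat))
}

# enumeration of the 9 single-nt mutations of a codon: synonymous site count
# with mutations-to-stop dropped from each position's denominator
syn_sites_oracle <- function(codon) {
  cod <- strsplit(codon, "")[[1]]
  aa0 <- translate2(codon)
  stopifnot(aa0 != "*")
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    usable <- 0
    for (b in setdiff(BASES, cod[pos])) {
      mut <- cod
      mut[pos] <- b
      aam <- translate2(paste(mut, collapse = ""))
      if (aam == "*") next
      usable <- usable + 1
      if (aam == aa0) syn <- syn + 1
    }
    if (usable > 0) s <- s + syn / usable
  }
  s
}

# Nei-Gojobori for sequences whose codon pairs differ at most at one position
ng_single_oracle <- function(cds1, cds2) {
  split3 <- function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  cod1 <- split3(cds1)
  cod2 <- split3(cds2)
  S <- (sum(vapply(cod1, syn_sites_oracle, 1)) +
    sum(vapply(cod2, syn_sites_oracle, 1))) / 2
  N <- 3 * length(cod1) - S
  sd <- 0
  nd <- 0
  for (k in seq_along(cod1)) {
    if (cod1[k] == cod2[k]) next
    ndiff <- sum(strsplit(cod1[k], "")[[1]] != strsplit(cod2[k], "")[[1]])
    stopifnot(ndiff == 1)
    if (translate2(cod1[k]) == translate2(cod2[k])) sd <- sd + 1 else nd <- nd + 1
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, sd = sd, nd = nd, ks = jc(sd / S), ka = jc(nd / N))
}

# random in-frame ORF under code 2 (ATG start, sense internal codons, TAA stop)
random_orf <- function(n_codons) {
  internal <- character(n_codons - 2)
  i <- 1
  while (i <= length(internal)) {
    cand <- random_seq(3)
    if (translate2(cand) != "*") {
      internal[i] <- cand
      i <- i + 1
    }
  }
  paste(c("ATG", internal, "TAA"), collapse = "")
}

random_alignment <- function(gene, n_taxa, len, gap_frac = 0) {
  seqs <- vapply(seq_len(n_taxa), function(i) random_seq(len), "")
  if (gap_frac > 0) {
    for (i in seq_along(seqs)) {
      v <- strsplit(seqs[i], "")[[1]]
      ng <- rbinom(1, len, gap_frac)
      if (ng > 0) v[sample(len, ng)] <- "-"
      seqs[i] <- paste(v, collapse = "")
    }
  }
  names(seqs) <- sprintf("tx%02d", seq_len(n_taxa))
  gene_alignment(gene, seqs)
}
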