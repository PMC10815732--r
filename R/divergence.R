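# Alignment-based evolution statistics: nucleotide diversity (Pi), variable
# sites, and Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.

#' Construct a gene alignment
#'
#' @param gene gene name.
#' @param seqs named character vector (names = taxa) of equal-length aligned
#'   sequences, gap character \code{"-"}.
#' @param codon_aware flag for protein-coding alignments kept in frame
#'   (ungapped length of every row a multiple of 3).
#' @return object of class \code{"gene_alignment"}.
#' @export
gene_alignment <- function(gene, seqs, codon_aware = FALSE) {
  seqs <- toupper(vapply(seqs, as.character, character(1)))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("alignment rows must carry unique taxon names")
  }
  if (length(unique(nchar(seqs))) > 1) stop("alignment rows differ in length")
  if (codon_aware) {
    ungapped <- nchar(gsub("-", "", seqs))
    if (any(ungapped %% 3 != 0)) {
      stop("codon_aware alignment has rows whose ungapped length is not a multiple of 3")
    }
  }
  structure(
    list(gene = gene, taxa = names(seqs), seqs = seqs, codon_aware = codon_aware),
    class = "gene_alignment"
  )
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf(
    "Alignment %s: %d taxa x %d columns%s\n",
    x$gene, length(x$taxa), nchar(x$seqs[1]),
    if (x$codon_aware) " (codon-aware)" else ""
  ))
  invisible(x)
}

#' Read a gene alignment from FASTA
#'
#' @param file aligned FASTA, record ids are taxa.
#' @param gene gene name; defaults to the file name without extension.
#' @param codon_aware see \code{\link{gene_alignment}}.
#' @return a \code{\link{gene_alignment}}.
#' @export
read_gene_alignment <- function(file, gene = NULL, codon_aware = FALSE) {
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(file))
  x <- Biostrings::readDNAStringSet(file)
  gene_alignment(gene, stats::setNames(as.character(x), names(x)), codon_aware)
}

#' Write a gene alignment to FASTA
#' @param aln a \code{\link{gene_alignment}}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
write_gene_alignment <- function(aln, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(aln$seqs), file)
  invisible(file)
}

# character matrix of an alignment (rows = taxa)
.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$seqs), ""))
}

# columns free of gaps and ambiguity across all rows (complete deletion)
.usable_columns <- function(mat) {
  apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
}

#' Nucleotide diversity (Pi)
#'
#' Average over all unordered sequence pairs of the per-site proportion of
#' differences. The default site filter is complete deletion: any column
#' containing a gap or ambiguity in any row is dropped for all pairs (the
#' DnaSP-style default); \code{gap_policy = "pairwise"} instead drops columns
#' per pair.
#'
#' @param aln a \code{\link{gene_alignment}} with >= 2 rows.
#' @param gap_policy \code{"complete"} (default) or \code{"pairwise"}.
#' @return list: \code{pi} (NA when no usable columns), \code{n_sites_used},
#'   \code{n_taxa}.
#' @export
nucleotide_diversity <- function(aln, gap_policy = c("complete", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  mat <- .aln_matrix(aln)
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 sequences")
  if (gap_policy == "complete") {
    keep <- .usable_columns(mat)
    if (!any(keep)) return(list(pi = NA_real_, n_sites_used = 0L, n_taxa = n))
    mat <- mat[, keep, drop = FALSE]
    tot <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        tot <- tot + sum(mat[i, ] != mat[j, ]) / ncol(mat)
      }
    }
    list(
      pi = tot / (n * (n - 1) / 2),
      n_sites_used = ncol(mat), n_taxa = n
    )
  } else {
    props <- c()
    used <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- mat[i, ] %in% c("A", "C", "G", "T") & mat[j, ] %in% c("A", "C", "G", "T")
        if (!any(ok)) next
        props <- c(props, sum(mat[i, ok] != mat[j, ok]) / sum(ok))
        used <- c(used, sum(ok))
      }
    }
    if (!length(props)) return(list(pi = NA_real_, n_sites_used = 0L, n_taxa = n))
    list(pi = mean(props), n_sites_used = as.integer(round(mean(used))), n_taxa = n)
  }
}

#' Variable sites of an alignment
#'
#' Under complete deletion, a usable column (no gaps/ambiguity in any row) is
#' variable iff at least two distinct bases occur in it.
#'
#' @param aln a \code{\link{gene_alignment}} with >= 2 rows.
#' @return list: \code{count}, \code{percent} (of usable columns; NA when no
#'   usable columns), \code{n_sites_used}.
#' @export
variable_sites <- function(aln) {
  mat <- .aln_matrix(aln)
  if (nrow(mat) < 2) stop("need at least 2 sequences")
  keep <- .usable_columns(mat)
  if (!any(keep)) return(list(count = 0L, percent = NA_real_, n_sites_used = 0L))
  mat <- mat[, keep, drop = FALSE]
  var <- apply(mat, 2, function(col) length(unique(col)) > 1)
  list(
    count = sum(var),
    percent = 100 * sum(var) / ncol(mat),
    n_sites_used = ncol(mat)
  )
}

#' Nei-Gojobori (1986) Ka/Ks between two coding sequences
#'
#' Unweighted-pathway Nei-Gojobori with Jukes-Cantor correction. Synonymous
#' sites per codon are the per-position fraction of synonymous single-nt
#' changes, with mutations to stop codons dropped from the denominator (each
#' position still counts one site, so N + S = 3 x codons). Codon pairs
#' differing at several positions are averaged over all minimal pathways,
#' equally weighted, discarding pathways through stop codons. Proportions are
#' corrected by d = -3/4 ln(1 - 4/3 p); p >= 3/4 (saturation) yields NA,
#' never a clamped value.
#'
#' @param cds1,cds2 equal-length, gap-free, in-frame coding sequences;
#'   terminal stop codons are trimmed automatically.
#' @param code a \code{\link{genetic_code}} or NCBI table number (default 2).
#' @return list: \code{ka}, \code{ks}, \code{ka_ks} (NA when ks is 0 or
#'   either rate is undefined), \code{N_sites}, \code{S_sites}, \code{pn},
#'   \code{ps}, \code{nd}, \code{sd}, \code{n_codons}.
#' @export
nei_gojobori <- function(cds1, cds2, code = 2) {
  code <- get_code(code)
  c1 <- split_codons(cds1)
  c2 <- split_codons(cds2)
  if (length(c1$codons) != length(c2$codons)) {
    stop("coding sequences differ in codon count")
  }
  i1 <- match(c1$codons, code$codons)
  i2 <- match(c2$codons, code$codons)
  if (anyNA(i1) || anyNA(i2)) stop("non-ACGT codon in coding sequence")
  # trim terminal stop codons (on either sequence)
  n <- length(i1)
  while (n > 0 && (code$aa[i1[n]] == "*" || code$aa[i2[n]] == "*")) n <- n - 1
  i1 <- i1[seq_len(n)]
  i2 <- i2[seq_len(n)]
  if (n == 0) stop("no sense codons to compare")
  if (any(code$aa[i1] == "*") || any(code$aa[i2] == "*")) {
    stop("internal stop codon in coding sequence")
  }
  S <- (sum(code$syn_sites[i1]) + sum(code$syn_sites[i2])) / 2
  N <- 3 * n - S
  sd <- sum(code$sd_mat[cbind(i1, i2)])
  nd <- sum(code$nd_mat[cbind(i1, i2)])
  ps <- sd / S
  pn <- nd / N
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps)
  ka <- jc(pn)
  ka_ks <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  list(
    ka = ka, ks = ks, ka_ks = ka_ks, N_sites = N, S_sites = S,
    pn = pn, ps = ps, nd = nd, sd = sd, n_codons = n
  )
}

#' Per-gene divergence summary across taxa
#'
#' Computes Pi and variable sites for any alignment; for codon-aware
#' (protein-coding) alignments additionally the per-gene Ka, Ks and Ka/Ks.
#' Pairwise Ka/Ks values are pooled as mean(Ka)/mean(Ks) by default, which
#' keeps pairs with Ks = 0 from dominating; \code{ratio = "mean_of_ratios"}
#' averages defined pairwise ratios instead. For Ka/Ks, codon columns
#' containing a gap or ambiguity in either row of a pair are dropped for that
#' pair. Undefined pairwise values propagate as NA without aborting the batch.
#'
#' @param aln a \code{\link{gene_alignment}}.
#' @param code a \code{\link{genetic_code}} or NCBI table number.
#' @param ratio \code{"mean_ka_over_mean_ks"} (default) or
#'   \code{"mean_of_ratios"}.
#' @param gap_policy site filter for Pi (see
#'   \code{\link{nucleotide_diversity}}).
#' @return one-row data.frame: \code{gene}, \code{pi}, \code{var_site_pct},
#'   \code{ka}, \code{ks}, \code{ka_ks}, \code{purifying} (ka_ks < 1),
#'   \code{n_taxa}, \code{n_sites_used}.
#' @export
gene_divergence_summary <- function(aln, code = 2,
                                    ratio = c("mean_ka_over_mean_ks", "mean_of_ratios"),
                                    gap_policy = "complete") {
  ratio <- match.arg(ratio)
  code <- get_code(code)
  pi <- nucleotide_diversity(aln, gap_policy)
  vs <- variable_sites(aln)
  ka <- ks <- ka_ks <- NA_real_
  if (isTRUE(aln$codon_aware) && length(aln$taxa) >= 2) {
    mat <- .aln_matrix(aln)
    n <- nrow(mat)
    kas <- c(); kss <- c(); ratios <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        pair <- .pair_codon_filter(mat[i, ], mat[j, ])
        if (is.null(pair)) next
        res <- tryCatch(nei_gojobori(pair[1], pair[2], code), error = function(e) NULL)
        if (is.null(res)) next
        kas <- c(kas, res$ka)
        kss <- c(kss, res$ks)
        ratios <- c(ratios, res$ka_ks)
      }
    }
    if (length(kas)) {
      ka <- mean(kas, na.rm = TRUE)
      ks <- mean(kss, na.rm = TRUE)
      ka_ks <- if (ratio == "mean_ka_over_mean_ks") {
        if (is.finite(ks) && ks > 0) ka / ks else NA_real_
      } else {
        if (any(is.finite(ratios))) mean(ratios, na.rm = TRUE) else NA_real_
      }
    }
  }
  data.frame(
    gene = aln$gene, pi = pi$pi, var_site_pct = vs$percent,
    ka = ka, ks = ks, ka_ks = ka_ks,
    purifying = if (is.na(ka_ks)) NA else ka_ks < 1,
    n_taxa = length(aln$taxa), n_sites_used = pi$n_sites_used,
    stringsAsFactors = FALSE
  )
}

# drop codon columns with gaps/ambiguity in either row; returns the two
# cleaned sequences or NULL when nothing remains
.pair_codon_filter <- function(r1, r2) {
  L <- (length(r1) %/% 3) * 3
  if (L == 0) return(NULL)
  ok1 <- r1[seq_len(L)] %in% c("A", "C", "G", "T")
  ok2 <- r2[seq_len(L)] %in% c("A", "C", "G", "T")
  cod_ok <- matrix(ok1 & ok2, nrow = 3)
  keep <- which(apply(cod_ok, 2, all))
  if (!length(keep)) return(NULL)
  idx <- as.vector(vapply(keep, function(k) (k - 1L) * 3L + 1:3, integer(3)))
  c(paste(r1[idx], collapse = ""), paste(r2[idx], collapse = ""))
}

#' Divergence summaries for a batch of gene alignments
#'
#' @param alignments list of \code{\link{gene_alignment}} objects.
#' @param code a \code{\link{genetic_code}} or NCBI table number.
#' @param ... passed to \code{\link{gene_divergence_summary}}.
#' @return data.frame, one row per gene.
#' @export
divergence_table <- function(alignments, code = 2, ...) {
  out <- do.call(rbind, lapply(alignments, gene_divergence_summary, code = code, ...))
  rownames(out) <- NULL
  out
}

#' Write a divergence table as TSV
#'
#' Pi/Ka/Ks at 5 decimals, percentages at 2 - the conventional reporting
#' precision for these statistics.
#'
#' @param div a \code{\link{divergence_table}} result.
#' @param file output path (or \code{""}).
#' @return the TSV text, invisibly.
#' @export
write_divergence_tsv <- function(div, file = "") {
  df <- as.data.frame(div)
  for (col in c("pi", "ka", "ks", "ka_ks")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "NA", sprintf("%.5f", df[[col]]))
  }
  df$var_site_pct <- ifelse(is.na(df$var_site_pct), "NA", sprintf("%.2f", df$var_site_pct))
  keep <- c("gene", "pi", "var_site_pct", "ka", "ks", "ka_ks", "n_taxa")
  txt <- paste(
    c(paste(keep, collapse = "\t"), apply(df[, keep], 1, paste, collapse = "\t")),
    collapse = "\n"
  )
  if (nzchar(file)) writeLines(txt, file)
  invisible(txt)
}
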