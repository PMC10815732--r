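# Base composition, AT/GC content and strand skews. Skews measure strand
# compositional asymmetry: AT-skew = (A - T)/(A + T), GC-skew = (G - C)/(G + C).
# Avian mitogenomes are typically C/A-rich on the reference (heavy) strand,
# giving positive AT-skew and negative GC-skew.

#' Strand skew
#'
#' \code{(a - t) / (a + t)}: for AT-skew pass the A and T counts (or
#' percentages - units cancel), for GC-skew pass G and C. A zero denominator
#' yields \code{NA} (undefined), never 0.
#'
#' @param a_like,t_like non-negative counts or percentages (vectorized).
#' @return numeric in [-1, 1], or \code{NA} where \code{a + t = 0}.
#' @export
skew <- function(a_like, t_like) {
  if (any(a_like < 0 | t_like < 0, na.rm = TRUE)) stop("negative counts")
  denom <- a_like + t_like
  ifelse(denom == 0, NA_real_, (a_like - t_like) / denom)
}

#' Base composition of a nucleotide sequence
#'
#' Counts unambiguous A/C/G/T; IUPAC ambiguity codes are excluded from all
#' denominators (never allocated fractionally) and reported via
#' \code{n_effective}.
#'
#' @param seq nucleotide string.
#' @return one-row data.frame: counts \code{a,c,g,t}; percentages
#'   \code{pct_a..pct_t}; \code{at_content}, \code{gc_content} (percent);
#'   \code{at_skew}, \code{gc_skew}; \code{n_effective}.
#' @export
base_composition <- function(seq) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0) stop("empty sequence")
  v <- strsplit(seq, "")[[1]]
  a <- sum(v == "A"); c_ <- sum(v == "C"); g <- sum(v == "G"); t <- sum(v == "T")
  n_eff <- a + c_ + g + t
  if (n_eff == 0) stop("sequence contains no unambiguous A/C/G/T")
  data.frame(
    a = a, c = c_, g = g, t = t,
    pct_a = 100 * a / n_eff, pct_c = 100 * c_ / n_eff,
    pct_g = 100 * g / n_eff, pct_t = 100 * t / n_eff,
    at_content = 100 * (a + t) / n_eff,
    gc_content = 100 * (g + c_) / n_eff,
    at_skew = skew(a, t), gc_skew = skew(g, c_),
    n_effective = n_eff
  )
}

#' Per-gene composition profile of an annotated mitogenome
#'
#' One row per annotated feature plus three aggregate rows: the concatenated
#' 13 protein-coding genes (\code{"PCGs"}), the concatenated rRNAs
#' (\code{"rRNAs"}) and the whole genome (\code{"genome"}).
#'
#' By default every row is measured on the reference (heavy) strand, so
#' skews are comparable across genes regardless of coding strand;
#' \code{orientation = "coding"} instead measures light-strand genes on their
#' extracted coding strand (which negates their skews).
#'
#' @param genome a \code{\link{mitogenome}}.
#' @param orientation \code{"reference"} (default) or \code{"coding"}.
#' @return data.frame with a \code{region} column followed by the
#'   \code{\link{base_composition}} columns.
#' @export
per_gene_composition <- function(genome, orientation = c("reference", "coding")) {
  orientation <- match.arg(orientation)
  tb <- genome$table
  if (nrow(tb) == 0) stop("genome has no annotation")
  rows <- list()
  for (i in seq_len(nrow(tb))) {
    f <- tb[i, ]
    s <- extract_gene_sequence(genome, f)
    if (orientation == "reference" && f$strand == "-") s <- .revcomp(s)
    rows[[i]] <- cbind(region = f$gene, base_composition(s))
  }
  concat_of <- function(cat) {
    sub <- tb[tb$category == cat, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    seqs <- vapply(seq_len(nrow(sub)), function(i) {
      s <- extract_gene_sequence(genome, sub[i, ])
      if (orientation == "reference" && sub$strand[i] == "-") s <- .revcomp(s)
      s
    }, character(1))
    paste(seqs, collapse = "")
  }
  pcg <- concat_of("PCG")
  rrna <- concat_of("rRNA")
  if (!is.null(pcg)) rows[[length(rows) + 1]] <- cbind(region = "PCGs", base_composition(pcg))
  if (!is.null(rrna)) rows[[length(rows) + 1]] <- cbind(region = "rRNAs", base_composition(rrna))
  rows[[length(rows) + 1]] <- cbind(region = "genome", base_composition(genome$sequence))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between nucleotide content and skew
#'
#' The content-vs-skew scatter across genomes (e.g. %AT vs AT-skew, one point
#' per mitogenome) summarised by its Pearson correlation coefficient. No
#' p-value is computed.
#'
#' @param content,skew numeric vectors of equal length >= 3.
#' @return list with \code{r} (NA when either coordinate has zero variance)
#'   and \code{n}.
#' @export
content_skew_correlation <- function(content, skew) {
  ok <- is.finite(content) & is.finite(skew)
  content <- content[ok]
  skew <- skew[ok]
  if (length(content) < 3) stop("need at least 3 points")
  if (stats::sd(content) == 0 || stats::sd(skew) == 0) {
    return(list(r = NA_real_, n = length(content)))
  }
  list(r = stats::cor(content, skew), n = length(content))
}

#' Write a composition table as TSV
#'
#' Percentages and skews are rounded at this reporting layer only (2 and 4
#' decimals respectively); upstream values keep full precision.
#'
#' @param comp a \code{\link{per_gene_composition}}-style data.frame with a
#'   leading \code{genome} or \code{region} label column.
#' @param file output path (or \code{""}).
#' @return the TSV text, invisibly.
#' @export
write_composition_tsv <- function(comp, file = "") {
  df <- as.data.frame(comp)
  for (col in c("pct_a", "pct_c", "pct_g", "pct_t", "at_content", "gc_content")) {
    df[[col]] <- sprintf("%.2f", df[[col]])
  }
  for (col in c("at_skew", "gc_skew")) df[[col]] <- sprintf("%.4f", df[[col]])
  keep <- c(
    names(df)[1], "pct_a", "pct_c", "pct_g", "pct_t",
    "at_content", "gc_content", "at_skew", "gc_skew", "n_effective"
  )
  df <- df[, keep]
  txt <- paste(
    c(paste(keep, collapse = "\t"), apply(df, 1, paste, collapse = "\t")),
    collapse = "\n"
  )
  if (nzchar(file)) writeLines(txt, file)
  invisible(txt)
}
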