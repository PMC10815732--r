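# Codon-level statistics under the vertebrate mitochondrial genetic code:
# codon splitting with incomplete-stop handling, start/stop classification,
# usage counts, amino-acid usage and relative synonymous codon usage (RSCU).

#' Split a coding sequence into codons and a trailing remnant
#'
#' Mitochondrial protein-coding genes frequently end on an incomplete stop
#' codon ("T" or "TA", completed to TAA by polyadenylation of the mRNA), so a
#' CDS length need not be a multiple of three. The remnant carries those
#' trailing 1-2 nucleotides.
#'
#' @param cds strand-correct coding sequence (DNA alphabet).
#' @return list with \code{codons} (character vector of triplets, read from
#'   position 1) and \code{remnant} (\code{""} when length is a multiple of 3).
#' @export
split_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n == 0) stop("empty coding sequence")
  n_cod <- n %/% 3
  codons <- if (n_cod > 0) {
    substring(cds, seq(1, by = 3, length.out = n_cod), seq(3, by = 3, length.out = n_cod))
  } else {
    character(0)
  }
  list(codons = codons, remnant = if (n %% 3) substr(cds, n_cod * 3 + 1, n) else "")
}

#' Detect and classify the start and stop codon of a CDS
#'
#' The start is the first triplet, classified as canonical ATG, alternative
#' (another initiation codon of the active genetic code, e.g. GTG), or
#' non-standard. The stop token is the trailing remnant ("T"/"TA", a truncated
#' stop) when the length is not a multiple of three, otherwise the final
#' triplet, which is checked against the code's stop set.
#'
#' @param cds strand-correct coding sequence, length >= 6.
#' @param code a \code{\link{genetic_code}} or NCBI table number (default 2).
#' @return list: \code{start}, \code{start_class}, \code{stop} (token),
#'   \code{stop_truncated} (logical), \code{stop_is_valid} (complete stop in
#'   the code's stop set, or a truncated T/TA).
#' @export
detect_start_stop <- function(cds, code = 2) {
  code <- get_code(code)
  cds <- toupper(as.character(cds))
  if (nchar(cds) < 6) stop("coding sequence shorter than 6 nt")
  sp <- split_codons(cds)
  start <- sp$codons[1]
  start_class <- if (start == "ATG") {
    "canonical-ATG"
  } else if (start %in% code$starts) {
    "alternative"
  } else {
    "non-standard"
  }
  if (nzchar(sp$remnant)) {
    stop_token <- sp$remnant
    truncated <- TRUE
    valid <- stop_token %in% c("T", "TA")
  } else {
    stop_token <- sp$codons[length(sp$codons)]
    truncated <- FALSE
    valid <- stop_token %in% code$stops
  }
  list(
    start = start, start_class = start_class,
    stop = stop_token, stop_truncated = truncated, stop_is_valid = valid
  )
}

#' Count codon usage over a set of coding sequences
#'
#' Sums full codons across genes; trailing remnants (truncated stops) are
#' never counted. With \code{include_stops = TRUE} complete stop triplets are
#' counted, so the total equals \code{sum(floor(length/3))} over the input -
#' the convention behind headline "total codons" figures for mitogenomes.
#'
#' @param cds_set character vector or list of strand-correct coding sequences.
#' @param code a \code{\link{genetic_code}} or NCBI table number.
#' @param include_stops count complete stop triplets (default TRUE).
#' @return object of class \code{"codon_usage"}: list with \code{counts}
#'   (named integer vector over the 64 codons), \code{total_codons},
#'   \code{include_stops} and \code{code_id}.
#' @export
count_codons <- function(cds_set, code = 2, include_stops = TRUE) {
  code <- get_code(code)
  cds_set <- unlist(cds_set, use.names = FALSE)
  counts <- stats::setNames(integer(64), code$codons)
  for (cds in cds_set) {
    cod <- split_codons(cds)$codons
    if (!all(cod %in% code$codons)) {
      bad <- cod[!cod %in% code$codons][1]
      stop("non-ACGT codon '", bad, "' in coding sequence")
    }
    t <- table(cod)
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  if (!include_stops) counts[code$stops] <- 0L
  structure(
    list(
      counts = counts, total_codons = sum(counts),
      include_stops = include_stops, code_id = code$id
    ),
    class = "codon_usage"
  )
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf(
    "Codon usage: %d codons over %d distinct triplets (stops %s)\n",
    x$total_codons, sum(x$counts > 0),
    if (x$include_stops) "included" else "excluded"
  ))
  invisible(x)
}

#' Amino-acid usage from codon usage
#'
#' Pools codon counts by encoded amino acid (Leu pools all six Leu codons
#' under the vertebrate mitochondrial code). Stop codons are reported
#' separately under \code{"Ter"}, never merged into an amino-acid family.
#'
#' @param usage a \code{\link{count_codons}} result.
#' @param code a \code{\link{genetic_code}}; defaults to the usage's code.
#' @return named integer vector of counts per amino acid (one-letter codes),
#'   with attribute \code{"Ter"} holding the stop-triplet count.
#' @export
amino_acid_usage <- function(usage, code = NULL) {
  code <- get_code(if (is.null(code)) usage$code_id else code)
  aa <- code$aa[names(usage$counts)]
  sense <- aa != "*"
  out <- tapply(usage$counts[sense], aa[sense], sum)
  out <- stats::setNames(as.integer(out), names(out))
  attr(out, "Ter") <- sum(usage$counts[!sense])
  out
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon c in a synonymous family of size k with family total n,
#' RSCU(c) = k * count(c) / n: the observed count relative to the expectation
#' under uniform usage within the family. RSCU > 1 marks an over-used codon.
#' Stop codons are excluded from families; a family with zero total usage gets
#' RSCU 0 for all its codons and is flagged.
#'
#' @param usage a \code{\link{count_codons}} result.
#' @param code a \code{\link{genetic_code}}; defaults to the usage's code.
#' @return data.frame (class \code{"rscu_table"}) with columns \code{codon},
#'   \code{aa}, \code{family_size}, \code{count}, \code{rscu},
#'   \code{zero_family}; rows in codon order, stop codons omitted.
#' @export
compute_rscu <- function(usage, code = NULL) {
  code <- get_code(if (is.null(code)) usage$code_id else code)
  rows <- list()
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    k <- length(fam)
    cnt <- usage$counts[fam]
    tot <- sum(cnt)
    rscu <- if (tot > 0) as.numeric(cnt) * k / tot else rep(0, k)
    rows[[aa]] <- data.frame(
      codon = fam, aa = aa, family_size = k, count = as.integer(cnt),
      rscu = rscu, zero_family = tot == 0, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$codon, code$codons)), ]
  rownames(out) <- NULL
  class(out) <- c("rscu_table", "data.frame")
  out
}

#' Write a codon usage / RSCU table as TSV
#'
#' @param rscu a \code{\link{compute_rscu}} result.
#' @param file path (or \code{""} to only return the text).
#' @param rna display codons in RNA alphabet (T -> U), as codon-usage figures
#'   conventionally do.
#' @return the TSV text, invisibly.
#' @export
write_codon_usage <- function(rscu, file = "", rna = TRUE) {
  df <- as.data.frame(rscu)
  if (rna) df$codon <- chartr("T", "U", df$codon)
  df$rscu <- sprintf("%.4f", df$rscu)
  txt <- paste(
    c(
      paste(c("codon", "aa", "count", "rscu"), collapse = "\t"),
      apply(df[, c("codon", "aa", "count", "rscu")], 1, paste, collapse = "\t")
    ),
    collapse = "\n"
  )
  if (nzchar(file)) writeLines(txt, file)
  invisible(txt)
}
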