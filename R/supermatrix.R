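# Concatenation of per-gene alignments into a partitioned supermatrix, the
# standard input for partitioned phylogenetic inference (RAxML/IQ-TREE/MrBayes).

#' Concatenate gene alignments into a partitioned supermatrix
#'
#' Partitions tile the matrix 1..L in input gene order with no gaps or
#' overlap. Under the \code{"union"} taxa policy a taxon absent from a gene
#' gets \code{"?"} (missing data, deliberately distinct from the alignment
#' gap \code{"-"}) across that gene's columns; under \code{"intersection"}
#' only taxa present in every gene are kept.
#'
#' @param alignments non-empty list of \code{\link{gene_alignment}} objects.
#' @param taxa_policy \code{"intersection"} (default) or \code{"union"}.
#' @return object of class \code{"supermatrix"}: list with \code{taxa},
#'   \code{matrix} (named character vector of concatenated rows),
#'   \code{partitions} (data.frame name/start/end, 1-based inclusive).
#' @export
concatenate_alignments <- function(alignments, taxa_policy = c("intersection", "union")) {
  taxa_policy <- match.arg(taxa_policy)
  if (!length(alignments)) stop("empty alignment list")
  taxa_sets <- lapply(alignments, function(a) a$taxa)
  for (a in alignments) {
    if (anyDuplicated(a$taxa)) stop("duplicate taxon ids in gene ", a$gene)
  }
  taxa <- if (taxa_policy == "intersection") {
    Reduce(intersect, taxa_sets)
  } else {
    unique(unlist(taxa_sets))
  }
  if (!length(taxa)) stop("no taxa shared across alignments")
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- data.frame(
    name = character(), start = integer(), end = integer(),
    stringsAsFactors = FALSE
  )
  pos <- 0L
  for (a in alignments) {
    len <- nchar(a$seqs[1])
    fill <- strrep("?", len)
    for (tx in taxa) {
      rows[tx] <- paste0(rows[tx], if (tx %in% a$taxa) a$seqs[tx] else fill)
    }
    parts <- rbind(parts, data.frame(
      name = a$gene, start = pos + 1L, end = pos + len,
      stringsAsFactors = FALSE
    ))
    pos <- pos + len
  }
  rownames(parts) <- NULL
  structure(list(taxa = taxa, matrix = rows, partitions = parts),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf(
    "Supermatrix: %d taxa x %d bp, %d partitions\n",
    length(x$taxa), nchar(x$matrix[1]), nrow(x$partitions)
  ))
  invisible(x)
}

#' Extract one partition of a supermatrix as a gene alignment
#'
#' @param sm a \code{\link{concatenate_alignments}} result.
#' @param k partition index or name.
#' @return a \code{\link{gene_alignment}}.
#' @export
extract_partition <- function(sm, k) {
  if (is.character(k)) k <- match(k, sm$partitions$name)
  p <- sm$partitions[k, ]
  gene_alignment(p$name, vapply(sm$matrix, substr, "", p$start, p$end))
}

#' Write a partition definition file
#'
#' RAxML dialect: one \code{"DNA, <gene> = <start>-<end>"} line per
#' partition; NEXUS dialect: a \code{sets} block with one \code{charset} per
#' partition. Output is byte-stable for a fixed supermatrix.
#'
#' @param sm a \code{\link{concatenate_alignments}} result.
#' @param dialect \code{"raxml"} or \code{"nexus"}.
#' @param file output path (or \code{""} to only return the text).
#' @return the partition text, invisibly.
#' @export
write_partitions <- function(sm, dialect = c("raxml", "nexus"), file = "") {
  dialect <- match.arg(dialect)
  p <- sm$partitions
  txt <- if (dialect == "raxml") {
    paste(sprintf("DNA, %s = %d-%d", p$name, p$start, p$end), collapse = "\n")
  } else {
    paste(
      c(
        "#nexus", "begin sets;",
        sprintf("    charset %s = %d-%d;", p$name, p$start, p$end),
        "end;"
      ),
      collapse = "\n"
    )
  }
  if (nzchar(file)) writeLines(txt, file)
  invisible(txt)
}

#' Write a supermatrix as FASTA or relaxed PHYLIP
#'
#' @param sm a \code{\link{concatenate_alignments}} result.
#' @param file output path.
#' @param format \code{"fasta"} or \code{"phylip"} (relaxed: full taxon
#'   names, two header fields).
#' @return invisibly, \code{file}.
#' @export
write_supermatrix <- function(sm, file, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(
      as.vector(rbind(paste0(">", sm$taxa), unname(sm$matrix[sm$taxa]))),
      file
    )
  } else {
    writeLines(
      c(
        sprintf("%d %d", length(sm$taxa), nchar(sm$matrix[1])),
        sprintf("%s  %s", sm$taxa, unname(sm$matrix[sm$taxa]))
      ),
      file
    )
  }
  invisible(file)
}

#' Read a supermatrix back from FASTA (+ optional RAxML partition file)
#'
#' @param fasta path to a FASTA written by \code{\link{write_supermatrix}}.
#' @param partitions optional path to a RAxML-dialect partition file.
#' @return a \code{\link{concatenate_alignments}}-compatible
#'   \code{supermatrix} (partitions empty when no file given).
#' @export
read_supermatrix_fasta <- function(fasta, partitions = NULL) {
  x <- Biostrings::readBStringSet(fasta)
  rows <- stats::setNames(as.character(x), names(x))
  parts <- data.frame(name = character(), start = integer(), end = integer(),
    stringsAsFactors = FALSE)
  if (!is.null(partitions)) {
    for (ln in readLines(partitions)) {
      m <- regmatches(ln, regexec("^DNA,\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)\\s*$", ln))[[1]]
      if (length(m)) {
        parts <- rbind(parts, data.frame(
          name = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  structure(list(taxa = names(rows), matrix = rows, partitions = parts),
    class = "supermatrix"
  )
}

#' Write a JSON manifest for a supermatrix
#'
#' Records gene order, per-gene lengths and coordinates, and the taxon set.
#'
#' @param sm a \code{\link{concatenate_alignments}} result.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
write_supermatrix_manifest <- function(sm, file) {
  p <- sm$partitions
  jsonlite::write_json(
    list(
      n_taxa = length(sm$taxa),
      taxa = sm$taxa,
      total_length = nchar(sm$matrix[1]),
      genes = lapply(seq_len(nrow(p)), function(i) {
        list(
          name = p$name[i], start = p$start[i], end = p$end[i],
          length = p$end[i] - p$start[i] + 1L
        )
      })
    ),
    file,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(file)
}
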