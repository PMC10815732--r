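# Canonical gene inventory of the vertebrate mitogenome ----------------------

PCG_NAMES <- c(
  "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
  "COX1", "COX2", "COX3", "ATP6", "ATP8", "Cytb"
)
RRNA_NAMES <- c("rrnS", "rrnL")
TRNA_NAMES <- c(
  "trnF", "trnV", "trnL1", "trnL2", "trnI", "trnQ", "trnM", "trnW", "trnA",
  "trnN", "trnC", "trnY", "trnS1", "trnS2", "trnD", "trnK", "trnG", "trnR",
  "trnH", "trnT", "trnP", "trnE"
)

# The ancestral avian mitochondrial gene arrangement, written from trnF to the
# control region; comparisons against it are cyclic so any rotation matches.
AVIAN_GENE_ORDER <- c(
  "trnF", "rrnS", "trnV", "rrnL", "trnL2", "ND1", "trnI", "trnQ", "trnM",
  "ND2", "trnW", "trnA", "trnN", "trnC", "trnY", "COX1", "trnS2", "trnD",
  "COX2", "trnK", "ATP8", "ATP6", "COX3", "trnG", "ND3", "trnR", "ND4L",
  "ND4", "trnH", "trnS1", "trnL1", "ND5", "Cytb", "trnT", "trnP", "ND6",
  "trnE", "D-loop"
)

.name_synonyms <- c(
  "COI" = "COX1", "COII" = "COX2", "COIII" = "COX3",
  "CO1" = "COX1", "CO2" = "COX2", "CO3" = "COX3",
  "COX1" = "COX1", "COX2" = "COX2", "COX3" = "COX3",
  "CYTB" = "Cytb", "COB" = "Cytb", "CYB" = "Cytb",
  "12S" = "rrnS", "16S" = "rrnL", "RRN12" = "rrnS", "RRN16" = "rrnL",
  "S-RRNA" = "rrnS", "L-RRNA" = "rrnL", "RRNS" = "rrnS", "RRNL" = "rrnL",
  "12S RRNA" = "rrnS", "16S RRNA" = "rrnL",
  "ATPASE6" = "ATP6", "ATPASE8" = "ATP8", "ATP6" = "ATP6", "ATP8" = "ATP8",
  "D-LOOP" = "D-loop", "DLOOP" = "D-loop", "CR" = "D-loop",
  "CONTROL REGION" = "D-loop", "CONTROL-REGION" = "D-loop",
  "NAD1" = "ND1", "NAD2" = "ND2", "NAD3" = "ND3", "NAD4" = "ND4",
  "NAD4L" = "ND4L", "NAD5" = "ND5", "NAD6" = "ND6"
)

.trna_aa_map <- c(
  "PHE" = "trnF", "VAL" = "trnV", "ILE" = "trnI", "GLN" = "trnQ",
  "MET" = "trnM", "TRP" = "trnW", "ALA" = "trnA", "ASN" = "trnN",
  "CYS" = "trnC", "TYR" = "trnY", "ASP" = "trnD", "LYS" = "trnK",
  "GLY" = "trnG", "ARG" = "trnR", "HIS" = "trnH", "THR" = "trnT",
  "PRO" = "trnP", "GLU" = "trnE"
)

#' Normalize a mitochondrial gene name
#'
#' Maps common synonyms (COI/COX1, CYTB/Cytb, 12S/rrnS, tRNA-Phe/trnF, ...)
#' onto the canonical names used throughout the package. Unknown names pass
#' through unchanged.
#'
#' @param x character vector of gene names.
#' @return character vector of canonical names.
#' @export
normalize_gene_name <- function(x) {
  out <- as.character(x)
  canon <- c(PCG_NAMES, RRNA_NAMES, TRNA_NAMES, "D-loop")
  for (i in seq_along(out)) {
    nm <- trimws(out[i])
    up <- toupper(nm)
    hit <- match(up, toupper(canon))
    if (!is.na(hit)) {
      out[i] <- canon[hit]
      next
    }
    if (up %in% names(.name_synonyms)) {
      out[i] <- unname(.name_synonyms[up])
      next
    }
    # tRNA-Phe, trnF(gaa), tRNA-Leu(UUR)/(CUN), trnL2 ...
    if (grepl("^TRN|^TRNA", up)) {
      core <- sub("\\(.*\\)$", "", nm)
      core <- sub("^tRNA[-_ ]?", "trn", core, ignore.case = TRUE)
      core <- sub("^trn", "trn", core, ignore.case = TRUE)
      aa3 <- toupper(sub("^trn", "", core))
      if (aa3 %in% names(.trna_aa_map)) {
        out[i] <- unname(.trna_aa_map[aa3])
      } else if (aa3 %in% c("LEU", "L")) {
        out[i] <- if (grepl("CUN|L1|TAG|UAG", up)) "trnL1" else "trnL2"
      } else if (aa3 %in% c("SER", "S")) {
        out[i] <- if (grepl("AGY|S1|GCT|GCU", up)) "trnS1" else "trnS2"
      } else {
        cand <- paste0("trn", substr(sub("^trn", "", core), 1, 2))
        out[i] <- if (cand %in% TRNA_NAMES) cand else core
      }
      next
    }
  }
  out
}

#' Categorize gene names
#'
#' @param name character vector of (canonical) gene names.
#' @return one of \code{"PCG"}, \code{"tRNA"}, \code{"rRNA"},
#'   \code{"control-region"}, \code{"other"} per element.
#' @export
gene_category <- function(name) {
  name <- normalize_gene_name(name)
  ifelse(name %in% PCG_NAMES, "PCG",
    ifelse(name %in% TRNA_NAMES, "tRNA",
      ifelse(name %in% RRNA_NAMES, "rRNA",
        ifelse(name == "D-loop", "control-region", "other")
      )
    )
  )
}

# gene_table S3 --------------------------------------------------------------

#' Construct a gene table
#'
#' A gene table is the annotated layout of a circular mitogenome: an ordered
#' data frame of features with 1-based, fully inclusive coordinates (the
#' GenBank convention), one row per gene or region.
#'
#' @param features data.frame with at least \code{gene}, \code{start},
#'   \code{end}, \code{strand} (\code{"+"} heavy / \code{"-"} light); optional
#'   \code{category}, \code{anticodon}, \code{start_codon}, \code{stop_codon},
#'   \code{length} (printed length, cross-checked against coordinates).
#' @param genome_length total length in bp; defaults to \code{max(end)}.
#' @return object of class \code{"gene_table"}: the feature data frame with a
#'   computed \code{length} column, plus attributes \code{genome_length} and
#'   \code{discrepancies} (rows whose printed length disagrees with
#'   coordinate arithmetic).
#' @export
gene_table <- function(features, genome_length = NULL) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0) {
    out <- data.frame(
      gene = character(), category = character(), start = integer(),
      end = integer(), strand = character(), length = integer(),
      stringsAsFactors = FALSE
    )
    attr(out, "genome_length") <- if (is.null(genome_length)) 0L else as.integer(genome_length)
    attr(out, "discrepancies") <- out[0, ]
    class(out) <- c("gene_table", "data.frame")
    return(out)
  }
  req <- c("gene", "start", "end", "strand")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols)) {
    stop("gene table lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  features$gene <- normalize_gene_name(features$gene)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (!all(features$strand %in% c("+", "-"))) {
    bad <- which(!features$strand %in% c("+", "-"))[1]
    stop("unknown strand symbol '", features$strand[bad], "' in row ", bad,
      " (", features$gene[bad], ")")
  }
  if (is.null(genome_length)) genome_length <- max(features$end)
  genome_length <- as.integer(genome_length)
  if (any(features$start < 1 | features$start > genome_length |
    features$end < 1 | features$end > genome_length)) {
    stop("coordinates outside [1, ", genome_length, "]")
  }
  dup <- features$gene[duplicated(features$gene) &
    features$gene %in% c(PCG_NAMES, RRNA_NAMES, TRNA_NAMES, "D-loop")]
  if (length(dup)) stop("duplicate canonical gene name(s): ", paste(unique(dup), collapse = ", "))

  if (is.null(features$category)) features$category <- gene_category(features$gene)
  printed <- if ("length" %in% names(features)) suppressWarnings(as.integer(features$length)) else NULL
  features$length <- gene_length(features$start, features$end, genome_length)

  disc <- features[0, ]
  if (!is.null(printed)) {
    bad <- which(!is.na(printed) & printed != features$length)
    if (length(bad)) {
      disc <- features[bad, ]
      disc$printed_length <- printed[bad]
    }
  }
  attr(features, "genome_length") <- genome_length
  attr(features, "discrepancies") <- disc
  class(features) <- c("gene_table", "data.frame")
  features
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf(
    "Gene table: %d features, genome length %d bp\n",
    nrow(x), genome_length_of(x)
  ))
  NextMethod()
}

#' Genome length recorded on a gene table or mitogenome
#' @param x a \code{gene_table} or \code{mitogenome}.
#' @return integer length in bp.
#' @export
genome_length_of <- function(x) {
  if (inherits(x, "mitogenome")) return(nchar(x$sequence))
  as.integer(attr(x, "genome_length"))
}

#' Printed-length discrepancies recorded while building a gene table
#' @param x a \code{gene_table}.
#' @return data.frame of rows whose printed length disagreed with coordinates.
#' @export
length_discrepancies <- function(x) attr(x, "discrepancies")

#' Length of a gene on a circular genome
#'
#' Coordinates are 1-based and fully inclusive. A feature with
#' \code{end < start} wraps across the origin, so its length is
#' \code{(genome_length - start + 1) + end}.
#'
#' @param start,end 1-based inclusive coordinates (vectorized).
#' @param genome_length total genome length in bp.
#' @return integer vector of lengths.
#' @export
gene_length <- function(start, end, genome_length) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 1 | end < 1 | start > genome_length | end > genome_length)) {
    stop("coordinates outside [1, ", genome_length, "]")
  }
  as.integer(ifelse(end >= start, end - start + 1L,
    (genome_length - start + 1L) + end))
}

# parsing --------------------------------------------------------------------

.clean_coord <- function(x) {
  x <- gsub("[, ]", "", x)       # thousands separators
  gsub("[–—−]", "-", x) # en/em dashes, minus sign
}

#' Parse a gene feature table from TSV text
#'
#' Accepts the documented dialect (columns \code{gene}, \code{start},
#' \code{end}, \code{strand}, optional \code{category}, \code{length},
#' \code{start_codon}, \code{stop_codon}, \code{anticodon}; header required;
#' UTF-8) and, alternatively, a \code{location} column holding
#' \code{"start-end: strand"} strings as printed in annotation tables
#' (thousands separators and en/em dashes are stripped). When a length column
#' is present it is cross-checked against coordinate arithmetic and
#' disagreements are recorded (see \code{\link{length_discrepancies}}), not
#' resolved.
#'
#' @param text either a file path or a character scalar of TSV content.
#' @param genome_length optional; defaults to \code{max(end)}.
#' @return a \code{\link{gene_table}}.
#' @export
parse_feature_table <- function(text, genome_length = NULL) {
  if (length(text) == 1 && !grepl("[\t\n]", text) && file.exists(text)) {
    lines <- readLines(text, encoding = "UTF-8")
  } else {
    lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(gene_table(data.frame(), genome_length))
  }
  df <- utils::read.delim(
    text = paste(lines, collapse = "\n"),
    stringsAsFactors = FALSE, check.names = FALSE,
    colClasses = "character", na.strings = c("NA", "")
  )
  names(df) <- tolower(trimws(names(df)))
  if ("location" %in% names(df) && !all(c("start", "end") %in% names(df))) {
    loc <- .clean_coord(df$location)
    m <- regmatches(loc, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*(?::\\s*([+-]))?\\s*$", loc))
    bad <- which(vapply(m, length, 1L) == 0)
    if (length(bad)) {
      stop("malformed coordinates in row ", bad[1], " ('", df$location[bad[1]], "')")
    }
    df$start <- vapply(m, `[`, "", 2)
    df$end <- vapply(m, `[`, "", 3)
    st <- vapply(m, `[`, "", 4)
    if (!"strand" %in% names(df)) df$strand <- st
  }
  for (col in c("start", "end")) {
    if (!col %in% names(df)) stop("feature table lacks column '", col, "'")
    raw <- .clean_coord(df[[col]])
    val <- suppressWarnings(as.integer(raw))
    if (any(is.na(val))) {
      bad <- which(is.na(val))[1]
      stop("malformed coordinates in row ", bad, " (", df$gene[bad], ": '",
        df[[col]][bad], "')")
    }
    df[[col]] <- val
  }
  if ("length" %in% names(df)) df$length <- suppressWarnings(as.integer(.clean_coord(df$length)))
  df$strand <- trimws(df$strand)
  gene_table(df, genome_length)
}

#' Write a gene table as normalized TSV
#'
#' Round-trips through \code{\link{parse_feature_table}}.
#'
#' @param table a \code{gene_table}.
#' @param file path (or \code{""} to return the text invisibly).
#' @return the TSV text, invisibly.
#' @export
write_feature_table <- function(table, file = "") {
  cols <- intersect(
    c("gene", "start", "end", "strand", "category", "length",
      "start_codon", "stop_codon", "anticodon"),
    names(table)
  )
  df <- as.data.frame(table)[, cols, drop = FALSE]
  txt <- paste(
    c(paste(cols, collapse = "\t"),
      apply(df, 1, function(r) paste(ifelse(is.na(r), "", trimws(r)), collapse = "\t"))),
    collapse = "\n"
  )
  if (nzchar(file)) writeLines(txt, file, useBytes = TRUE)
  invisible(txt)
}

# mitogenome S3 --------------------------------------------------------------

#' Construct a mitogenome: a circular sequence bound to its gene table
#'
#' @param id accession or label.
#' @param sequence nucleotide string (IUPAC letters); stored uppercase.
#' @param table a \code{\link{gene_table}} whose \code{genome_length} equals
#'   \code{nchar(sequence)}.
#' @return object of class \code{"mitogenome"}.
#' @export
mitogenome <- function(id, sequence, table) {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGTURYSWKMBDHVN]*$", sequence)) {
    stop("sequence contains non-IUPAC characters")
  }
  if (nchar(sequence) != genome_length_of(table)) {
    stop(
      "sequence length (", nchar(sequence), ") does not match gene table genome length (",
      genome_length_of(table), ")"
    )
  }
  structure(list(id = id, sequence = sequence, table = table),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf(
    "Mitogenome %s: %d bp circular, %d annotated features\n",
    x$id, nchar(x$sequence), nrow(x$table)
  ))
  invisible(x)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract the strand-correct sequence of a gene
#'
#' Heavy-strand features return the reference subsequence \code{start..end}
#' (wrapping across the origin when \code{end < start}); light-strand features
#' return its reverse complement, i.e. the coding-strand reading of the gene.
#'
#' @param genome a \code{\link{mitogenome}}.
#' @param feature a gene name present in the table, or a one-row feature
#'   (list/data.frame with \code{start}, \code{end}, \code{strand}).
#' @return nucleotide string of length \code{\link{gene_length}}.
#' @export
extract_gene_sequence <- function(genome, feature) {
  if (is.character(feature) && length(feature) == 1) {
    hit <- which(genome$table$gene == normalize_gene_name(feature))
    if (!length(hit)) stop("gene '", feature, "' not in annotation")
    feature <- genome$table[hit[1], ]
  }
  L <- nchar(genome$sequence)
  s <- as.integer(feature$start)
  e <- as.integer(feature$end)
  if (s < 1 || e < 1 || s > L || e > L) stop("feature outside [1, ", L, "]")
  seq <- if (e >= s) {
    substr(genome$sequence, s, e)
  } else {
    paste0(substr(genome$sequence, s, L), substr(genome$sequence, 1, e))
  }
  if (identical(as.character(feature$strand), "-")) seq <- .revcomp(seq)
  seq
}

#' Count heavy- and light-strand genes
#'
#' Tallies the 37 genes of a mitogenome annotation by strand; the control
#' region and unrecognized features are excluded from the census.
#'
#' @param table a \code{\link{gene_table}}.
#' @return list with \code{heavy}, \code{light} counts and
#'   \code{light_genes} (names of light-strand genes).
#' @export
strand_census <- function(table) {
  genes <- table[table$category %in% c("PCG", "tRNA", "rRNA"), ]
  light <- genes$gene[genes$strand == "-"]
  list(
    heavy = sum(genes$strand == "+"),
    light = length(light),
    light_genes = light
  )
}

#' Check a gene table against the ancestral avian gene order
#'
#' Compares the cyclic sequence of gene names against the ancestral avian
#' arrangement (trnF, rrnS, ..., Cytb, trnT, trnP, ND6, trnE, D-loop). The
#' comparison is rotation-invariant: the observed order is rotated to its
#' best-matching phase before positions are compared.
#'
#' @param table a complete \code{\link{gene_table}} (13 PCG + 22 tRNA +
#'   2 rRNA + control region).
#' @return list: \code{is_ancestral_avian} (all 38 positions match),
#'   \code{n_matched}, \code{mismatches} (data.frame of position, expected,
#'   observed).
#' @export
validate_avian_order <- function(table) {
  observed <- table$gene[table$category %in% c("PCG", "tRNA", "rRNA", "control-region")]
  missing <- setdiff(AVIAN_GENE_ORDER, observed)
  if (length(missing)) {
    stop(
      "incomplete gene table; missing canonical genes: ",
      paste(missing, collapse = ", ")
    )
  }
  n <- length(AVIAN_GENE_ORDER)
  best <- list(matched = -1L)
  for (rot in seq_len(length(observed))) {
    obs <- c(observed[rot:length(observed)], observed[seq_len(rot - 1)])[seq_len(n)]
    matched <- sum(obs == AVIAN_GENE_ORDER)
    if (matched > best$matched) best <- list(matched = matched, obs = obs)
  }
  mism <- which(best$obs != AVIAN_GENE_ORDER)
  list(
    is_ancestral_avian = length(mism) == 0 && length(observed) == n,
    n_matched = best$matched,
    mismatches = data.frame(
      position = mism,
      expected = AVIAN_GENE_ORDER[mism],
      observed = best$obs[mism],
      stringsAsFactors = FALSE
    )
  )
}

#' Write every annotated gene of a mitogenome to FASTA
#'
#' One record per feature, id \code{"<genome_id>|<gene>"}, strand-correct
#' sequences (light-strand genes reverse-complemented).
#'
#' @param genome a \code{\link{mitogenome}}.
#' @param file output FASTA path.
#' @return invisibly, the named character vector of sequences.
#' @export
genes_to_fasta <- function(genome, file) {
  seqs <- vapply(
    seq_len(nrow(genome$table)),
    function(i) extract_gene_sequence(genome, genome$table[i, ]),
    character(1)
  )
  names(seqs) <- paste0(genome$id, "|", genome$table$gene)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file)
  invisible(seqs)
}

# Bundled annotation tables --------------------------------------------------

#' Bundled Tarsiger gene tables
#'
#' The published mitogenome annotations of \emph{Tarsiger indicus}
#' (GenBank OR459825, 16,723 bp) and \emph{T. cyanurus} (KF997864, 16,803 bp):
#' gene coordinates, strands, printed lengths, start/stop codons and tRNA
#' anticodons.
#'
#' @param species \code{"indicus"} or \code{"cyanurus"}.
#' @return a \code{\link{gene_table}}.
#' @export
tarsiger_gene_table <- function(species = c("indicus", "cyanurus")) {
  species <- match.arg(species)
  path <- system.file("extdata",
    paste0("tarsiger_", species, "_genes.tsv"),
    package = "mitocomp", mustWork = TRUE
  )
  parse_feature_table(path)
}
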