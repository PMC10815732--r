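# Minimal GenBank flat-file dialect: LOCUS / FEATURES / ORIGIN. Enough to
# round-trip the annotated genomes this package writes and to ingest typical
# mitogenome records. Join/complement locations spanning the origin are
# supported; anything fancier (multi-interval CDS, fuzzy coordinates) is out
# of scope and rejected with a clear message.

.gb_feature_keys <- c(
  "gene", "CDS", "tRNA", "rRNA", "D-loop", "misc_feature", "source"
)

#' Read a mitogenome from a GenBank flat file
#'
#' Parses LOCUS (id, length, circular flag), the FEATURES table (CDS, tRNA,
#' rRNA, D-loop/misc_feature; \code{complement(a..b)} for light-strand genes;
#' \code{join(a..L,1..b)} for origin-spanning features) and the ORIGIN
#' sequence block. Gene names are taken from \code{/gene=} or \code{/product=}
#' qualifiers and normalized.
#'
#' @param file path to a GenBank flat file.
#' @return a \code{\link{mitogenome}}.
#' @export
read_genbank <- function(file) {
  lines <- readLines(file, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", file)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("no ORIGIN block in ", file)
  seq_lines <- lines[(ostart[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1):(ostart[1] - 1)]
    cur <- NULL
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) { # new feature
        if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
        key <- trimws(substr(ln, 1, 20))
        loc <- trimws(substr(ln, 21, nchar(ln)))
        cur <- list(key = key, loc = loc, quals = character())
      } else if (!is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) {
          cur$quals <- c(cur$quals, txt)
        } else {
          cur$loc <- paste0(cur$loc, txt) # continuation of a location
        }
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
  }

  rows <- list()
  for (f in feats) {
    if (!f$key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
    p <- .gb_parse_location(f$loc, nchar(sequence))
    gene <- NA_character_
    anticodon <- NA_character_
    for (q in f$quals) {
      if (grepl("^/gene=", q)) gene <- gsub('^/gene="?|"$', "", q)
      if (is.na(gene) && grepl("^/product=", q)) gene <- gsub('^/product="?|"$', "", q)
      if (grepl("^/note=\"?anticodon:", q)) {
        anticodon <- sub('^/note="?anticodon:([a-zA-Z]+)"?$', "\\1", q)
      }
    }
    if (is.na(gene) && f$key %in% c("D-loop", "misc_feature")) gene <- "D-loop"
    if (is.na(gene)) next
    rows[[length(rows) + 1]] <- data.frame(
      gene = gene, start = p$start, end = p$end, strand = p$strand,
      anticodon = anticodon, stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  # a record may carry both a gene and a CDS/tRNA row per gene; keep first
  df <- df[!duplicated(normalize_gene_name(df$gene)), , drop = FALSE]
  mitogenome(id, sequence, gene_table(df, genome_length = nchar(sequence)))
}

.gb_parse_location <- function(loc, L) {
  strand <- "+"
  inner <- loc
  if (grepl("^complement\\(", inner)) {
    strand <- "-"
    inner <- sub("^complement\\((.*)\\)$", "\\1", inner)
  }
  if (grepl("^join\\(", inner)) {
    parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", inner), ",")[[1]]
    if (length(parts) != 2) stop("unsupported join location: ", loc)
    a <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
    b <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
    if (a[2] != L || b[1] != 1) stop("unsupported join location: ", loc)
    return(list(start = a[1], end = b[2], strand = strand))
  }
  if (!grepl("^[0-9]+\\.\\.[0-9]+$", inner)) stop("unsupported location: ", loc)
  ab <- as.integer(strsplit(inner, "\\.\\.")[[1]])
  list(start = ab[1], end = ab[2], strand = strand)
}

#' Write a mitogenome as a GenBank flat file
#'
#' Emits the minimal dialect \code{\link{read_genbank}} consumes: LOCUS line
#' with circular flag, one feature per annotated gene (CDS/tRNA/rRNA/D-loop;
#' light-strand genes as \code{complement(...)}; origin-spanning features as
#' \code{join(a..L,1..b)}) and a 60-column ORIGIN block.
#'
#' @param genome a \code{\link{mitogenome}}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
write_genbank <- function(genome, file) {
  L <- nchar(genome$sequence)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "LOCUS       %s %d bp    DNA     circular     %s",
    genome$id, L, format(Sys.Date(), "%d-%b-%Y")
  ), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  writeLines(sprintf('                     /organism="%s"', genome$id), con)
  tb <- genome$table
  for (i in seq_len(nrow(tb))) {
    key <- switch(tb$category[i],
      "PCG" = "CDS", "tRNA" = "tRNA", "rRNA" = "rRNA",
      "control-region" = "D-loop", "misc_feature"
    )
    s <- tb$start[i]
    e <- tb$end[i]
    span <- if (e >= s) sprintf("%d..%d", s, e) else sprintf("join(%d..%d,1..%d)", s, L, e)
    if (tb$strand[i] == "-") span <- sprintf("complement(%s)", span)
    writeLines(sprintf("     %-15s %s", key, span), con)
    writeLines(sprintf('                     /gene="%s"', tb$gene[i]), con)
    if (!is.null(tb$anticodon) && !is.na(tb$anticodon[i]) && nzchar(tb$anticodon[i])) {
      writeLines(sprintf('                     /note="anticodon:%s"', tb$anticodon[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1, L, by = 60)
  for (p in pos) {
    chunk <- substr(genome$sequence, p, min(p + 59, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(file)
}
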