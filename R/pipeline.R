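# Report-level orchestration. Each run_* function executes one analysis stage
# over annotated genomes or alignments and writes deterministic TSV/JSON
# artifacts to an output directory; the numbered scripts under analysis/ are
# thin narrative drivers over these functions.

.ensure_dir <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir
}

#' Structure report: gene layout, lengths, strands, order check
#'
#' Per genome: a normalized gene-table TSV (with coordinate-derived lengths)
#' and a JSON summary holding the strand census, the ancestral-avian order
#' check, genome length, control-region length, and any printed-length
#' discrepancies recorded at parse time.
#'
#' @param tables named list of \code{\link{gene_table}} objects (or
#'   \code{\link{mitogenome}}s, whose tables are used).
#' @param out_dir output directory.
#' @return invisibly, the list of per-genome summaries.
#' @export
run_structure <- function(tables, out_dir) {
  if (!length(tables)) stop("no input genomes")
  .ensure_dir(out_dir)
  summaries <- list()
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (inherits(tb, "mitogenome")) tb <- tb$table
    census <- strand_census(tb)
    order_chk <- tryCatch(validate_avian_order(tb), error = function(e) {
      list(is_ancestral_avian = NA, error = conditionMessage(e))
    })
    dl <- tb$length[tb$category == "control-region"]
    s <- list(
      genome = nm,
      genome_length = genome_length_of(tb),
      n_features = nrow(tb),
      n_pcg = sum(tb$category == "PCG"),
      n_trna = sum(tb$category == "tRNA"),
      n_rrna = sum(tb$category == "rRNA"),
      heavy_strand = census$heavy,
      light_strand = census$light,
      light_genes = census$light_genes,
      is_ancestral_avian = order_chk$is_ancestral_avian,
      dloop_length = if (length(dl)) dl[1] else NA,
      length_discrepancies = nrow(length_discrepancies(tb))
    )
    write_feature_table(tb, file.path(out_dir, paste0(nm, "_genes.tsv")))
    summaries[[nm]] <- s
  }
  jsonlite::write_json(summaries, file.path(out_dir, "structure_summary.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(summaries)
}

#' Codon usage / RSCU report
#'
#' Extracts the 13 protein-coding genes of each genome, classifies start/stop
#' codons, counts codon usage (stop triplets included in the headline total by
#' default, matching the sum-of-floor(length/3) convention) and writes
#' codon-usage + RSCU TSVs. RSCU always excludes stop codons from synonymous
#' families.
#'
#' @param genomes named list of \code{\link{mitogenome}} objects.
#' @param out_dir output directory.
#' @param include_stops count complete stop triplets in usage totals.
#' @param code NCBI genetic code id.
#' @return invisibly, per-genome list with \code{usage}, \code{rscu},
#'   \code{start_stop}.
#' @export
run_codon <- function(genomes, out_dir, include_stops = TRUE, code = 2) {
  if (!length(genomes)) stop("no input genomes")
  .ensure_dir(out_dir)
  out <- list()
  for (nm in names(genomes)) {
    g <- genomes[[nm]]
    pcgs <- g$table$gene[g$table$category == "PCG"]
    cds <- stats::setNames(
      lapply(pcgs, function(x) extract_gene_sequence(g, x)), pcgs
    )
    ss <- do.call(rbind, lapply(pcgs, function(x) {
      d <- detect_start_stop(cds[[x]], code)
      data.frame(
        gene = x, start = d$start, start_class = d$start_class,
        stop = d$stop, stop_truncated = d$stop_truncated,
        stringsAsFactors = FALSE
      )
    }))
    usage <- count_codons(cds, code, include_stops = include_stops)
    rscu <- compute_rscu(usage)
    write_codon_usage(rscu, file.path(out_dir, paste0(nm, "_rscu.tsv")))
    utils::write.table(ss, file.path(out_dir, paste0(nm, "_start_stop.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    out[[nm]] <- list(usage = usage, rscu = rscu, start_stop = ss)
  }
  invisible(out)
}

#' Composition and skew report
#'
#' Per genome: the per-gene/per-region composition TSV. Across genomes: a
#' scatter-ready TSV of whole-genome content vs skew plus the Pearson
#' correlations (AT and GC), written as JSON.
#'
#' @param genomes named list of \code{\link{mitogenome}} objects.
#' @param out_dir output directory.
#' @param orientation see \code{\link{per_gene_composition}}.
#' @return invisibly, list with the combined composition table and the
#'   correlation summaries.
#' @export
run_composition <- function(genomes, out_dir, orientation = "reference") {
  if (!length(genomes)) stop("no input genomes")
  .ensure_dir(out_dir)
  combined <- list()
  for (nm in names(genomes)) {
    comp <- per_gene_composition(genomes[[nm]], orientation)
    comp <- cbind(genome = nm, comp)
    write_composition_tsv(comp, file.path(out_dir, paste0(nm, "_composition.tsv")))
    combined[[nm]] <- comp
  }
  all_comp <- do.call(rbind, combined)
  whole <- all_comp[all_comp$region == "genome", ]
  cors <- list(at = list(r = NA, n = nrow(whole)), gc = list(r = NA, n = nrow(whole)))
  if (nrow(whole) >= 3) {
    cors$at <- content_skew_correlation(whole$at_content, whole$at_skew)
    cors$gc <- content_skew_correlation(whole$gc_content, whole$gc_skew)
  }
  utils::write.table(
    data.frame(
      genome = whole$genome,
      at_content = sprintf("%.2f", whole$at_content),
      at_skew = sprintf("%.4f", whole$at_skew),
      gc_content = sprintf("%.2f", whole$gc_content),
      gc_skew = sprintf("%.4f", whole$gc_skew)
    ),
    file.path(out_dir, "content_vs_skew.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(cors, file.path(out_dir, "content_skew_correlation.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(list(composition = all_comp, correlations = cors))
}

#' Divergence + supermatrix report
#'
#' Computes the per-gene divergence table (Pi, variable sites, Ka/Ks for
#' codon-aware alignments) and builds the concatenated supermatrix with
#' partition files (RAxML and NEXUS dialects), FASTA/PHYLIP matrices and a
#' JSON manifest. Genes whose alignment is missing or unreadable are skipped
#' with a warning rather than aborting the batch.
#'
#' @param alignments named list of \code{\link{gene_alignment}} objects.
#' @param out_dir output directory.
#' @param code NCBI genetic code id.
#' @param taxa_policy see \code{\link{concatenate_alignments}}.
#' @return invisibly, list with \code{divergence} and \code{supermatrix}.
#' @export
run_evolution <- function(alignments, out_dir, code = 2,
                          taxa_policy = "intersection") {
  if (!length(alignments)) stop("no input alignments")
  .ensure_dir(out_dir)
  ok <- vapply(alignments, inherits, TRUE, "gene_alignment")
  if (any(!ok)) {
    warning("skipping non-alignment input(s): ", paste(names(alignments)[!ok], collapse = ", "))
    alignments <- alignments[ok]
  }
  div <- divergence_table(alignments, code)
  write_divergence_tsv(div, file.path(out_dir, "divergence.tsv"))
  sm <- concatenate_alignments(alignments, taxa_policy)
  write_supermatrix(sm, file.path(out_dir, "supermatrix.fasta"), "fasta")
  write_supermatrix(sm, file.path(out_dir, "supermatrix.phy"), "phylip")
  write_partitions(sm, "raxml", file.path(out_dir, "partitions_raxml.txt"))
  write_partitions(sm, "nexus", file.path(out_dir, "partitions.nex"))
  write_supermatrix_manifest(sm, file.path(out_dir, "supermatrix_manifest.json"))
  invisible(list(divergence = div, supermatrix = sm))
}
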