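# Synthetic mitogenome and alignment generator. Emulates the study system:
# a 16-17 kb circular genome with the 37-gene avian arrangement, C/A-biased
# composition, protein-coding genes that are valid ORFs under the vertebrate
# mitochondrial code (GTG starts and truncated stops where annotated), and
# multi-taxon gene alignments evolved under a codon substitution process with
# known per-gene omega - so every estimator in the package can be checked
# against ground truth without downloading data.

#' Simulation configuration
#'
#' @param seed integer seed; one global generator drives every draw, so a
#'   fixed seed reproduces fixtures byte-identically.
#' @param genome_length_target total genome size in bp; the D-loop absorbs
#'   the slack (mirroring real congeners, whose size differences live almost
#'   entirely in the control region). Default 16,723 bp.
#' @param composition target percentages named A/C/G/T. Default is the
#'   C/A-biased composition typical of avian heavy strands
#'   (A 29.63, C 32.88, G 14.73, T 22.75).
#' @param gene_template a \code{\link{gene_table}} giving gene order, strands
#'   and lengths; default the bundled \emph{T. indicus} annotation. Real
#'   annotations contain small overlaps (e.g. ATP8/ATP6); the simulator lays
#'   genes out without overlap at the template lengths, since one random
#'   sequence cannot satisfy two overlapping reading frames.
#' @param n_taxa taxa per alignment; default 25, the size of a typical
#'   family-level comparative panel.
#' @param tree \code{NULL} for a star tree with \code{branch_length} per tip,
#'   or an \code{ape::phylo} with edge lengths (expected substitutions/site).
#' @param branch_length star-tree tip branch length; default 0.05
#'   substitutions/site (pairwise distance ~0.1, typical intra-family
#'   mitochondrial divergence).
#' @param omega named per-gene dN/dS for the 13 PCGs; defaults span the
#'   purifying range reported for mitochondrial PCGs, ATP8 highest (0.13)
#'   and COX1 lowest (0.015).
#' @param kappa transition/transversion rate ratio; default 2.
#' @param rate_scale named per-gene rate multipliers (branch lengths are
#'   scaled per gene); defaults slow the rRNAs (0.35) relative to PCGs (1).
#' @param truncated_stop_genes genes ending on an incomplete stop; default
#'   ND2, COX3, ND4 as annotated in the template.
#' @param code NCBI genetic code id (default 2).
#' @return object of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1,
                       genome_length_target = 16723,
                       composition = c(A = 29.63, C = 32.88, G = 14.73, T = 22.75),
                       gene_template = NULL,
                       n_taxa = 25,
                       tree = NULL,
                       branch_length = 0.05,
                       omega = NULL,
                       kappa = 2,
                       rate_scale = NULL,
                       truncated_stop_genes = c("ND2", "COX3", "ND4"),
                       code = 2) {
  composition <- composition[c("A", "C", "G", "T")]
  if (anyNA(composition) || any(composition < 0)) {
    stop("composition must name non-negative A/C/G/T values")
  }
  # printed compositions round to 2 dp, so allow a small slack and renormalize
  if (abs(sum(composition) - 100) > 0.1) {
    stop("composition percentages must sum to 100")
  }
  composition <- 100 * composition / sum(composition)
  if (composition[["A"]] == 0 || composition[["T"]] == 0) {
    stop("infeasible composition: stop/start codons need A and T")
  }
  if (is.null(omega)) {
    omega <- c(
      ND1 = 0.04, ND2 = 0.08, ND3 = 0.06, ND4 = 0.07, ND4L = 0.05,
      ND5 = 0.06, ND6 = 0.09, COX1 = 0.015, COX2 = 0.03, COX3 = 0.025,
      ATP6 = 0.06, ATP8 = 0.13, Cytb = 0.04
    )
  }
  if (any(omega <= 0)) stop("omega must be > 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
    if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
      stop("tree needs non-negative edge lengths")
    }
  }
  if (branch_length < 0) stop("branch_length must be >= 0")
  if (is.null(rate_scale)) rate_scale <- c(rrnS = 0.35, rrnL = 0.35)
  structure(
    list(
      seed = as.integer(seed), genome_length_target = as.integer(genome_length_target),
      composition = composition, gene_template = gene_template,
      n_taxa = as.integer(n_taxa), tree = tree, branch_length = branch_length,
      omega = omega, kappa = kappa, rate_scale = rate_scale,
      truncated_stop_genes = truncated_stop_genes, code = code
    ),
    class = "sim_config"
  )
}

.cfg_template <- function(cfg) {
  if (!is.null(cfg$gene_template)) cfg$gene_template else tarsiger_gene_table("indicus")
}

.cfg_probs <- function(cfg) cfg$composition / sum(cfg$composition)

# Lay the template's genes out without overlap, preserving order, strand and
# length; positive intergenic spacers are preserved, overlaps flattened to
# adjacency; the control region (assumed last) absorbs the remaining length.
.sim_layout <- function(cfg) {
  tpl <- as.data.frame(.cfg_template(cfg))
  pos <- 0L
  starts <- ends <- integer(nrow(tpl))
  for (i in seq_len(nrow(tpl))) {
    gap <- if (i == 1) tpl$start[i] - 1L else max(0L, tpl$start[i] - tpl$end[i - 1L] - 1L)
    len <- if (tpl$category[i] == "control-region") {
      dl <- cfg$genome_length_target - (pos + gap)
      if (dl < 50L) stop("genome_length_target too small for the template genes")
      dl
    } else {
      tpl$length[i]
    }
    starts[i] <- pos + gap + 1L
    ends[i] <- pos + gap + len
    pos <- ends[i]
  }
  tpl$start <- starts
  tpl$end <- ends
  tpl$length <- NULL
  gene_table(tpl, genome_length = pos)
}

.sample_bases <- function(n, probs) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs)
}

# random sense codons (no stops) under the composition bias
.sample_sense_codons <- function(n, probs, code) {
  out <- character(n)
  filled <- 0L
  while (filled < n) {
    need <- n - filled
    cand <- paste0(
      .sample_bases(need, probs), .sample_bases(need, probs), .sample_bases(need, probs)
    )
    keep <- cand[!cand %in% code$stops]
    take <- utils::head(keep, need)
    out[filled + seq_along(take)] <- take
    filled <- filled + length(take)
  }
  out
}

.sim_pcg <- function(feature, cfg, code, probs) {
  len <- feature$end - feature$start + 1L
  if (feature$end < feature$start) len <- len + cfg$genome_length_target
  n_cod <- len %/% 3L
  # a truncated stop is forced whenever the annotated length is not a
  # multiple of 3 (cfg$truncated_stop_genes documents the default template)
  remnant_len <- len %% 3L
  start_codon <- if (!is.null(feature$start_codon) && !is.na(feature$start_codon) &&
    nzchar(feature$start_codon)) feature$start_codon else "ATG"
  stop_codon <- if (!is.null(feature$stop_codon) && !is.na(feature$stop_codon) &&
    feature$stop_codon %in% code$stops) feature$stop_codon else "TAA"
  if (remnant_len > 0) {
    internal <- .sample_sense_codons(n_cod - 1L, probs, code)
    cds <- paste0(start_codon, paste(internal, collapse = ""),
      if (remnant_len == 2L) "TA" else "T")
  } else {
    internal <- .sample_sense_codons(n_cod - 2L, probs, code)
    cds <- paste0(start_codon, paste(internal, collapse = ""), stop_codon)
  }
  cds
}

.gen_genome <- function(cfg, id = "sim") {
  code <- get_code(cfg$code)
  probs <- .cfg_probs(cfg)
  layout <- .sim_layout(cfg)
  L <- genome_length_of(layout)
  seq_vec <- .sample_bases(L, probs) # background: spacers, D-loop, RNAs
  for (i in seq_len(nrow(layout))) {
    f <- layout[i, ]
    if (f$category == "PCG") {
      gene_seq <- .sim_pcg(f, cfg, code, probs)
    } else {
      next # background draw already matches the composition
    }
    if (f$strand == "-") gene_seq <- .revcomp(gene_seq)
    seq_vec[f$start:f$end] <- strsplit(gene_seq, "")[[1]]
  }
  mitogenome(id, paste(seq_vec, collapse = ""), layout)
}

#' Generate an annotated circular mitogenome
#'
#' Produces a genome with the template's gene order, strands and lengths:
#' background, RNA genes and control region drawn i.i.d. from the composition
#' bias; protein-coding genes are valid ORFs under the configured genetic
#' code (annotated start codon, no internal stops, complete or truncated
#' stop); light-strand genes are stored reverse-complemented in the reference
#' sequence, so strand-correct extraction recovers the ORF. Deterministic for
#' a fixed seed.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param id genome id.
#' @return a \code{\link{mitogenome}}.
#' @export
generate_mitogenome <- function(cfg, id = "sim") {
  set.seed(cfg$seed)
  .gen_genome(cfg, id)
}

# --- substitution machinery -------------------------------------------------

# codon-model weights: 64 x 9 relative rates for single-nt changes
.codon_weights <- function(code, omega, kappa) {
  W <- matrix(0, 64, 9)
  kap <- ifelse(code$nbr_ti, kappa, 1)
  W[code$nbr_syn] <- kap[code$nbr_syn]
  W[code$nbr_syn == FALSE & code$nbr_stop == FALSE] <-
    omega * kap[code$nbr_syn == FALSE & code$nbr_stop == FALSE]
  W[code$aa == "*", ] <- 0 # stop codons are frozen (never reached anyway)
  W
}

# Gillespie over independent sites: idx are state indices, W the per-state
# neighbour weights, nbr the neighbour index table, b the scaled duration
.evolve_states <- function(idx, b, W, nbr, scale) {
  rowrate <- rowSums(W) * scale
  rem <- rep(b, length(idx))
  active <- which(rowrate[idx] > 0 & rem > 0)
  while (length(active)) {
    rate <- rowrate[idx[active]]
    wait <- stats::rexp(length(active), rate)
    hit <- wait < rem[active]
    mut <- active[hit]
    rem[mut] <- rem[mut] - wait[hit]
    for (s in mut) {
      c0 <- idx[s]
      idx[s] <- nbr[c0, sample.int(ncol(nbr), 1L, prob = W[c0, ])]
    }
    active <- mut[rowrate[idx[mut]] > 0]
  }
  idx
}

# nucleotide (HKY-like) weights: 4 x 3 target rates pi_j * kappa^ti
.nuc_tables <- function(probs, kappa) {
  bases <- c("A", "C", "G", "T")
  nbr <- matrix(0L, 4, 3)
  W <- matrix(0, 4, 3)
  for (i in 1:4) {
    targets <- setdiff(1:4, i)
    nbr[i, ] <- targets
    ti <- (bases[i] %in% c("A", "G") & bases[targets] %in% c("A", "G")) |
      (bases[i] %in% c("C", "T") & bases[targets] %in% c("C", "T"))
    W[i, ] <- probs[targets] * ifelse(ti, kappa, 1)
  }
  list(nbr = nbr, W = W)
}

.edge_list <- function(cfg) {
  if (is.null(cfg$tree)) {
    # star tree: root node 0, tips 1..n
    data.frame(
      parent = rep(0L, cfg$n_taxa), child = seq_len(cfg$n_taxa),
      length = rep(cfg$branch_length, cfg$n_taxa)
    )
  } else {
    tr <- ape::reorder.phylo(cfg$tree, "cladewise")
    data.frame(
      parent = tr$edge[, 1], child = tr$edge[, 2],
      length = tr$edge.length
    )
  }
}

.tip_labels <- function(cfg) {
  if (is.null(cfg$tree)) {
    sprintf("t%02d", seq_len(cfg$n_taxa))
  } else {
    cfg$tree$tip.label
  }
}

.evolve_over_tree <- function(root_idx, cfg, W, nbr, scale, rate_mult = 1) {
  edges <- .edge_list(cfg)
  if (is.null(cfg$tree)) {
    root_node <- 0L
    n_tip <- cfg$n_taxa
  } else {
    n_tip <- length(cfg$tree$tip.label)
    root_node <- n_tip + 1L
  }
  states <- list()
  states[[as.character(root_node)]] <- root_idx
  for (e in seq_len(nrow(edges))) {
    parent_seq <- states[[as.character(edges$parent[e])]]
    states[[as.character(edges$child[e])]] <-
      .evolve_states(parent_seq, edges$length[e] * rate_mult, W, nbr, scale)
  }
  tips <- .tip_labels(cfg)
  out <- lapply(seq_len(n_tip), function(i) states[[as.character(i)]])
  names(out) <- tips
  out
}

#' Evolve a multi-taxon alignment from a root coding sequence
#'
#' Codon substitution process: at every codon site, candidate single-nt
#' changes occur with relative rate kappa^[transition] x 1 (synonymous),
#' omega (non-synonymous) or 0 (to a stop codon), simulated by exponential
#' waiting times per site along each branch. Branch lengths are calibrated so
#' they equal expected substitutions per nucleotide site at the root
#' composition. The output alignment is gap-free and codon-aware;
#' deterministic for a fixed seed.
#'
#' @param root_cds in-frame coding sequence (valid ORF; a terminal stop codon
#'   is kept but frozen; a trailing 1-2 nt remnant is carried unchanged).
#' @param cfg a \code{\link{sim_config}}; \code{cfg$omega[gene]} (or
#'   \code{cfg$omega[1]} when unnamed/absent) supplies omega.
#' @param gene gene name used for the alignment and omega lookup.
#' @return a \code{\link{gene_alignment}} (codon_aware).
#' @export
evolve_alignment <- function(root_cds, cfg, gene = "gene") {
  set.seed(cfg$seed)
  .evolve_alignment(root_cds, cfg, gene)
}

.evolve_alignment <- function(root_cds, cfg, gene) {
  code <- get_code(cfg$code)
  omega <- if (gene %in% names(cfg$omega)) cfg$omega[[gene]] else cfg$omega[[1]]
  if (omega <= 0) stop("omega must be > 0")
  sp <- split_codons(root_cds)
  idx <- match(sp$codons, code$codons)
  if (anyNA(idx)) stop("root cds contains non-ACGT codons")
  if (any(code$aa[idx[-length(idx)]] == "*")) stop("root cds has internal stop codons")
  W <- .codon_weights(code, omega, cfg$kappa)
  mean_rate <- mean(rowSums(W)[idx][code$aa[idx] != "*"])
  scale <- 3 / mean_rate # branch length b => 3b expected changes per codon
  mult <- if (gene %in% names(cfg$rate_scale)) cfg$rate_scale[[gene]] else 1
  tips <- .evolve_over_tree(idx, cfg, W, code$nbr_idx, scale, mult)
  seqs <- vapply(tips, function(ix) {
    paste(code$codons[ix], collapse = "")
  }, character(1))
  aln <- gene_alignment(gene, seqs, codon_aware = TRUE)
  # a truncated-stop remnant (T/TA) is not part of the codon alignment; it is
  # carried so genome reconstruction can restore the full annotated span
  attr(aln, "remnant") <- sp$remnant
  aln
}

#' Evolve a non-coding (RNA) alignment from a root sequence
#'
#' Plain HKY-like nucleotide process (equilibrium = the configured
#' composition, transition bias kappa), no coding constraint - used for the
#' rRNA genes.
#'
#' @param root_seq root nucleotide sequence.
#' @param cfg a \code{\link{sim_config}}.
#' @param gene name for the alignment (also looked up in
#'   \code{cfg$rate_scale}).
#' @return a \code{\link{gene_alignment}} (not codon-aware).
#' @export
evolve_nucleotide_alignment <- function(root_seq, cfg, gene = "gene") {
  set.seed(cfg$seed)
  .evolve_nucleotide_alignment(root_seq, cfg, gene)
}

.evolve_nucleotide_alignment <- function(root_seq, cfg, gene) {
  probs <- .cfg_probs(cfg)
  nt <- .nuc_tables(probs, cfg$kappa)
  bases <- c("A", "C", "G", "T")
  idx <- match(strsplit(toupper(root_seq), "")[[1]], bases)
  if (anyNA(idx)) stop("root sequence contains non-ACGT characters")
  scale <- 1 / mean(rowSums(nt$W)[idx])
  mult <- if (gene %in% names(cfg$rate_scale)) cfg$rate_scale[[gene]] else 1
  tips <- .evolve_over_tree(idx, cfg, nt$W, nt$nbr, scale, mult)
  seqs <- vapply(tips, function(ix) paste(bases[ix], collapse = ""), character(1))
  gene_alignment(gene, seqs, codon_aware = FALSE)
}

#' Generate a full study fixture: genomes, alignments and truth manifest
#'
#' Builds a root mitogenome, evolves the 13 protein-coding genes under the
#' codon model (known per-gene omega) and the 2 rRNAs under the nucleotide
#' model across \code{n_taxa} taxa, assembles one annotated genome per taxon
#' (evolved PCG/rRNA regions substituted into the root background), and
#' optionally writes everything to disk: GenBank flat file + gene-table TSV
#' per genome, per-gene aligned FASTA, and a JSON manifest recording the true
#' simulation parameters.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param dir output directory (created); \code{NULL} to skip writing.
#' @return (invisibly when writing) list with \code{genomes} (list of
#'   \code{\link{mitogenome}}), \code{alignments} (named list of
#'   \code{\link{gene_alignment}}), \code{root}, \code{manifest}.
#' @export
generate_study_fixture <- function(cfg, dir = NULL) {
  set.seed(cfg$seed)
  root <- .gen_genome(cfg, id = "sim_root")
  tb <- root$table
  alignments <- list()
  for (g in tb$gene[tb$category == "PCG"]) {
    alignments[[g]] <- .evolve_alignment(extract_gene_sequence(root, g), cfg, g)
  }
  for (g in tb$gene[tb$category == "rRNA"]) {
    alignments[[g]] <- .evolve_nucleotide_alignment(extract_gene_sequence(root, g), cfg, g)
  }
  tips <- .tip_labels(cfg)
  genomes <- lapply(seq_along(tips), function(i) {
    seq_vec <- strsplit(root$sequence, "")[[1]]
    for (g in names(alignments)) {
      f <- tb[tb$gene == g, ]
      s <- paste0(
        alignments[[g]]$seqs[[tips[i]]],
        if (!is.null(attr(alignments[[g]], "remnant"))) attr(alignments[[g]], "remnant") else ""
      )
      if (f$strand == "-") s <- .revcomp(s)
      seq_vec[f$start:f$end] <- strsplit(s, "")[[1]]
    }
    mitogenome(paste0("sim_", tips[i]), paste(seq_vec, collapse = ""), tb)
  })
  names(genomes) <- vapply(genomes, `[[`, "", "id")
  manifest <- list(
    seed = cfg$seed, n_taxa = cfg$n_taxa,
    genome_length = genome_length_of(root$table),
    composition = as.list(cfg$composition),
    kappa = cfg$kappa, branch_length = cfg$branch_length,
    tree = if (is.null(cfg$tree)) "star" else "user",
    omega = as.list(cfg$omega),
    rate_scale = as.list(cfg$rate_scale),
    genes = names(alignments)
  )
  out <- list(genomes = genomes, alignments = alignments, root = root, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (g in genomes) {
      write_genbank(g, file.path(dir, paste0(g$id, ".gb")))
      write_feature_table(g$table, file.path(dir, paste0(g$id, "_genes.tsv")))
    }
    for (g in names(alignments)) {
      write_gene_alignment(alignments[[g]], file.path(dir, paste0(g, ".aln.fasta")))
    }
    jsonlite::write_json(manifest, file.path(dir, "truth_manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
    return(invisible(out))
  }
  out
}
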