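#' Genetic code with codon-level machinery for mitochondrial analyses
#'
#' Wraps an NCBI translation table (via \code{Biostrings::getGeneticCode}) and
#' precomputes everything the codon-level statistics need: synonymous codon
#' families, per-codon synonymous site counts in the Nei-Gojobori sense, the
#' single-nucleotide neighbourhood of every codon, and pairwise
#' synonymous/non-synonymous difference counts averaged over equally weighted
#' minimal mutational pathways (pathways through stop codons discarded).
#'
#' The default is NCBI translation table 2, the vertebrate mitochondrial code,
#' under which AGA/AGG are stops, TGA is Trp and ATA is Met. That is the code
#' required to read avian mitochondrial protein-coding genes, whose annotated
#' stops include AGA and AGG.
#'
#' @param id NCBI translation table number (default 2, vertebrate
#'   mitochondrial). Anything \code{Biostrings} knows is accepted.
#' @return An object of class \code{"genetic_code"}: a list with elements
#'   \code{id}, \code{codons} (the 64 codons, DNA alphabet), \code{aa}
#'   (named codon -> one-letter amino acid, \code{"*"} for stop),
#'   \code{starts}, \code{stops}, \code{families} (amino acid -> codon set,
#'   stops excluded), \code{syn_sites} (per-codon synonymous site count),
#'   and internal neighbour/pathway lookup tables.
#' @export
genetic_code <- function(id = 2) {
  tab <- Biostrings::getGeneticCode(as.character(id))
  codons <- names(tab)
  aa <- as.character(tab)
  names(aa) <- codons
  stops <- codons[aa == "*"]
  alt_init <- attr(Biostrings::getGeneticCode(as.character(id)), "alt_init_codons")
  starts <- unique(c("ATG", alt_init))

  families <- split(codons[aa != "*"], aa[aa != "*"])

  # --- single-nucleotide neighbourhood -------------------------------------
  # nbr_idx[c, k]: index of the k-th single-nt mutant of codon c (9 per codon)
  # nbr_syn / nbr_stop / nbr_ti: classification of that mutation
  bases <- c("A", "C", "G", "T")
  n <- length(codons)
  nbr_idx <- matrix(0L, n, 9)
  nbr_syn <- matrix(FALSE, n, 9)
  nbr_stop <- matrix(FALSE, n, 9)
  nbr_ti <- matrix(FALSE, n, 9)
  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  for (i in seq_len(n)) {
    cod <- strsplit(codons[i], "")[[1]]
    k <- 0L
    for (pos in 1:3) {
      for (b in bases[bases != cod[pos]]) {
        k <- k + 1L
        mut <- cod
        mut[pos] <- b
        j <- match(paste(mut, collapse = ""), codons)
        nbr_idx[i, k] <- j
        nbr_syn[i, k] <- aa[j] == aa[i] && aa[i] != "*"
        nbr_stop[i, k] <- aa[j] == "*"
        nbr_ti[i, k] <- is_transition(cod[pos], b)
      }
    }
  }

  # --- Nei-Gojobori synonymous site counts ---------------------------------
  # Per position: fraction of non-stop single-nt mutations that are synonymous;
  # mutations to stop codons are dropped from the 3-count denominator, so each
  # position still contributes exactly one site and N + S = 3 per codon.
  syn_sites <- numeric(n)
  for (i in seq_len(n)) {
    if (aa[i] == "*") {
      syn_sites[i] <- NA_real_
      next
    }
    s <- 0
    for (pos in 1:3) {
      k <- (pos - 1) * 3 + 1:3
      usable <- !nbr_stop[i, k]
      s <- s + if (any(usable)) sum(nbr_syn[i, k][usable]) / sum(usable) else 0
    }
    syn_sites[i] <- s
  }
  names(syn_sites) <- codons

  pw <- ng_pathway_tables(codons, aa, stops)

  structure(
    list(
      id = id, codons = codons, aa = aa, starts = starts, stops = stops,
      families = families, syn_sites = syn_sites,
      nbr_idx = nbr_idx, nbr_syn = nbr_syn, nbr_stop = nbr_stop,
      nbr_ti = nbr_ti,
      sd_mat = pw$sd, nd_mat = pw$nd
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf(
    "Genetic code (NCBI table %s): %d stop codons (%s), %d families\n",
    x$id, length(x$stops), paste(x$stops, collapse = ","), length(x$families)
  ))
  invisible(x)
}

# Pairwise syn/nonsyn difference counts between every pair of sense codons,
# averaged over all minimal mutational pathways (orders of introducing the
# differing positions), each pathway weighted equally; pathways passing
# through a stop codon are discarded. If every pathway is blocked by a stop,
# fall back to averaging over all pathways so the pair still contributes.
ng_pathway_tables <- function(codons, aa, stops) {
  n <- length(codons)
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- matrix(0, n, n, dimnames = list(codons, codons))
  split_cod <- strsplit(codons, "")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- split_cod[[i]]
      cj <- split_cod[[j]]
      diffpos <- which(ci != cj)
      perms <- permutations_of(diffpos)
      path_sd <- numeric(0)
      path_nd <- numeric(0)
      ok <- logical(0)
      for (p in seq_len(nrow(perms))) {
        cur <- ci
        s_cnt <- 0
        n_cnt <- 0
        blocked <- FALSE
        for (pos in perms[p, ]) {
          nxt <- cur
          nxt[pos] <- cj[pos]
          a1 <- aa[paste(cur, collapse = "")]
          a2 <- aa[paste(nxt, collapse = "")]
          if (a2 == "*" && paste(nxt, collapse = "") != codons[j]) blocked <- TRUE
          if (a1 == a2) s_cnt <- s_cnt + 1 else n_cnt <- n_cnt + 1
          cur <- nxt
        }
        path_sd <- c(path_sd, s_cnt)
        path_nd <- c(path_nd, n_cnt)
        ok <- c(ok, !blocked)
      }
      use <- if (any(ok)) ok else rep(TRUE, length(ok))
      sd[i, j] <- mean(path_sd[use])
      nd[i, j] <- mean(path_nd[use])
    }
  }
  list(sd = sd, nd = nd)
}

permutations_of <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (k in seq_along(x)) {
    rest <- permutations_of(x[-k])
    out <- rbind(out, cbind(x[k], rest))
  }
  out
}

# cache: building the pathway tables costs a fraction of a second but is
# called from many entry points
.code_cache <- new.env(parent = emptyenv())

get_code <- function(code = 2) {
  if (inherits(code, "genetic_code")) return(code)
  key <- as.character(code)
  if (is.null(.code_cache[[key]])) .code_cache[[key]] <- genetic_code(code)
  .code_cache[[key]]
}
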