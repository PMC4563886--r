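# Built-in homology search and best-hit selection. The built-in search lets
# the package run with no external aligner; precomputed hit tables
# (read_hit_table) are the higher-fidelity path for real data.

#' All-vs-all protein similarity search
#'
#' Word-seeded Smith-Waterman local alignment with BLOSUM62 scoring and
#' affine gaps (defaults open 11 / extend 1, word size 3). A subject is
#' aligned when it shares at least `min_seed_hits` exact words of
#' `word_size` residues with the query. E-values use fixed Karlin-Altschul
#' constants for gapped BLOSUM62 (lambda 0.267, K 0.041) and are approximate.
#' Self hits (query id equal to subject id) are excluded; same-species
#' non-self hits are retained.
#'
#' @param queries,subjects named character vectors of amino-acid sequences,
#'   or `AAStringSet`, or a [gene_set()] (collapsed transcripts used).
#' @param word_size exact-word seed length.
#' @param min_seed_hits number of distinct shared words required before a
#'   pair is aligned (raising this speeds up large searches at a small
#'   sensitivity cost).
#' @param gap_open,gap_extend affine gap penalties.
#' @param max_evalue report hits at or below this e-value.
#' @return hit table data frame in the standard 12-column layout.
#' @export
search_proteins <- function(queries, subjects, word_size = 3,
                            min_seed_hits = 1, gap_open = 11,
                            gap_extend = 1, max_evalue = 10) {
  q <- .as_protein_vector(queries)
  s <- .as_protein_vector(subjects)
  if (length(q) == 0L || length(s) == 0L)
    stop("empty sequence set")
  .protein_search_cpp(unname(q), names(q), unname(s), names(s),
                      word_size = as.integer(word_size),
                      min_seed_hits = as.integer(min_seed_hits),
                      gap_open = as.integer(gap_open),
                      gap_extend = as.integer(gap_extend),
                      max_evalue = max_evalue)
}

.as_protein_vector <- function(x) {
  if (inherits(x, "gene_set")) {
    v <- x$transcripts$protein
    names(v) <- x$transcripts$gene_id
    v <- v[!is.na(v) & nzchar(v)]
    return(vapply(v, .strip_stop, character(1)))
  }
  if (inherits(x, "AAStringSet")) {
    v <- as.character(x)
    return(v)
  }
  stopifnot(is.character(x), !is.null(names(x)))
  x
}

#' Nucleotide similarity search against large sequences
#'
#' Seed-and-extend local alignment: exact `word_size`-mer seeds against an
#' indexed subject (e.g. a pseudomolecule), diagonal clustering, and local
#' dynamic programming restricted to a window around each seed cluster.
#' Scoring defaults follow blastn (+2/-3, gap open 5 / extend 2). One best
#' local hit is reported per query/subject pair.
#'
#' @param queries named character vector (or `DNAStringSet`) of query
#'   nucleotide sequences.
#' @param subjects named character vector (or `DNAStringSet`) of subject
#'   sequences.
#' @param word_size exact seed length.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param max_evalue report hits at or below this e-value (approximate
#'   Karlin-Altschul, lambda 0.625, K 0.41).
#' @param both_strands also search the reverse complement of each query and
#'   keep the better hit per query/subject pair.
#' @param min_cluster_seeds minimum number of co-diagonal seed matches
#'   before a region is extended by dynamic programming (2 screens out
#'   isolated chance seeds; set 1 for maximum sensitivity on tiny inputs).
#' @return hit table data frame in the standard 12-column layout.
#' @export
search_nucleotide <- function(queries, subjects, word_size = 11, match = 2,
                              mismatch = -3, gap_open = 5, gap_extend = 2,
                              max_evalue = 1e-5, both_strands = TRUE,
                              min_cluster_seeds = 2) {
  q <- .as_dna_vector(queries)
  s <- .as_dna_vector(subjects)
  if (length(q) == 0L || length(s) == 0L)
    return(data.frame(matrix(nrow = 0, ncol = 12,
                             dimnames = list(NULL, .HIT_COLS))))
  run <- function(qv) .nucleotide_search_cpp(
    unname(qv), names(qv), unname(s), names(s),
    word_size = as.integer(word_size), match = as.integer(match),
    mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
    gap_extend = as.integer(gap_extend), max_evalue = max_evalue,
    min_cluster_seeds = as.integer(min_cluster_seeds))
  out <- run(q)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(q)))
    names(rc) <- names(q)
    h2 <- run(rc)
    if (nrow(h2)) {
      # report reverse-strand query coordinates on the forward query
      qlen <- nchar(q)[h2$query_id]
      qs <- qlen - h2$q_end + 1
      h2$q_end <- qlen - h2$q_start + 1
      h2$q_start <- qs
      out <- rbind(out, h2)
      out <- out[order(out$query_id, out$subject_id, -out$bitscore), ,
                 drop = FALSE]
      out <- out[!duplicated(paste(out$query_id, out$subject_id,
                                   sep = "\r")), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

.as_dna_vector <- function(x) {
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  stopifnot(is.character(x))
  x
}

#' Pairwise local protein alignment
#'
#' Exposes the exact Smith-Waterman (Gotoh) kernel used by
#' [search_proteins()] for a single pair, without seeding.
#'
#' @param a,b amino-acid strings.
#' @param gap_open,gap_extend affine gap penalties.
#' @return list with `score`, `n_ident`, `aln_length`, coordinates.
#' @export
align_protein_pair <- function(a, b, gap_open = 11, gap_extend = 1) {
  .align_pair_protein_cpp(a, b, as.integer(gap_open), as.integer(gap_extend))
}

#' Best hit per query and target species
#'
#' For every query gene, keeps the single best hit in each target species:
#' maximum bit score, ties broken by lower e-value, then higher identity,
#' then lexicographically smaller subject id (deterministic across runs).
#' Hits above the e-value cutoff and self hits are dropped first.
#'
#' @param hits hit table (annotated: needs `subject_species`; use
#'   [annotate_hits()]).
#' @param max_evalue e-value cutoff (default 1e-5).
#' @return data frame with one row per (query, target species), carrying the
#'   winning hit's statistics and subject location.
#' @export
best_hits <- function(hits, max_evalue = 1e-5) {
  stopifnot("subject_species" %in% names(hits))
  h <- hits[!is.na(hits$evalue) & hits$evalue <= max_evalue &
              hits$query_id != hits$subject_id &
              !is.na(hits$subject_species), , drop = FALSE]
  if (nrow(h) == 0L) {
    out <- h
    out$target_species <- character(0)
    return(out)
  }
  key <- paste(h$query_id, h$subject_species, sep = "\r")
  ord <- order(key, -h$bitscore, h$evalue, -h$pct_identity, h$subject_id)
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(paste(h$query_id, h$subject_species, sep = "\r")), ,
         drop = FALSE]
  h$target_species <- h$subject_species
  rownames(h) <- NULL
  h
}
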