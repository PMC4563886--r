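# Independent oracles used to check the package's implementations. These
# deliberately re-derive everything from first principles (standard genetic
# code via seqinr, exhaustive enumeration, naive dynamic programming) and
# share no code with the package.

.oracle_code_cache <- new.env(parent = emptyenv())

oracle_translate_codon <- function(codon) {
  # one-time lookup table built from seqinr's standard-code translation
  if (is.null(.oracle_code_cache$tab)) {
    all <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             c("A", "C", "G", "T")), 1, paste, collapse = "")
    .oracle_code_cache$tab <- stats::setNames(
      vapply(all, function(cd)
        seqinr::translate(strsplit(tolower(cd), "")[[1]]), character(1)),
      all)
  }
  .oracle_code_cache$tab[[toupper(codon)]]
}

oracle_bases <- c("A", "C", "G", "T")

oracle_sense_codons <- function() {
  all <- apply(expand.grid(oracle_bases, oracle_bases, oracle_bases), 1,
               paste, collapse = "")
  all[vapply(all, oracle_translate_codon, character(1)) != "*"]
}

# Nei-Gojobori site counting by exhaustive enumeration of the 9 single-base
# mutants; changes creating stop codons are excluded from each position's
# denominator and each position contributes one site.
oracle_count_sites <- function(codon) {
  aa0 <- oracle_translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    valid <- 0
    for (b in setdiff(oracle_bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      aa1 <- oracle_translate_codon(mut)
      if (aa1 == "*") next
      valid <- valid + 1
      if (aa1 == aa0) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

# Pathway-averaged differences by brute-force enumeration of all orders of
# the differing positions; pathways through stop codons excluded, with a
# fallback to all pathways when none survive.
oracle_count_differences <- function(a, b) {
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (p in perms(x[-i])) out <- c(out, list(c(x[i], p)))
    out
  }
  walk <- function(ord, allow_stop) {
    cur <- a
    sd <- 0
    nd <- 0
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (!allow_stop && oracle_translate_codon(nxt) == "*") return(NULL)
      if (oracle_translate_codon(cur) == oracle_translate_codon(nxt))
        sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms(diffs), walk, FALSE))
  if (length(res) == 0) res <- lapply(perms(diffs), walk, TRUE)
  m <- Reduce(`+`, res) / length(res)
  c(sd = m[1], nd = m[2])
}

# Naive full Smith-Waterman (Gotoh affine) over BLOSUM62, no seeding.
# Returns only the optimal local score.
oracle_sw_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av)
  n <- length(bv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      d <- H[i - 1, j - 1] + B[av[i - 1], bv[j - 1]]
      H[i, j] <- max(0, d, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Naive O(genes x windows) window recount.
oracle_window_counts <- function(positions, nonsyn, window, step,
                                 chrom_length) {
  starts <- seq(1, chrom_length, by = step)
  t(vapply(starts, function(w) {
    inw <- positions >= w & positions < w + window
    c(n = sum(inw), ns = sum(inw & nonsyn))
  }, numeric(2)))
}

# Upper-tail hypergeometric by direct summation of the density.
oracle_hyper_p <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# Minimal gene_set builder for hand-constructed fixtures.
mk_gene_set <- function(..., species = "spA") {
  genes <- list(...)
  gdf <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, species = species,
               chromosome = g$chromosome %||% "chr1",
               start = g$start, end = g$end,
               strand = g$strand %||% "+",
               is_te_related = isTRUE(g$te),
               description = g$description %||% "",
               stringsAsFactors = FALSE)))
  tx <- do.call(rbind, lapply(genes, function(g) {
    trs <- g$transcripts
    df <- data.frame(
      gene_id = g$gene_id,
      transcript_id = vapply(trs, `[[`, character(1), "id"),
      stringsAsFactors = FALSE)
    df$exons <- lapply(trs, function(t)
      t[["exons"]] %||% cbind(g$start, g$end))
    df$cds <- lapply(trs, function(t)
      t[["cds"]] %||% t[["exons"]] %||% cbind(g$start, g$end))
    df$cds_seq <- vapply(trs, function(t)
      t[["cds_seq"]] %||% NA_character_, character(1))
    df$protein <- vapply(trs, function(t) {
      if (!is.null(t[["protein"]])) t[["protein"]]
      else if (!is.null(t[["cds_seq"]]))
        syntenica::translate_cds(t[["cds_seq"]])
      else NA_character_
    }, character(1))
    df
  }))
  syntenica::gene_set(gdf, tx, validate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal hit-record row compatible with the annotated hit table layout.
mk_hit <- function(query_id, subject_id, pct_identity = 90, aln_length = 100,
                   q_start = 1, q_end = 100, s_start = 1, s_end = 100,
                   evalue = 1e-20, bitscore = 200,
                   subject_species = "spB", subject_chromosome = "chr1",
                   subject_pos = 5000) {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = pct_identity, aln_length = aln_length,
             mismatches = 0, gap_opens = 0, q_start = q_start,
             q_end = q_end, s_start = s_start, s_end = s_end,
             evalue = evalue, bitscore = bitscore,
             subject_chromosome = subject_chromosome,
             subject_pos = subject_pos,
             subject_species = subject_species, stringsAsFactors = FALSE)
}

random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- oracle_sense_codons()
  sense <- setdiff(sense, c("ATG"))
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}
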