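# The four sequential filters reducing a raw annotation to the comparable
# "core" gene set: isoform collapse, TE removal, cross-species homology
# support, pseudogene removal. The report reproduces the sequential
# semantics: each stage count is conditioned on the previous stage.

#' Collapse alternative splice variants
#'
#' Keeps exactly one transcript per gene: the one with the longest CDS, ties
#' broken by longest genomic span, then lexicographically smallest
#' transcript id.
#'
#' @param genes a [gene_set()].
#' @return a [gene_set()] with one transcript per gene.
#' @export
collapse_isoforms <- function(genes) {
  t <- genes$transcripts
  ord <- order(t$gene_id, -t$cds_len, -t$span, t$transcript_id)
  t <- t[ord, , drop = FALSE]
  t <- t[!duplicated(t$gene_id), , drop = FALSE]
  rownames(t) <- NULL
  gene_set(genes$genes, t, validate = FALSE)
}

#' Remove transposable-element-related genes
#'
#' Drops genes flagged TE-related in the annotation or carrying a
#' case-insensitive "transposon" substring in their description.
#'
#' @param genes a [gene_set()].
#' @return filtered [gene_set()]; removed ids in attribute `removed`.
#' @export
remove_te_genes <- function(genes) {
  g <- genes$genes
  te <- g$is_te_related | grepl("transposon", g$description,
                                ignore.case = TRUE)
  out <- subset_genes(genes, g$gene_id[!te])
  attr(out, "removed") <- g$gene_id[te]
  out
}

#' Cross-species homology support
#'
#' For each gene, finds qualifying protein hits in *other* species:
#' `evalue <= max_evalue`, `pct_identity >= min_identity` and aligned-span
#' overlap at or above `min_overlap` percent. The overlap denominator is the
#' query protein length by default (`"query"`), or the shorter of the two
#' proteins (`"min"`).
#'
#' @param genes a collapsed [gene_set()] (one transcript per gene).
#' @param hits annotated hit table (needs `subject_species`; see
#'   [annotate_hits()]). Protein-level coordinates.
#' @param other_species species counted as homology evidence.
#' @param max_evalue,min_identity,min_overlap thresholds (defaults 1e-5,
#'   35, 35).
#' @param overlap_denominator `"query"` or `"min"`.
#' @param subject_lengths optional named vector of subject protein lengths
#'   (needed for `"min"` and for the pseudogene homolog-length rule).
#' @return data frame, one row per gene: `gene_id`, `supported`,
#'   `n_qualifying`, `best_subject`, `best_subject_len`.
#' @export
homology_support <- function(genes, hits, other_species,
                             max_evalue = 1e-5, min_identity = 35,
                             min_overlap = 35,
                             overlap_denominator = c("query", "min"),
                             subject_lengths = NULL) {
  overlap_denominator <- match.arg(overlap_denominator)
  t <- genes$transcripts
  qlen <- stats::setNames(nchar(.strip_stop(t$protein)), t$gene_id)
  h <- hits[hits$query_id %in% genes$genes$gene_id &
              !is.na(hits$subject_species) &
              hits$subject_species %in% other_species &
              hits$query_id != hits$subject_id, , drop = FALSE]
  span <- abs(h$q_end - h$q_start) + 1
  denom <- qlen[h$query_id]
  if (overlap_denominator == "min" && !is.null(subject_lengths))
    denom <- pmin(denom, subject_lengths[h$subject_id])
  h$overlap <- 100 * span / denom
  qual <- h$evalue <= max_evalue & h$pct_identity >= min_identity &
    h$overlap >= min_overlap
  hq <- h[qual & !is.na(qual), , drop = FALSE]
  best <- hq[order(hq$query_id, -hq$bitscore, hq$evalue, hq$subject_id), ,
             drop = FALSE]
  best <- best[!duplicated(best$query_id), , drop = FALSE]
  gid <- genes$genes$gene_id
  idx <- match(gid, best$query_id)
  nq <- table(hq$query_id)
  out <- data.frame(gene_id = gid, supported = !is.na(idx),
                    n_qualifying = rep(0L, length(gid)),
                    best_subject = if (length(gid)) best$subject_id[idx]
                    else character(0),
                    stringsAsFactors = FALSE)
  got <- match(gid, names(nq))
  out$n_qualifying[!is.na(got)] <- as.integer(nq[got[!is.na(got)]])
  out$best_subject_len <- if (!is.null(subject_lengths))
    as.numeric(subject_lengths[out$best_subject]) else NA_real_
  out
}

#' Homology-support filter
#'
#' Keeps genes with at least one qualifying hit in at least one other
#' species (see [homology_support()] for the thresholds). Genes absent from
#' the hit table count as unsupported and are removed.
#'
#' @inheritParams homology_support
#' @return filtered [gene_set()], with the support table as attribute
#'   `support` and removed ids as attribute `removed`.
#' @export
homology_support_filter <- function(genes, hits, other_species,
                                    max_evalue = 1e-5, min_identity = 35,
                                    min_overlap = 35,
                                    overlap_denominator = "query",
                                    subject_lengths = NULL) {
  sup <- homology_support(genes, hits, other_species, max_evalue,
                          min_identity, min_overlap, overlap_denominator,
                          subject_lengths)
  out <- subset_genes(genes, sup$gene_id[sup$supported])
  attr(out, "support") <- sup
  attr(out, "removed") <- sup$gene_id[!sup$supported]
  out
}

#' Pseudogene detection
#'
#' A gene model is called a pseudogene when its translation contains an
#' internal stop codon, its CDS length is not a multiple of 3 (frameshift
#' proxy), or its protein is shorter than `min_fraction` (default 0.70) of
#' the length of its best complete homolog.
#'
#' @param cds_seq the gene's (collapsed) CDS sequence.
#' @param homolog_len protein length (aa) of the best qualifying homolog;
#'   `NA` skips the truncation rule.
#' @param min_fraction truncation threshold.
#' @return list `pseudogene` (logical) and `reason` (`"internal_stop"`,
#'   `"frameshift"`, `"truncation"`, or `NA`).
#' @export
detect_pseudogene <- function(cds_seq, homolog_len = NA,
                              min_fraction = 0.70) {
  if (is.null(cds_seq) || is.na(cds_seq) || !nzchar(cds_seq))
    stop("cannot assess pseudogene status without a CDS sequence")
  if (nchar(cds_seq) %% 3L != 0L)
    return(list(pseudogene = TRUE, reason = "frameshift"))
  protein <- translate_cds(cds_seq)
  internal <- substr(protein, 1L, nchar(protein) - 1L)
  if (grepl("*", internal, fixed = TRUE))
    return(list(pseudogene = TRUE, reason = "internal_stop"))
  plen <- nchar(.strip_stop(protein))
  if (!is.na(homolog_len) && plen < min_fraction * homolog_len)
    return(list(pseudogene = TRUE, reason = "truncation"))
  list(pseudogene = FALSE, reason = NA_character_)
}

#' Run the full filtration cascade
#'
#' Applies, in order: isoform collapse, TE removal, homology support,
#' pseudogene removal. Each removed gene records the first failing filter as
#' its reason. The homolog length for the truncation rule is the protein
#' length of the gene's best hit surviving the homology filter.
#'
#' @param genes raw [gene_set()] for one species.
#' @param hits annotated hit table covering this species' queries.
#' @param other_species species counted as homology evidence.
#' @param subject_lengths named vector of protein lengths for potential
#'   subjects (e.g. from the other species' collapsed gene sets).
#' @param max_evalue,min_identity,min_overlap,overlap_denominator
#'   homology-filter thresholds.
#' @param pseudogene_fraction truncation threshold (default 0.70).
#' @return list `core` (the filtered [gene_set()]) and `report`
#'   (a `filtration_report`).
#' @export
run_filtration <- function(genes, hits, other_species,
                           subject_lengths = NULL,
                           max_evalue = 1e-5, min_identity = 35,
                           min_overlap = 35, overlap_denominator = "query",
                           pseudogene_fraction = 0.70) {
  species <- if (nrow(genes$genes)) genes$genes$species[1] else NA_character_
  reasons <- character(0)
  ids <- character(0)

  collapsed <- collapse_isoforms(genes)
  n_raw <- n_genes(collapsed)

  no_te <- remove_te_genes(collapsed)
  te_removed <- attr(no_te, "removed")
  ids <- c(ids, te_removed)
  reasons <- c(reasons, rep("te_related", length(te_removed)))

  supported <- homology_support_filter(
    no_te, hits, other_species, max_evalue, min_identity, min_overlap,
    overlap_denominator, subject_lengths)
  hom_removed <- attr(supported, "removed")
  ids <- c(ids, hom_removed)
  reasons <- c(reasons, rep("no_homology_support", length(hom_removed)))
  sup <- attr(supported, "support")

  t <- supported$transcripts
  hl <- sup$best_subject_len[match(t$gene_id, sup$gene_id)]
  pseudo <- vapply(seq_len(nrow(t)), function(i) {
    r <- detect_pseudogene(t$cds_seq[i], hl[i], pseudogene_fraction)
    if (r$pseudogene) r$reason else NA_character_
  }, character(1))
  pg_ids <- t$gene_id[!is.na(pseudo)]
  ids <- c(ids, pg_ids)
  if (length(pg_ids))
    reasons <- c(reasons, paste0("pseudogene:", pseudo[!is.na(pseudo)]))
  core <- subset_genes(supported, setdiff(t$gene_id, pg_ids))

  counts <- c(raw = n_raw,
              no_asv_te = n_genes(no_te),
              homology_supported = n_genes(supported),
              non_pseudogene = n_genes(core))
  report <- structure(list(
    species = species, counts = counts,
    reasons = data.frame(gene_id = ids, reason = reasons,
                         stringsAsFactors = FALSE)),
    class = "filtration_report")
  list(core = core, report = report)
}

#' @export
print.filtration_report <- function(x, ...) {
  cat("Filtration report for", x$species, "\n")
  stage <- c("raw (collapsed isoforms)", "no ASVs or TEs",
             ">= 1 homolog in another species", "after removing pseudogenes")
  for (i in seq_along(x$counts))
    cat(sprintf("  %-36s %d\n", stage[i], x$counts[i]))
  invisible(x)
}
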