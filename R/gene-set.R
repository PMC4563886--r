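# The shared gene/annotation data model: a gene_set holds one table of gene
# loci and one table of transcript models (exon/CDS structures, sequences).

#' Construct a gene set
#'
#' The container every pipeline stage consumes: a `genes` table (one row per
#' gene locus) and a `transcripts` table (one row per transcript model, with
#' exon and CDS intervals as list columns of two-column start/end matrices,
#' plus optional CDS and protein sequences). Coordinates are 1-based
#' inclusive throughout, following GFF3.
#'
#' @param genes data frame with columns `gene_id`, `species`, `chromosome`,
#'   `start`, `end`, `strand` (`+`/`-`), `is_te_related` (logical),
#'   `description`.
#' @param transcripts data frame with columns `gene_id`, `transcript_id`,
#'   `exons` (list of matrices), `cds` (list of matrices), `cds_seq`,
#'   `protein`, and derived `cds_len`, `span`, `cds_complete`.
#' @param validate skip invariant checks when `FALSE` (internal fast path).
#' @return object of class `gene_set`.
#' @export
gene_set <- function(genes, transcripts, validate = TRUE) {
  need_g <- c("gene_id", "species", "chromosome", "start", "end", "strand",
              "is_te_related", "description")
  need_t <- c("gene_id", "transcript_id", "exons", "cds", "cds_seq",
              "protein")
  stopifnot(all(need_g %in% names(genes)), all(need_t %in% names(transcripts)))
  if (!"cds_len" %in% names(transcripts))
    transcripts$cds_len <- vapply(transcripts$cds, function(m)
      if (is.null(m) || nrow(m) == 0L) 0L else
        as.integer(sum(m[, 2] - m[, 1] + 1)), integer(1))
  if (!"span" %in% names(transcripts))
    transcripts$span <- vapply(transcripts$exons, function(m)
      if (is.null(m) || nrow(m) == 0L) 0L else
        as.integer(max(m[, 2]) - min(m[, 1]) + 1L), integer(1))
  if (!"cds_complete" %in% names(transcripts))
    transcripts$cds_complete <- transcripts$cds_len %% 3L == 0L
  obj <- structure(list(genes = genes, transcripts = transcripts),
                   class = "gene_set")
  if (validate) validate_gene_set(obj)
  obj
}

#' @rdname gene_set
#' @param x a `gene_set`.
#' @export
validate_gene_set <- function(x) {
  g <- x$genes
  t <- x$transcripts
  dup <- duplicated(paste(g$species, g$gene_id))
  if (any(dup))
    stop("duplicate gene_id within a species: ",
         paste(unique(g$gene_id[dup]), collapse = ", "))
  if (any(g$start > g$end)) stop("gene with start > end")
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  miss <- setdiff(g$gene_id, t$gene_id)
  if (length(miss))
    stop("genes without any transcript: ", paste(miss, collapse = ", "))
  orphan <- setdiff(t$gene_id, g$gene_id)
  if (length(orphan))
    stop("transcripts with unknown gene parent: ",
         paste(orphan, collapse = ", "))
  gi <- match(t$gene_id, g$gene_id)
  for (i in seq_len(nrow(t))) {
    for (m in list(t$exons[[i]], t$cds[[i]])) {
      if (is.null(m) || nrow(m) == 0L) next
      if (min(m[, 1]) < g$start[gi[i]] || max(m[, 2]) > g$end[gi[i]])
        stop("transcript ", t$transcript_id[i],
             " has coordinates outside its gene")
    }
  }
  invisible(x)
}

#' Number of genes in a gene set
#' @param x a `gene_set`.
#' @export
n_genes <- function(x) nrow(x$genes)

#' Subset a gene set by gene identifiers
#'
#' @param x a `gene_set`.
#' @param gene_ids character vector of gene ids to keep.
#' @return a `gene_set` restricted to those genes (and their transcripts).
#' @export
subset_genes <- function(x, gene_ids) {
  gene_set(x$genes[x$genes$gene_id %in% gene_ids, , drop = FALSE],
           x$transcripts[x$transcripts$gene_id %in% gene_ids, , drop = FALSE],
           validate = FALSE)
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts")
  sp <- unique(x$genes$species)
  cat(" (", paste(sp, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Gene midpoint positions (bp), used for window assignment and synteny maps.
gene_midpoints <- function(x) {
  as.numeric((x$genes$start + x$genes$end) / 2)
}
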