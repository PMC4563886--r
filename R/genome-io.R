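# Readers and writers for the standard formats: GFF3 + FASTA in, gene_set
# out; 12/13-column tabular homology hit tables; generic TSV results.

#' Read gene models from GFF3 and FASTA
#'
#' Parses a GFF3 annotation (gene / mRNA / exon / CDS features) together with
#' the genome FASTA and returns a [gene_set()] with strand-aware CDS
#' extraction and translation. Exons and CDS intervals are stored in
#' transcription order (descending coordinates on the minus strand).
#'
#' TE-relatedness is taken from a `te_related=true` attribute or a
#' case-insensitive "transposon" substring in the description attribute.
#'
#' @param path GFF3 file.
#' @param fasta genome FASTA containing every chromosome referenced.
#' @return a [gene_set()].
#' @export
read_gff3 <- function(path, fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  df$Parent1 <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  raw <- readLines(path)

  line_of <- function(id) {
    hit <- grep(paste0("ID=", id, "(;|$)"), raw)
    if (length(hit)) hit[1] else NA_integer_
  }

  gdf <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gdf) == 0L) stop("no gene features in ", path)
  if (anyNA(gdf$ID)) stop("gene feature without ID attribute in ", path)
  if (anyDuplicated(gdf$ID)) {
    dup <- gdf$ID[duplicated(gdf$ID)][1]
    stop("duplicate gene ID '", dup, "' at line ", line_of(dup))
  }
  flat <- function(col) {
    if (is.null(col)) return(rep(NA_character_, nrow(gdf)))
    if (is.list(col) || inherits(col, "CharacterList"))
      return(vapply(col, function(x)
        if (length(x)) paste(x, collapse = ",") else NA_character_,
        character(1)))
    as.character(col)
  }
  desc <- if ("description" %in% names(gdf)) flat(gdf$description)
          else if ("Note" %in% names(gdf)) flat(gdf$Note)
          else rep(NA_character_, nrow(gdf))
  desc[is.na(desc)] <- ""
  te_attr <- if ("te_related" %in% names(gdf))
    tolower(as.character(gdf$te_related)) %in% c("true", "1", "yes")
  else rep(FALSE, nrow(gdf))
  genes <- data.frame(
    gene_id = gdf$ID,
    species = if ("species" %in% names(gdf) && !all(is.na(gdf$species)))
      gdf$species else rep(NA_character_, nrow(gdf)),
    chromosome = gdf$seqnames,
    start = gdf$start, end = gdf$end, strand = gdf$strand,
    is_te_related = te_attr | grepl("transposon", desc, ignore.case = TRUE),
    description = desc,
    stringsAsFactors = FALSE)

  mdf <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  bad <- is.na(mdf$Parent1) | !(mdf$Parent1 %in% genes$gene_id)
  if (any(bad)) {
    id <- mdf$ID[bad][1]
    stop("mRNA '", id, "' at line ", line_of(id),
         " has missing or unknown Parent")
  }
  parts <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  badp <- is.na(parts$Parent1) | !(parts$Parent1 %in% mdf$ID)
  if (any(badp))
    stop(parts$type[badp][1], " feature at line ",
         grep(paste0("\t", parts$type[badp][1], "\t", parts$start[badp][1]),
              raw)[1], " has missing or unknown Parent")

  order_sa <- function(m, strand) {
    if (nrow(m) == 0L) return(m)
    m[order(m[, 1], decreasing = (strand == "-")), , drop = FALSE]
  }

  tr <- lapply(seq_len(nrow(mdf)), function(i) {
    tid <- mdf$ID[i]
    strand <- mdf$strand[i]
    chrom <- mdf$seqnames[i]
    ex <- parts[parts$type == "exon" & parts$Parent1 == tid, , drop = FALSE]
    cd <- parts[parts$type == "CDS" & parts$Parent1 == tid, , drop = FALSE]
    exm <- order_sa(cbind(ex$start, ex$end), strand)
    cdm <- order_sa(cbind(cd$start, cd$end), strand)
    cds_seq <- NA_character_
    protein <- NA_character_
    if (nrow(cdm) > 0L) {
      if (!chrom %in% names(seqs))
        stop("CDS of '", tid, "' references sequence '", chrom,
             "' absent from FASTA")
      asc <- cdm[order(cdm[, 1]), , drop = FALSE]
      pieces <- Biostrings::extractAt(
        seqs[[chrom]], IRanges::IRanges(asc[, 1], asc[, 2]))
      cds <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
      if (strand == "-") cds <- Biostrings::reverseComplement(cds)
      cds_seq <- as.character(cds)
      protein <- translate_cds(cds_seq)
    }
    list(transcript_id = tid, gene_id = mdf$Parent1[i],
         exons = exm, cds = cdm, cds_seq = cds_seq, protein = protein)
  })
  transcripts <- data.frame(
    gene_id = vapply(tr, `[[`, character(1), "gene_id"),
    transcript_id = vapply(tr, `[[`, character(1), "transcript_id"),
    stringsAsFactors = FALSE)
  transcripts$exons <- lapply(tr, `[[`, "exons")
  transcripts$cds <- lapply(tr, `[[`, "cds")
  transcripts$cds_seq <- vapply(tr, `[[`, character(1), "cds_seq")
  transcripts$protein <- vapply(tr, `[[`, character(1), "protein")
  gene_set(genes, transcripts)
}

#' Translate a coding sequence
#'
#' Standard-code translation keeping internal stops as `*`. An incomplete
#' trailing codon is dropped. Ambiguous codons translate to `X`.
#'
#' @param cds_seq nucleotide string.
#' @return amino-acid string.
#' @export
translate_cds <- function(cds_seq) {
  cds_seq <- toupper(cds_seq)
  n <- nchar(cds_seq) - nchar(cds_seq) %% 3L
  if (n == 0L) return("")
  codons <- .split_codons(substr(cds_seq, 1L, n))
  gc <- .genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Write a gene set as GFF3
#'
#' Emits gene / mRNA / exon / CDS features with ID/Parent links, preserving
#' coordinates and identifiers exactly so that
#' `read_gff3(write_gff3(x), fasta)` round-trips.
#'
#' @param x a [gene_set()].
#' @param path output file.
#' @export
write_gff3 <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- x$genes
  t <- x$transcripts
  esc <- function(s) gsub(",", "%2C", gsub(";", "%3B", gsub("=", "%3D", s)))
  for (i in seq_len(nrow(g))) {
    attrs <- sprintf("ID=%s", g$gene_id[i])
    if (!is.na(g$description[i]) && nzchar(g$description[i]))
      attrs <- paste0(attrs, ";description=", esc(g$description[i]))
    if (isTRUE(g$is_te_related[i]))
      attrs <- paste0(attrs, ";te_related=true")
    writeLines(sprintf("%s\tsyntenica\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$chromosome[i], g$start[i], g$end[i], g$strand[i],
                       attrs), con)
    tt <- t[t$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(tt))) {
      exm <- tt$exons[[j]]
      cdm <- tt$cds[[j]]
      lo <- min(exm[, 1])
      hi <- max(exm[, 2])
      writeLines(sprintf("%s\tsyntenica\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$chromosome[i], lo, hi, g$strand[i],
                         tt$transcript_id[j], g$gene_id[i]), con)
      exa <- exm[order(exm[, 1]), , drop = FALSE]
      for (k in seq_len(nrow(exa)))
        writeLines(sprintf("%s\tsyntenica\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                           g$chromosome[i], exa[k, 1], exa[k, 2],
                           g$strand[i], tt$transcript_id[j]), con)
      if (!is.null(cdm) && nrow(cdm) > 0L) {
        cda <- cdm[order(cdm[, 1]), , drop = FALSE]
        for (k in seq_len(nrow(cda)))
          writeLines(sprintf("%s\tsyntenica\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                             g$chromosome[i], cda[k, 1], cda[k, 2],
                             g$strand[i], tt$transcript_id[j]), con)
      }
    }
  }
  invisible(path)
}

.HIT_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
               "mismatches", "gap_opens", "q_start", "q_end", "s_start",
               "s_end", "evalue", "bitscore")

#' Read a tabular homology hit table
#'
#' Standard 12-column tab-separated format (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score), with an optional 13th column
#' giving the subject chromosome. When the 13th column is absent the subject
#' chromosome and midpoint position are resolved from `genes` if supplied.
#'
#' @param path tab-separated file (no header).
#' @param genes optional [gene_set()] (or list of them) used to annotate
#'   `subject_chromosome` and `subject_pos` from the subject gene ids.
#' @return data frame of hit records.
#' @export
read_hit_table <- function(path, genes = NULL) {
  empty <- data.frame(matrix(nrow = 0, ncol = 12,
                             dimnames = list(NULL, .HIT_COLS)))
  if (file.size(path) == 0) return(annotate_hits(empty, genes))
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 12L)
    stop("hit table must have >= 12 tab-separated columns; found ",
         ncol(raw), " in ", path)
  h <- raw[, 1:12]
  names(h) <- .HIT_COLS
  for (col in c("pct_identity", "aln_length", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end", "evalue",
                "bitscore")) {
    v <- suppressWarnings(as.numeric(h[[col]]))
    if (anyNA(v) && !all(is.na(h[[col]])))
      stop("non-numeric ", col, " at row ", which(is.na(v))[1], " of ", path)
    h[[col]] <- v
  }
  if (any(h$pct_identity < 0 | h$pct_identity > 100))
    stop("pct_identity outside [0, 100] at row ",
         which(h$pct_identity < 0 | h$pct_identity > 100)[1])
  if (any(h$evalue < 0)) stop("negative e-value at row ",
                              which(h$evalue < 0)[1])
  if (ncol(raw) >= 13L) h$subject_chromosome <- raw[[13]]
  annotate_hits(h, genes)
}

#' Annotate hits with subject chromosome and position
#'
#' @param hits hit data frame.
#' @param genes a [gene_set()] or list of gene sets covering the subjects;
#'   subjects not found are marked `unplaced`.
#' @return hits with `subject_chromosome`, `subject_pos` and
#'   `subject_protein_len` columns.
#' @export
annotate_hits <- function(hits, genes = NULL) {
  if (is.null(genes)) return(hits)
  if (inherits(genes, "gene_set")) genes <- list(genes)
  g <- do.call(rbind, lapply(genes, function(x)
    data.frame(gene_id = x$genes$gene_id, chromosome = x$genes$chromosome,
               pos = gene_midpoints(x), species = x$genes$species,
               stringsAsFactors = FALSE)))
  idx <- match(hits$subject_id, g$gene_id)
  if (!"subject_chromosome" %in% names(hits))
    hits$subject_chromosome <- ifelse(is.na(idx), "unplaced",
                                      g$chromosome[idx])
  hits$subject_pos <- g$pos[idx]
  hits$subject_species <- g$species[idx]
  hits
}

#' Write any tabular result as TSV
#'
#' Tab-separated with a header line and deterministic column order;
#' round-trips through [read_table()].
#'
#' @param records data frame (or object with `as.data.frame` method).
#' @param path output file.
#' @export
write_table <- function(records, path) {
  df <- as.data.frame(records)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}
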