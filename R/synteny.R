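# Synteny classification: best-hit-based syntenic / non-syntenic calls,
# annotation-independent reclassification against orthologous
# pseudomolecules, duplication-origin detection against whole-genome
# sequence, age stratification against close relatives, and duplicate
# families with random representatives.

#' Classify core genes as syntenic or non-syntenic
#'
#' A gene is syntenic when at least one of its per-species best hits lies on
#' a syntenic counterpart (an orthology block of the gene's own chromosome);
#' it is non-syntenic when all best hits lie on non-syntenic chromosomes.
#' Best hits on chromosomes absent from the map count as non-syntenic
#' evidence.
#'
#' @param genes core [gene_set()] for one species.
#' @param best best-hit table from [best_hits()] (queries of this species).
#' @param map a [synteny_map()].
#' @param target_species species whose best hits count as evidence (default:
#'   every target present in `best`).
#' @return `synteny_calls` data frame: `gene_id`, `species`, `chromosome`,
#'   `position`, `class`, `reclassified`, `origin`, `age_stratum`,
#'   `evidence`.
#' @export
classify_genes <- function(genes, best, map, target_species = NULL) {
  g <- genes$genes
  sp <- g$species[1]
  b <- best[best$query_id %in% g$gene_id, , drop = FALSE]
  if (!is.null(target_species))
    b <- b[b$target_species %in% target_species, , drop = FALSE]
  b <- b[b$target_species != sp, , drop = FALSE]
  qc <- g$chromosome[match(b$query_id, g$gene_id)]
  b$syntenic_hit <- is_syntenic_location(map, sp, qc, b$target_species,
                                         b$subject_chromosome, b$subject_pos)
  ev <- vapply(split(seq_len(nrow(b)), factor(b$query_id)), function(ix)
    paste(sprintf("%s:%s=%s", b$target_species[ix],
                  b$subject_chromosome[ix],
                  ifelse(b$syntenic_hit[ix], "syntenic", "other")),
          collapse = ";"), character(1))
  any_syn <- vapply(split(b$syntenic_hit, factor(b$query_id)), any,
                    logical(1))
  no_hits <- setdiff(g$gene_id, b$query_id)
  if (length(no_hits))
    warning(length(no_hits), " core gene(s) of ", sp,
            " have no best hits; classified non-syntenic")
  cls <- ifelse(g$gene_id %in% names(any_syn)[any_syn],
                "syntenic", "non-syntenic")
  data.frame(gene_id = g$gene_id, species = sp, chromosome = g$chromosome,
             position = gene_midpoints(genes),
             class = cls, reclassified = FALSE,
             origin = NA_character_, age_stratum = NA_character_,
             evidence = ifelse(g$gene_id %in% names(ev),
                               ev[g$gene_id], "no_hits"),
             stringsAsFactors = FALSE)
}

#' Reclassify non-syntenic genes by annotation-independent genomic search
#'
#' Guards against calling a gene non-syntenic merely because its ortholog
#' was never annotated: each non-syntenic gene's CDS is searched against the
#' genomic sequence of the orthologous chromosomes in the other species, and
#' flipped to syntenic when a nucleotide hit at `min_identity` percent
#' identity and `min_overlap` percent query coverage falls inside an
#' orthology block.
#'
#' @param calls `synteny_calls` for one species.
#' @param genes the species' core [gene_set()] (CDS populated).
#' @param pseudomolecules named list (by species) of `DNAStringSet`
#'   chromosome sequences.
#' @param map a [synteny_map()].
#' @param min_identity,min_overlap thresholds (defaults 80, 50).
#' @param word_size seed length of the nucleotide search.
#' @param min_cluster_seeds co-diagonal seed words required before a region
#'   is extended; hits at the 80%/50% thresholds carry dozens.
#' @return updated calls with `reclassified = TRUE` on flipped genes.
#' @export
reclassify_by_genomic_search <- function(calls, genes, pseudomolecules, map,
                                         min_identity = 80, min_overlap = 50,
                                         word_size = 11,
                                         min_cluster_seeds = 4) {
  ns <- which(calls$class == "non-syntenic")
  if (length(ns) == 0L) return(calls)
  sp <- calls$species[1]
  t <- genes$transcripts
  b <- map$blocks
  for (chrom in unique(calls$chromosome[ns])) {
    idx <- ns[calls$chromosome[ns] == chrom]
    qids <- calls$gene_id[idx]
    q <- stats::setNames(t$cds_seq[match(qids, t$gene_id)], qids)
    q <- q[!is.na(q)]
    if (length(q) == 0L) next
    tgt <- b[b$species_a == sp & b$chrom_a == chrom & b$species_b != sp, ,
             drop = FALSE]
    subs <- character(0)
    for (r in seq_len(nrow(tgt))) {
      sp_b <- tgt$species_b[r]
      ch_b <- tgt$chrom_b[r]
      if (is.null(pseudomolecules[[sp_b]]) ||
          !ch_b %in% names(pseudomolecules[[sp_b]])) {
        warning("missing pseudomolecule ", sp_b, ":", ch_b,
                "; genes left unchanged for that target")
        next
      }
      nm <- paste(sp_b, ch_b, sep = "::")
      if (!nm %in% names(subs))
        subs[nm] <- as.character(pseudomolecules[[sp_b]][[ch_b]])
    }
    if (length(subs) == 0L) next
    h <- search_nucleotide(q, subs, word_size = word_size,
                           min_cluster_seeds = min_cluster_seeds)
    if (nrow(h) == 0L) next
    h$overlap <- 100 * (abs(h$q_end - h$q_start) + 1) / nchar(q[h$query_id])
    parts <- strsplit(h$subject_id, "::", fixed = TRUE)
    h$sp_b <- vapply(parts, `[`, character(1), 1)
    h$ch_b <- vapply(parts, `[`, character(1), 2)
    mid <- (h$s_start + h$s_end) / 2
    in_block <- is_syntenic_location(map, sp, chrom, h$sp_b, h$ch_b, mid)
    ok <- h$pct_identity >= min_identity & h$overlap >= min_overlap &
      in_block
    flip <- unique(h$query_id[ok])
    sel <- calls$gene_id %in% flip
    calls$class[sel] <- "syntenic"
    calls$reclassified[sel] <- TRUE
  }
  calls
}

#' Detect duplication origin of non-syntenic genes
#'
#' A non-syntenic gene is flagged `origin = "duplication"` when its CDS has
#' a nucleotide hit at `min_identity` / `min_overlap` on a *non-homeologous*
#' chromosome of its own genome's survey sequences (evidence that a second
#' copy survives elsewhere); otherwise `"unresolved"` (translocation, lost
#' ancestral copy, or missing data).
#'
#' @param calls `synteny_calls` for one species.
#' @param genes the species' core [gene_set()].
#' @param survey_seqs `DNAStringSet` of the species' chromosome (survey)
#'   sequences, named by chromosome.
#' @param homeolog_groups list of character vectors of chromosome names; the
#'   group containing the gene's own chromosome is excluded from the search.
#' @param min_identity,min_overlap thresholds (defaults 80, 50).
#' @param word_size seed length.
#' @param min_cluster_seeds co-diagonal seed words required per extension.
#' @return updated calls with `origin` filled for non-syntenic genes.
#' @export
detect_duplicate_origin <- function(calls, genes, survey_seqs,
                                    homeolog_groups = NULL,
                                    min_identity = 80, min_overlap = 50,
                                    word_size = 11, min_cluster_seeds = 4) {
  ns <- which(calls$class == "non-syntenic")
  if (length(ns) == 0L) return(calls)
  t <- genes$transcripts
  calls$origin[ns] <- "unresolved"
  group_of <- function(chrom) {
    if (!is.null(homeolog_groups))
      for (grp in homeolog_groups) if (chrom %in% grp) return(grp)
    chrom
  }
  for (chrom in unique(calls$chromosome[ns])) {
    idx <- ns[calls$chromosome[ns] == chrom]
    qids <- calls$gene_id[idx]
    q <- stats::setNames(t$cds_seq[match(qids, t$gene_id)], qids)
    q <- q[!is.na(q)]
    if (length(q) == 0L) next
    excl <- group_of(chrom)
    keep <- setdiff(names(survey_seqs), excl)
    if (length(keep) == 0L) next
    subs <- stats::setNames(as.character(survey_seqs[keep]), keep)
    h <- search_nucleotide(q, subs, word_size = word_size,
                           min_cluster_seeds = min_cluster_seeds)
    if (nrow(h) == 0L) next
    h$overlap <- 100 * (abs(h$q_end - h$q_start) + 1) / nchar(q[h$query_id])
    ok <- h$pct_identity >= min_identity & h$overlap >= min_overlap
    dup <- unique(h$query_id[ok])
    calls$origin[calls$gene_id %in% dup] <- "duplication"
  }
  calls
}

#' Stratify non-syntenic genes by relocation age
#'
#' A non-syntenic gene is `recent` when no qualifying protein hit
#' (homology-filter thresholds) is found in any of the close-relative gene
#' sets on a chromosome orthologous to the gene's own; `old` otherwise
#' (i.e. the relocated copy predates the relatives' divergence).
#'
#' @param calls `synteny_calls` for the focal species.
#' @param genes the focal core [gene_set()].
#' @param hits annotated hit table (queries include focal genes, subjects
#'   include the relatives' genes).
#' @param relative_species character vector (e.g. homeolog A, homeolog D,
#'   sister species).
#' @param map a [synteny_map()] covering focal vs relatives.
#' @param max_evalue,min_identity,min_overlap qualifying-hit thresholds
#'   (defaults 1e-5, 35, 35).
#' @return updated calls with `age_stratum` (`recent` / `old`) on
#'   non-syntenic genes.
#' @export
stratify_age <- function(calls, genes, hits, relative_species, map,
                         max_evalue = 1e-5, min_identity = 35,
                         min_overlap = 35) {
  ns <- which(calls$class == "non-syntenic")
  if (length(ns) == 0L) return(calls)
  sp <- calls$species[1]
  t <- genes$transcripts
  qlen <- stats::setNames(nchar(.strip_stop(t$protein)), t$gene_id)
  h <- hits[hits$query_id %in% calls$gene_id[ns] &
              !is.na(hits$subject_species) &
              hits$subject_species %in% relative_species, , drop = FALSE]
  h$overlap <- 100 * (abs(h$q_end - h$q_start) + 1) / qlen[h$query_id]
  h <- h[h$evalue <= max_evalue & h$pct_identity >= min_identity &
           h$overlap >= min_overlap, , drop = FALSE]
  qc <- calls$chromosome[match(h$query_id, calls$gene_id)]
  on_orth <- is_syntenic_location(map, sp, qc, h$subject_species,
                                  h$subject_chromosome, h$subject_pos)
  old_ids <- unique(h$query_id[on_orth])
  calls$age_stratum[ns] <- ifelse(calls$gene_id[ns] %in% old_ids,
                                  "old", "recent")
  calls
}

#' Duplicate families and random representatives
#'
#' Builds single-linkage families (connected components) over same-species,
#' same-chromosome gene pairs whose protein hits pass the homology-filter
#' thresholds, then draws one representative per family uniformly at random
#' under the given seed. Genes without qualifying intra-chromosome hits form
#' singleton families.
#'
#' @param genes a [gene_set()] for one species.
#' @param hits annotated hit table including same-species hits.
#' @param seed integer seed for representative draws.
#' @param max_evalue,min_identity,min_overlap thresholds (1e-5, 35, 35).
#' @return data frame `gene_id`, `family_id`, `representative` (logical).
#' @export
build_duplicate_families <- function(genes, hits, seed = 1,
                                     max_evalue = 1e-5, min_identity = 35,
                                     min_overlap = 35) {
  g <- genes$genes
  t <- genes$transcripts
  qlen <- stats::setNames(nchar(.strip_stop(t$protein)), t$gene_id)
  h <- hits[hits$query_id %in% g$gene_id & hits$subject_id %in% g$gene_id &
              hits$query_id != hits$subject_id, , drop = FALSE]
  qc <- g$chromosome[match(h$query_id, g$gene_id)]
  sc <- g$chromosome[match(h$subject_id, g$gene_id)]
  h <- h[qc == sc, , drop = FALSE]
  if (nrow(h)) {
    h$overlap <- 100 * (abs(h$q_end - h$q_start) + 1) / qlen[h$query_id]
    h <- h[h$evalue <= max_evalue & h$pct_identity >= min_identity &
             h$overlap >= min_overlap, , drop = FALSE]
  }
  # union-find over gene ids
  parent <- stats::setNames(seq_along(g$gene_id), g$gene_id)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(h)) {
    qi <- match(h$query_id, g$gene_id)
    si <- match(h$subject_id, g$gene_id)
    for (k in seq_len(nrow(h))) {
      a <- find(qi[k])
      b <- find(si[k])
      if (a != b) parent[a] <- b
    }
  }
  root <- vapply(seq_along(parent), find, numeric(1))
  fam <- match(root, sort(unique(root)))
  out <- data.frame(gene_id = g$gene_id,
                    family_id = sprintf("fam%05d", fam),
                    representative = FALSE, stringsAsFactors = FALSE)
  .with_seed(seed, {
    for (f in split(seq_len(nrow(out)), out$family_id)) {
      pick <- f[sample.int(length(f), 1L)]
      out$representative[pick] <- TRUE
    }
  })
  out
}
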