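# End-to-end orchestration: filtration -> homology -> classification ->
# reclassification -> rates -> landscapes (-> Ka/Ks), from a simulated clade
# or from loaded inputs, under one seed and one set of thresholds.

#' Pipeline parameters
#'
#' All thresholds of the analysis, defaulting to the printed study values:
#' e-value 1e-5, identity 35 percent, overlap 35 percent for homology
#' support; 80 / 50 for the nucleotide reclassification and
#' duplication-origin searches; 0.70 for the pseudogene truncation rule.
#' `word_size` / `min_seed_hits` tune the built-in protein search used when
#' no precomputed hit table is supplied.
#'
#' @param max_evalue,min_identity,min_overlap homology-filter thresholds.
#' @param reclass_identity,reclass_overlap nucleotide search thresholds.
#' @param pseudogene_fraction truncation threshold.
#' @param window,step sliding-window sizes (bp).
#' @param word_size,min_seed_hits built-in protein search tuning.
#' @param nt_word_size nucleotide search seed length.
#' @param seed pipeline-level seed (representative draws).
#' @return list of class `scan_params`.
#' @export
scan_params <- function(max_evalue = 1e-5, min_identity = 35,
                        min_overlap = 35, reclass_identity = 80,
                        reclass_overlap = 50, pseudogene_fraction = 0.70,
                        window = 1e5, step = 1e4,
                        word_size = 5, min_seed_hits = 2,
                        nt_word_size = 11, seed = 1) {
  stopifnot(max_evalue > 0, min_identity >= 0, min_identity <= 100,
            min_overlap >= 0, min_overlap <= 100,
            reclass_identity >= 0, reclass_identity <= 100,
            reclass_overlap >= 0, reclass_overlap <= 100,
            pseudogene_fraction > 0, pseudogene_fraction <= 1,
            window >= step, step > 0)
  structure(list(max_evalue = max_evalue, min_identity = min_identity,
                 min_overlap = min_overlap,
                 reclass_identity = reclass_identity,
                 reclass_overlap = reclass_overlap,
                 pseudogene_fraction = pseudogene_fraction,
                 window = window, step = step, word_size = word_size,
                 min_seed_hits = min_seed_hits,
                 nt_word_size = nt_word_size, seed = as.integer(seed)),
            class = "scan_params")
}

#' Run the full synteny-duplication analysis
#'
#' Executes the stages in order: isoform collapse, all-vs-all protein search
#' (unless a hit table is supplied), four-stage filtration per species,
#' best-hit selection, synteny classification, annotation-independent
#' reclassification (when chromosome sequences are available), fixation
#' rates against the nearest compared relative, and sliding-window
#' landscapes.
#'
#' @param genes named list of [gene_set()] (one per species), or a
#'   `clade_sim` from [simulate_clade()] (genes, map, lineage and
#'   chromosomes are then taken from it).
#' @param map a [synteny_map()].
#' @param lineage a [lineage_config()].
#' @param hits optional precomputed hit table (12/13 column, protein level);
#'   when `NULL` the built-in [search_proteins()] runs on the collapsed
#'   proteins of all species.
#' @param chromosomes optional named list of `DNAStringSet` pseudomolecule
#'   sequences per species (enables reclassification).
#' @param classify_species species to classify (default: all in `genes`
#'   that appear in the synteny map); classification evidence is restricted
#'   to these species.
#' @param params a [scan_params()].
#' @param reclassify run the genomic reclassification stage.
#' @return object of class `synteny_scan`: per-species `core` gene sets,
#'   `reports`, `calls` (one combined data frame), `rates`, `summary` table,
#'   `profiles` (per species/chromosome window profiles with centromere
#'   correlations), `hits` (the table used) and `params`.
#' @export
synteny_scan <- function(genes, map = NULL, lineage = NULL, hits = NULL,
                         chromosomes = NULL, classify_species = NULL,
                         params = scan_params(), reclassify = TRUE) {
  if (inherits(genes, "clade_sim")) {
    sim <- genes
    genes <- sim$genes
    if (is.null(map)) map <- sim$map
    if (is.null(lineage)) lineage <- sim$lineage
    if (is.null(chromosomes)) chromosomes <- sim$chromosomes
    if (is.null(classify_species))
      classify_species <- sim$config$species
  }
  stopifnot(inherits(map, "synteny_map"), inherits(lineage, "lineage_config"))
  if (is.null(classify_species))
    classify_species <- intersect(names(genes),
                                  unique(map$blocks$species_a))
  log_stage <- function(...) message("[synteny_scan] ", ...)

  collapsed <- lapply(genes, collapse_isoforms)
  prot_len <- stats::setNames(
    unlist(lapply(collapsed, function(gs)
      nchar(.strip_stop(gs$transcripts$protein))), use.names = FALSE),
    unlist(lapply(collapsed, function(gs) gs$transcripts$gene_id),
           use.names = FALSE))

  if (is.null(hits)) {
    prots <- unlist(lapply(collapsed, .as_protein_vector))
    # names are gene ids (unlist may prefix with species name; rebuild)
    nm <- unlist(lapply(collapsed, function(gs)
      gs$transcripts$gene_id[!is.na(gs$transcripts$protein) &
                               nzchar(gs$transcripts$protein)]))
    names(prots) <- nm
    log_stage("built-in protein search over ", length(prots), " proteins")
    hits <- search_proteins(prots, prots, word_size = params$word_size,
                            min_seed_hits = params$min_seed_hits,
                            max_evalue = 10)
  }
  hits <- annotate_hits(hits, collapsed)

  cores <- list()
  reports <- list()
  for (sp in names(genes)) {
    other <- setdiff(names(genes), sp)
    fr <- run_filtration(collapsed[[sp]], hits, other,
                         subject_lengths = prot_len,
                         max_evalue = params$max_evalue,
                         min_identity = params$min_identity,
                         min_overlap = params$min_overlap,
                         pseudogene_fraction = params$pseudogene_fraction)
    cores[[sp]] <- fr$core
    reports[[sp]] <- fr$report
    log_stage("filtration ", sp, ": ",
              paste(names(fr$report$counts), fr$report$counts,
                    sep = "=", collapse = ", "))
  }

  core_ids <- unlist(lapply(cores, function(gs) gs$genes$gene_id))
  hcore <- hits[hits$query_id %in% core_ids &
                  hits$subject_id %in% core_ids, , drop = FALSE]
  best <- best_hits(hcore, max_evalue = params$max_evalue)

  calls <- list()
  for (sp in intersect(classify_species, names(genes))) {
    cl <- classify_genes(cores[[sp]], best, map,
                         target_species = setdiff(classify_species, sp))
    if (reclassify && !is.null(chromosomes))
      cl <- reclassify_by_genomic_search(
        cl, cores[[sp]], chromosomes, map,
        min_identity = params$reclass_identity,
        min_overlap = params$reclass_overlap,
        word_size = params$nt_word_size)
    calls[[sp]] <- cl
    log_stage("classified ", sp, ": ",
              sum(cl$class == "syntenic"), " syntenic / ",
              sum(cl$class == "non-syntenic"), " non-syntenic")
  }

  rates <- list()
  for (sp in names(calls)) {
    others <- setdiff(names(calls), sp)
    t_div <- min(lineage$divergence[sp, others])
    rates[[sp]] <- fixation_rate(sum(calls[[sp]]$class == "non-syntenic"),
                                 nrow(calls[[sp]]), t_div)
  }

  smry <- do.call(rbind, lapply(names(calls), function(sp) {
    r <- rates[[sp]]
    data.frame(species = sp, core_genes = r$n_total,
               syntenic = r$n_total - r$n_nonsyntenic,
               nonsyntenic = r$n_nonsyntenic,
               pct_nonsyntenic = r$percent_nonsyntenic,
               divergence_my = r$divergence_my, rate = r$rate,
               stringsAsFactors = FALSE)
  }))

  profiles <- list()
  cents <- map$centromeres
  for (sp in names(calls)) {
    cl <- calls[[sp]]
    for (chrom in sort(unique(cl$chromosome))) {
      sel <- cl$chromosome == chrom
      blk <- map$blocks[map$blocks$species_a == sp &
                          map$blocks$chrom_a == chrom, , drop = FALSE]
      clen <- if (nrow(blk)) max(blk$end_a) else max(cl$position[sel])
      cent <- if (!is.null(cents)) {
        hit <- cents$species == sp & cents$chromosome == chrom
        if (any(hit)) cents$centromere[hit][1] else NULL
      } else NULL
      profiles[[paste(sp, chrom, sep = ":")]] <- sliding_proportion(
        cl$position[sel], cl$class[sel] == "non-syntenic",
        params$window, params$step, clen, cent, chromosome = chrom)
    }
  }

  structure(list(core = cores, reports = reports,
                 calls = do.call(rbind, c(calls, make.row.names = FALSE)),
                 best = best, rates = rates, summary = smry,
                 profiles = profiles, hits = hits, params = params,
                 map = map, lineage = lineage),
            class = "synteny_scan")
}

#' @export
print.synteny_scan <- function(x, ...) {
  cat("synteny_scan over", length(x$core), "species\n")
  print(transform(x$summary,
                  pct_nonsyntenic = round(pct_nonsyntenic, 1),
                  rate = signif(rate, 2)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.synteny_scan <- function(object, ...) {
  cat("Synteny classification summary\n\n")
  print(object)
  cat("\nFiltration stages:\n")
  for (sp in names(object$reports)) print(object$reports[[sp]])
  r <- vapply(object$rates, `[[`, numeric(1), "rate")
  if (length(r) > 1) {
    focal <- names(which.max(r))
    contrast <- r[focal] / mean(r[names(r) != focal])
    cat(sprintf("\nHighest rate: %s (%.1fx the mean of the others)\n",
                focal, contrast))
  }
  cors <- vapply(object$profiles, function(p) {
    ok <- !is.null(attr(p, "centromere")) && sum(!is.na(p$proportion)) >= 3
    if (ok) suppressWarnings(centromere_distance_correlation(p))
    else NA_real_
  }, numeric(1))
  cors <- cors[!is.na(cors)]
  if (length(cors)) {
    cat("\nCentromere-distance correlations (Pearson r):\n")
    for (nm in names(cors)) cat(sprintf("  %-16s %+.3f\n", nm, cors[nm]))
  }
  invisible(object)
}

#' @export
plot.synteny_scan <- function(x, which = names(x$profiles)[1], ...) {
  plot(x$profiles[[which]], ...)
  invisible(x)
}
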