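# Synteny map (chromosome-level orthology blocks + centromeres) and lineage
# configuration (divergence times, homeolog groups, outgroup).

#' Chromosome-level synteny map
#'
#' Holds, per species pair, the orthology blocks (which interval of which
#' chromosome in species A corresponds to which interval in species B) and
#' the centromere position of each chromosome. Blocks are symmetrised on
#' construction: a block A-B implies the mirrored block B-A.
#'
#' @param blocks data frame with columns `species_a`, `chrom_a`, `start_a`,
#'   `end_a`, `species_b`, `chrom_b`, `start_b`, `end_b` (bp, 1-based
#'   inclusive).
#' @param centromeres optional data frame `species`, `chromosome`,
#'   `centromere` (bp).
#' @return object of class `synteny_map`.
#' @export
synteny_map <- function(blocks, centromeres = NULL) {
  need <- c("species_a", "chrom_a", "start_a", "end_a",
            "species_b", "chrom_b", "start_b", "end_b")
  stopifnot(all(need %in% names(blocks)))
  if (any(blocks$start_a > blocks$end_a | blocks$start_b > blocks$end_b))
    stop("block with start > end")
  mirror <- data.frame(species_a = blocks$species_b, chrom_a = blocks$chrom_b,
                       start_a = blocks$start_b, end_a = blocks$end_b,
                       species_b = blocks$species_a, chrom_b = blocks$chrom_a,
                       start_b = blocks$start_a, end_b = blocks$end_a,
                       stringsAsFactors = FALSE)
  all_blocks <- unique(rbind(blocks[, need], mirror[, need]))
  structure(list(blocks = all_blocks, centromeres = centromeres),
            class = "synteny_map")
}

#' @export
print.synteny_map <- function(x, ...) {
  cat("synteny_map:", nrow(x$blocks), "directed blocks over",
      length(unique(c(x$blocks$species_a, x$blocks$species_b))), "species\n")
  invisible(x)
}

#' Identity synteny map over shared chromosome names
#'
#' Convenience constructor for genomes whose orthologous chromosomes share
#' names: every chromosome maps full-length to the same-named chromosome in
#' every other species. Used by the clade simulator.
#'
#' @param species character vector of species names.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp),
#'   shared across species, or a list per species.
#' @param centromeres optional named vector of centromere positions.
#' @return a [synteny_map()].
#' @export
identity_synteny_map <- function(species, chrom_lengths, centromeres = NULL) {
  if (!is.list(chrom_lengths))
    chrom_lengths <- stats::setNames(
      rep(list(chrom_lengths), length(species)), species)
  pairs <- utils::combn(species, 2)
  blocks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    chroms <- intersect(names(chrom_lengths[[a]]), names(chrom_lengths[[b]]))
    data.frame(species_a = a, chrom_a = chroms, start_a = 1L,
               end_a = as.numeric(chrom_lengths[[a]][chroms]),
               species_b = b, chrom_b = chroms, start_b = 1L,
               end_b = as.numeric(chrom_lengths[[b]][chroms]),
               stringsAsFactors = FALSE)
  }))
  cent <- NULL
  if (!is.null(centromeres))
    cent <- do.call(rbind, lapply(species, function(s)
      data.frame(species = s, chromosome = names(centromeres),
                 centromere = as.numeric(centromeres),
                 stringsAsFactors = FALSE)))
  synteny_map(blocks, cent)
}

#' Is a subject location on the syntenic counterpart of a query chromosome?
#'
#' Vectorised over hits: `TRUE` where the map contains a block linking the
#' query chromosome (in the query species) to the subject chromosome, with
#' the subject position inside the block's subject-side interval.
#'
#' @param map a [synteny_map()].
#' @param query_species,query_chrom query gene location (recycled).
#' @param subject_species,subject_chrom,subject_pos hit locations.
#' @return logical vector.
#' @export
is_syntenic_location <- function(map, query_species, query_chrom,
                                 subject_species, subject_chrom,
                                 subject_pos) {
  n <- max(length(subject_chrom), length(query_chrom))
  query_species <- rep_len(query_species, n)
  query_chrom <- rep_len(query_chrom, n)
  subject_species <- rep_len(subject_species, n)
  subject_chrom <- rep_len(subject_chrom, n)
  subject_pos <- rep_len(as.numeric(subject_pos), n)
  b <- map$blocks
  vapply(seq_len(n), function(i) {
    sel <- b$species_a == query_species[i] & b$chrom_a == query_chrom[i] &
      b$species_b == subject_species[i] & b$chrom_b == subject_chrom[i]
    if (!any(sel)) return(FALSE)
    pos <- subject_pos[i]
    if (is.na(pos)) return(TRUE)  # chromosome-level evidence only
    any(pos >= b$start_b[sel] & pos <= b$end_b[sel])
  }, logical(1))
}

#' Which genes lie inside the mapped syntenic regions of their own species?
#'
#' @param map a [synteny_map()].
#' @param genes a [gene_set()].
#' @return logical vector over `genes$genes`.
#' @export
in_synteny_regions <- function(map, genes) {
  g <- genes$genes
  pos <- gene_midpoints(genes)
  b <- map$blocks
  vapply(seq_len(nrow(g)), function(i) {
    sel <- b$species_a == g$species[i] & b$chrom_a == g$chromosome[i]
    any(sel & pos[i] >= b$start_a & pos[i] <= b$end_a)
  }, logical(1))
}

#' Lineage configuration
#'
#' Species list, pairwise divergence times (million years), homeolog
#' chromosome groups (subgenome copies of an allopolyploid) and the outgroup
#' species used for Ka/Ks pairing.
#'
#' @param species character vector.
#' @param divergence data frame `species_a`, `species_b`, `my` or a symmetric
#'   named matrix of divergence times.
#' @param homeolog_groups optional list of character vectors of chromosome
#'   names forming homeologous groups.
#' @param outgroup optional species name.
#' @return object of class `lineage_config`.
#' @export
lineage_config <- function(species, divergence, homeolog_groups = NULL,
                           outgroup = NULL) {
  if (is.data.frame(divergence)) {
    m <- matrix(NA_real_, length(species), length(species),
                dimnames = list(species, species))
    diag(m) <- 0
    for (i in seq_len(nrow(divergence))) {
      a <- divergence$species_a[i]; b <- divergence$species_b[i]
      m[a, b] <- m[b, a] <- divergence$my[i]
    }
    divergence <- m
  }
  stopifnot(identical(rownames(divergence), species),
            isTRUE(all.equal(divergence, t(divergence))))
  off <- divergence[upper.tri(divergence)]
  if (any(!is.na(off) & off <= 0)) stop("divergence times must be positive")
  if (!is.null(outgroup)) stopifnot(outgroup %in% species)
  structure(list(species = species, divergence = divergence,
                 homeolog_groups = homeolog_groups, outgroup = outgroup),
            class = "lineage_config")
}

#' @export
print.lineage_config <- function(x, ...) {
  cat("lineage_config:", paste(x$species, collapse = ", "))
  if (!is.null(x$outgroup)) cat(" (outgroup:", x$outgroup, ")")
  cat("\n")
  invisible(x)
}

#' Divergence time between two species
#' @param config a [lineage_config()].
#' @param a,b species names.
#' @export
divergence_time <- function(config, a, b) config$divergence[a, b]
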