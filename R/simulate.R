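# Multi-species clade simulator. Generates genomes on the fixed four-taxon
# grass-like topology (splits at 39 / 54 / 60 MY, optionally a focal
# subclade with homeolog copies at 6.5 MY and a sister lineage at 11.6 MY),
# with ancestral genes placed collinearly on orthologous chromosomes,
# lineage-specific interchromosomal duplications/translocations,
# pseudogenization, TE and splice-variant decoys, and codon-level sequence
# divergence at a configurable Ka/Ks. Every emitted gene carries a ground
# truth record.

.BASE_CHARS <- c("A", "C", "G", "T")

.codon_cache <- new.env(parent = emptyenv())

# 64-entry lookup: codon id (16*b1 + 4*b2 + b3, bases 0..3 = ACGT) -> amino
# acid index, 0 for stop codons.
.aa64 <- function() {
  if (!is.null(.codon_cache$aa64)) return(.codon_cache$aa64)
  gc <- .genetic_code()
  ids <- expand.grid(b3 = 0:3, b2 = 0:3, b1 = 0:3)
  codons <- paste0(.BASE_CHARS[ids$b1 + 1], .BASE_CHARS[ids$b2 + 1],
                   .BASE_CHARS[ids$b3 + 1])
  aa <- gc[codons]
  lev <- setdiff(unique(gc), "*")
  v <- ifelse(aa == "*", 0L, match(aa, lev))
  ord <- 16L * ids$b1 + 4L * ids$b2 + ids$b3 + 1L
  out <- integer(64)
  out[ord] <- v
  .codon_cache$aa64 <- out
  out
}

.revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", intToUtf8(rev(utf8ToInt(s))))
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defines the study conditions for [simulate_clade()]. Defaults emulate the
#' comparative setting of a focal, duplication-rich lineage (`taes`) against
#' three model-grass-like relatives (`bdis`, `osat`, `sbic`) with splits at
#' 39, 54 and 60 MY and per-lineage fixation rates of 7.0e-3, 2.0e-3, 1.7e-3
#' and 2.3e-3 events per locus per MY.
#'
#' @param n_ancestral_genes ancestral loci shared by all species.
#' @param n_chromosomes chromosomes per species (orthologous by name).
#' @param duplication_rate named per-species rates (events/locus/MY) of
#'   interchromosomal duplication along the terminal branches; internal
#'   branches use the mean of their descendants' rates.
#' @param p_duplication probability an event retains the ancestral copy
#'   (duplication); otherwise the ancestral copy is removed (translocation).
#' @param pseudogenization_prob probability a new copy is emitted as a
#'   pseudogene (internal stop, 1-2 bp frameshift, or truncation below 70%
#'   length, chosen uniformly).
#' @param te_decoy_fraction fraction of extra TE-annotated decoy genes.
#' @param asv_decoy_fraction fraction of genes given extra (shorter) splice
#'   variants.
#' @param omega target Ka/Ks of the codon substitution process.
#' @param syn_rate_per_my synonymous divergence per site per MY.
#' @param cds_length ancestral CDS length in bp (multiple of 3).
#' @param intergenic_mean mean intergenic spacer length (bp).
#' @param insertion_bias placement of new copies along the target
#'   chromosome: `"none"` (uniform), `"distal"` or `"centromeric"`.
#' @param homeolog_mode add homeolog lineages (relA/relD, split 6.5 MY) and a
#'   sister lineage (11.6 MY) to the focal species for age stratification.
#' @param multi_exon emit 2-4 exon gene models instead of single-exon.
#' @param sequences simulate coding sequences (disable for fast
#'   position-only studies).
#' @param n_conditions,expr_prob,expr_breadth,fpkm_meanlog,fpkm_sdlog
#'   expression-table parameters (per true class syntenic/non-syntenic).
#' @param seed integer; fixes all randomness.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_ancestral_genes = 1000,
                              n_chromosomes = 4,
                              duplication_rate = c(taes = 7.0e-3,
                                                   bdis = 2.0e-3,
                                                   osat = 1.7e-3,
                                                   sbic = 2.3e-3),
                              p_duplication = 0.52,
                              pseudogenization_prob = 0.10,
                              te_decoy_fraction = 0.10,
                              asv_decoy_fraction = 0.30,
                              omega = 0.3,
                              syn_rate_per_my = 0.005,
                              cds_length = 900,
                              intergenic_mean = 300,
                              insertion_bias = c("none", "distal",
                                                 "centromeric"),
                              homeolog_mode = FALSE,
                              multi_exon = FALSE,
                              sequences = TRUE,
                              n_conditions = 15,
                              expr_prob = c(syntenic = 0.83,
                                            nonsyntenic = 0.74),
                              expr_breadth = c(syntenic = 0.80,
                                               nonsyntenic = 0.61),
                              fpkm_meanlog = c(syntenic = log(130),
                                               nonsyntenic = log(46)),
                              fpkm_sdlog = 1,
                              seed = 1) {
  insertion_bias <- match.arg(insertion_bias)
  species <- c("taes", "bdis", "osat", "sbic")
  stopifnot(all(species %in% names(duplication_rate)),
            all(duplication_rate >= 0),
            p_duplication >= 0, p_duplication <= 1,
            pseudogenization_prob >= 0, pseudogenization_prob <= 1,
            te_decoy_fraction >= 0, te_decoy_fraction <= 1,
            asv_decoy_fraction >= 0, asv_decoy_fraction <= 1,
            omega >= 0, syn_rate_per_my >= 0,
            cds_length %% 3 == 0, cds_length >= 9,
            n_chromosomes >= 2, n_ancestral_genes >= 1)
  structure(list(
    species = species, focal = "taes",
    split_times = c(bdis = 39, osat = 54, sbic = 60),
    homeolog_splits = c(sister = 11.6, homeolog = 6.5),
    n_ancestral_genes = as.integer(n_ancestral_genes),
    n_chromosomes = as.integer(n_chromosomes),
    duplication_rate = duplication_rate[species],
    p_duplication = p_duplication,
    pseudogenization_prob = pseudogenization_prob,
    te_decoy_fraction = te_decoy_fraction,
    asv_decoy_fraction = asv_decoy_fraction,
    omega = omega, syn_rate_per_my = syn_rate_per_my,
    cds_length = as.integer(cds_length),
    intergenic_mean = intergenic_mean,
    insertion_bias = insertion_bias,
    homeolog_mode = isTRUE(homeolog_mode),
    multi_exon = isTRUE(multi_exon),
    sequences = isTRUE(sequences),
    n_conditions = as.integer(n_conditions),
    expr_prob = expr_prob, expr_breadth = expr_breadth,
    fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
    seed = as.integer(seed)),
    class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", x$n_ancestral_genes, "loci,",
      x$n_chromosomes, "chromosomes,",
      if (x$homeolog_mode) "homeolog mode," else "4 taxa,",
      "seed", x$seed, "\n")
  invisible(x)
}

# Fixed topology as nested branch list. Each node: t_top (branch start,
# MYA), t_bottom, rate, and either $tip (species) or $children.
.build_tree <- function(config) {
  r <- config$duplication_rate
  tip <- function(sp, top, rate) list(t_top = top, t_bottom = 0,
                                      rate = rate, tip = sp)
  focal_subtree <- if (!config$homeolog_mode) {
    tip("taes", 39, r[["taes"]])
  } else {
    hs <- config$homeolog_splits
    list(t_top = 39, t_bottom = hs[["sister"]], rate = r[["taes"]],
         children = list(
           tip("sister", hs[["sister"]], r[["taes"]]),
           list(t_top = hs[["sister"]], t_bottom = hs[["homeolog"]],
                rate = r[["taes"]],
                children = list(tip("taes", hs[["homeolog"]], r[["taes"]]),
                                tip("relA", hs[["homeolog"]], r[["taes"]]),
                                tip("relD", hs[["homeolog"]], r[["taes"]])))))
  }
  list(t_top = 60, t_bottom = 60, rate = 0, children = list(
    tip("sbic", 60, r[["sbic"]]),
    list(t_top = 60, t_bottom = 54,
         rate = mean(r[c("taes", "bdis", "osat")]),
         children = list(
           tip("osat", 54, r[["osat"]]),
           list(t_top = 54, t_bottom = 39, rate = mean(r[c("taes", "bdis")]),
                children = list(tip("bdis", 39, r[["bdis"]]),
                                focal_subtree))))))
}

.all_tip_species <- function(config) {
  if (config$homeolog_mode) c(config$species, "relA", "relD", "sister")
  else config$species
}

# Divergence-time matrix over all emitted tips.
.divergence_matrix <- function(config) {
  sp <- .all_tip_species(config)
  st <- config$split_times
  d <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  diag(d) <- 0
  focal_grp <- intersect(sp, c("taes", "relA", "relD", "sister"))
  tsplit <- function(a, b) {
    if (a == b) return(0)
    ga <- a %in% focal_grp
    gb <- b %in% focal_grp
    if (ga && gb) {
      if (a == "sister" || b == "sister") return(config$homeolog_splits[["sister"]])
      return(config$homeolog_splits[["homeolog"]])
    }
    depth <- function(x) {
      if (x %in% focal_grp) return(0)  # focal side
      st[[x]]
    }
    # split of the focal clade with the non-focal species
    if (ga) return(st[[b]])
    if (gb) return(st[[a]])
    max(st[[a]], st[[b]])
  }
  for (a in sp) for (b in sp) d[a, b] <- tsplit(a, b)
  d
}

.sample_rel_pos <- function(n, bias) {
  u <- stats::runif(n)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  switch(bias,
         none = stats::runif(n),
         distal = 0.5 + sgn * 0.5 * sqrt(u),
         centromeric = 0.5 + sgn * 0.5 * (1 - sqrt(1 - u)))
}

# One round-based pass applying point-substitution proposals to an integer
# base matrix (rows = sequences). Proposals creating or destroying a stop
# codon are rejected; non-synonymous changes are accepted with probability
# omega, synonymous always.
.evolve_matrix <- function(mat, dt, mu, omega) {
  if (dt <= 0 || nrow(mat) == 0L || mu <= 0) return(mat)
  aa64 <- .aa64()
  ncell <- length(mat)
  n_prop <- stats::rpois(1, mu * ncell * dt)
  if (n_prop == 0) return(mat)
  cells <- sample.int(ncell, n_prop, replace = TRUE)
  nr <- nrow(mat)
  while (length(cells)) {
    rows <- (cells - 1L) %% nr + 1L
    cols <- (cells - 1L) %/% nr + 1L
    cd <- (cols - 1L) %/% 3L
    key <- rows + cd * nr
    first <- !duplicated(key)
    defer <- cells[!first]
    r <- rows[first]; cl <- cols[first]; c1 <- cd[first] * 3L + 1L
    b1 <- mat[cbind(r, c1)]
    b2 <- mat[cbind(r, c1 + 1L)]
    b3 <- mat[cbind(r, c1 + 2L)]
    old_codon <- 16L * b1 + 4L * b2 + b3 + 1L
    old_base <- mat[cbind(r, cl)]
    new_base <- (old_base + sample.int(3, length(r), replace = TRUE)) %% 4L
    mult <- c(16L, 4L, 1L)[(cl - c1) + 1L]
    new_codon <- old_codon + (new_base - old_base) * mult
    aa_old <- aa64[old_codon]
    aa_new <- aa64[new_codon]
    acc <- aa_old != 0L & aa_new != 0L &
      (aa_new == aa_old | stats::runif(length(r)) < omega)
    if (any(acc)) mat[cbind(r[acc], cl[acc])] <- new_base[acc]
    cells <- defer
  }
  mat
}

.random_cds_matrix <- function(n, len) {
  aa64 <- .aa64()
  n_codons <- len %/% 3L
  sense <- which(aa64 != 0L) - 1L  # codon ids 0..63
  ids <- matrix(sample(sense, n * n_codons, replace = TRUE), n, n_codons)
  ids[, 1] <- 16L * 0L + 4L * 3L + 2L  # ATG = A,T,G = 0,3,2
  stop_ids <- which(aa64 == 0L) - 1L
  ids[, n_codons] <- sample(stop_ids, n, replace = TRUE)
  mat <- matrix(0L, n, len)
  mat[, seq(1, len, 3)] <- ids %/% 16L
  mat[, seq(2, len, 3)] <- (ids %/% 4L) %% 4L
  mat[, seq(3, len, 3)] <- ids %% 4L
  mat
}

.mat_to_strings <- function(mat) {
  if (nrow(mat) == 0L) return(character(0))
  apply(mat, 1, function(row) paste(.BASE_CHARS[row + 1L], collapse = ""))
}

#' Simulate a clade with known duplication history
#'
#' Runs the event and sequence simulation over the fixed topology and emits,
#' per species, a [gene_set()] plus chromosome sequences, together with a
#' per-gene ground-truth table and event log. Identical seeds give identical
#' output.
#'
#' @param config a [simulation_config()].
#' @return object of class `clade_sim`: `genes` (named list of gene_set),
#'   `chromosomes` (named list of `DNAStringSet`, `NULL` without sequences),
#'   `truth` (per-gene data frame), `events` (event log), `map`
#'   ([synteny_map()]), `lineage` ([lineage_config()]), `config`.
#' @export
simulate_clade <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  exp_events <- max(config$duplication_rate) *
    max(config$split_times)
  if (exp_events > 1)
    warning("configured rates imply > 1 expected event per locus on some ",
            "branch; multiple events per locus are allowed")
  .with_seed(config$seed, .simulate_clade_impl(config))
}

.simulate_clade_impl <- function(config) {
  n <- config$n_ancestral_genes
  k <- config$n_chromosomes
  chroms <- paste0("chr", seq_len(k))
  env <- new.env(parent = emptyenv())
  env$uid <- n
  env$events <- list()
  env$copy_parent <- stats::setNames(rep(NA_integer_, n), seq_len(n))
  env$copy_birth <- stats::setNames(rep(Inf, n), seq_len(n))

  # ancestral placement: loci round-robin over chromosomes, collinear order
  anc_chrom <- rep(seq_len(k), length.out = n)
  rel <- stats::ave(seq_len(n), anc_chrom,
                    FUN = function(ix) seq_along(ix) / (length(ix) + 1))
  copies0 <- data.frame(uid = seq_len(n), locus = seq_len(n),
                        chrom = anc_chrom, rel_pos = rel,
                        birth_time = Inf, parent_uid = NA_integer_,
                        defect = "none", event_type = "ancestral",
                        stringsAsFactors = FALSE)
  mat0 <- if (config$sequences)
    .random_cds_matrix(n, config$cds_length) else NULL

  tips <- list()

  process <- function(node, copies, mat) {
    len <- node$t_top - node$t_bottom
    if (len > 0 && nrow(copies) > 0L) {
      nev <- stats::rpois(nrow(copies), node$rate * len)
      ev_parent <- rep(seq_len(nrow(copies)), nev)
      if (length(ev_parent)) {
        ev_time <- stats::runif(length(ev_parent), node$t_bottom, node$t_top)
        ord <- order(-ev_time)
        ev_parent <- ev_parent[ord]
        ev_time <- ev_time[ord]
        drop_rows <- integer(0)
        # per-row clock: rows touched by events evolve piecewise; the rest
        # evolve the whole branch in one batched call at the end
        last_t <- rep(node$t_top, nrow(copies))
        new_rows <- list()
        for (e in seq_along(ev_parent)) {
          p <- ev_parent[e]
          if (p %in% drop_rows) next  # parent already translocated away
          env$uid <- env$uid + 1L
          uid <- env$uid
          other <- setdiff(seq_len(config$n_chromosomes), copies$chrom[p])
          target <- other[sample.int(length(other), 1L)]
          defect <- if (stats::runif(1) < config$pseudogenization_prob)
            sample(c("internal_stop", "frameshift", "truncation"), 1L)
          else "none"
          # a copy of an internal-stop pseudogene inherits the dead
          # sequence (stops are sequence-level; the other defects are
          # annotation-level and not inherited)
          if (copies$defect[p] == "internal_stop" && defect == "none")
            defect <- "internal_stop"
          type <- if (stats::runif(1) < config$p_duplication)
            "duplication" else "translocation"
          newrow <- data.frame(uid = uid, locus = copies$locus[p],
                               chrom = target,
                               rel_pos = .sample_rel_pos(1, config$insertion_bias),
                               birth_time = ev_time[e],
                               parent_uid = copies$uid[p],
                               defect = defect, event_type = type,
                               stringsAsFactors = FALSE)
          env$copy_parent[as.character(uid)] <- copies$uid[p]
          env$copy_birth[as.character(uid)] <- ev_time[e]
          env$events[[length(env$events) + 1L]] <- data.frame(
            time = ev_time[e], type = type, locus = copies$locus[p],
            copy_uid = uid, parent_uid = copies$uid[p],
            from_chrom = chroms[copies$chrom[p]], to_chrom = chroms[target],
            defect = defect, stringsAsFactors = FALSE)
          copies <- rbind(copies, newrow)
          if (config$sequences) {
            if (p <= length(last_t)) {
              mat[p, ] <- .evolve_matrix(mat[p, , drop = FALSE],
                                         last_t[p] - ev_time[e],
                                         config$syn_rate_per_my,
                                         config$omega)
              last_t[p] <- ev_time[e]
            }
            row <- mat[p, , drop = FALSE]
            if (defect == "internal_stop") {
              # knock a stop into the middle third of the new copy
              rng <- seq(ceiling(ncol(mat) / 9), floor(2 * ncol(mat) / 9))
              cdn <- rng[sample.int(length(rng), 1L)]
              row[1, (3 * cdn - 2):(3 * cdn)] <- c(3L, 0L, 0L)  # TAA
            }
            mat <- rbind(mat, row)
            last_t <- c(last_t, ev_time[e])
          } else {
            last_t <- c(last_t, ev_time[e])
          }
          if (type == "translocation") drop_rows <- c(drop_rows, p)
        }
        if (config$sequences) {
          untouched <- which(last_t == node$t_top)
          if (length(untouched))
            mat[untouched, ] <- .evolve_matrix(
              mat[untouched, , drop = FALSE], len,
              config$syn_rate_per_my, config$omega)
          for (r in which(last_t < node$t_top))
            mat[r, ] <- .evolve_matrix(mat[r, , drop = FALSE],
                                       last_t[r] - node$t_bottom,
                                       config$syn_rate_per_my, config$omega)
        }
        if (length(drop_rows)) {
          keep <- setdiff(seq_len(nrow(copies)), drop_rows)
          copies <- copies[keep, , drop = FALSE]
          if (config$sequences) mat <- mat[keep, , drop = FALSE]
        }
      } else if (config$sequences) {
        mat <- .evolve_matrix(mat, len, config$syn_rate_per_my, config$omega)
      }
    }
    if (!is.null(node$tip)) {
      tips[[node$tip]] <<- list(copies = copies, mat = mat)
    } else {
      for (child in node$children) process(child, copies, mat)
    }
  }
  process(.build_tree(config), copies0, mat0)

  emitted <- lapply(names(tips), function(sp)
    .emit_species(sp, tips[[sp]], chroms, config, env))
  names(emitted) <- names(tips)

  truth <- do.call(rbind, lapply(emitted, `[[`, "truth"))
  rownames(truth) <- NULL
  truth <- .assign_true_classes(truth, config, env)

  genes <- lapply(emitted, `[[`, "gene_set")
  chrom_seqs <- if (config$sequences)
    lapply(emitted, `[[`, "chromosomes") else NULL
  chrom_lengths <- lapply(emitted, `[[`, "chrom_lengths")
  cent <- do.call(rbind, lapply(names(chrom_lengths), function(sp)
    data.frame(species = sp, chromosome = names(chrom_lengths[[sp]]),
               centromere = round(chrom_lengths[[sp]] / 2),
               stringsAsFactors = FALSE)))
  map <- synteny_map(
    identity_synteny_map(names(chrom_lengths), chrom_lengths)$blocks, cent)
  homeo <- if (config$homeolog_mode)
    lapply(chroms, function(cn) cn) else NULL
  lineage <- lineage_config(.all_tip_species(config),
                            .divergence_matrix(config),
                            homeolog_groups = homeo, outgroup = "bdis")
  events <- if (length(env$events)) do.call(rbind, env$events) else
    data.frame(time = numeric(0), type = character(0), locus = integer(0),
               copy_uid = integer(0), parent_uid = integer(0),
               from_chrom = character(0), to_chrom = character(0),
               defect = character(0))
  structure(list(genes = genes, chromosomes = chrom_seqs, truth = truth,
                 events = events, map = map, lineage = lineage,
                 config = config),
            class = "clade_sim")
}

# Lay a tip's copies (plus TE decoys) out on chromosomes, build annotation,
# sequences and per-gene truth rows.
.emit_species <- function(sp, tip, chroms, config, env) {
  copies <- tip$copies
  mat <- tip$mat
  n_te <- round(config$te_decoy_fraction * nrow(copies))
  te <- if (n_te > 0) data.frame(
    uid = -(seq_len(n_te)), locus = NA_integer_,
    chrom = sample(length(chroms), n_te, replace = TRUE),
    rel_pos = stats::runif(n_te), birth_time = NA_real_,
    parent_uid = NA_integer_, defect = "none", event_type = "te_decoy",
    stringsAsFactors = FALSE) else NULL
  all_copies <- rbind(copies, te)
  is_te <- all_copies$event_type == "te_decoy"
  if (config$sequences) {
    te_mat <- if (n_te > 0) .random_cds_matrix(n_te, config$cds_length)
    else NULL
    mat <- rbind(mat, te_mat)
  }
  ord <- order(all_copies$chrom, all_copies$rel_pos, all_copies$uid)
  all_copies <- all_copies[ord, , drop = FALSE]
  if (config$sequences) mat <- mat[ord, , drop = FALSE]
  is_te <- is_te[ord]
  ng <- nrow(all_copies)
  gene_ids <- sprintf("%s_g%05d", sp, seq_len(ng))
  strand <- sample(c("+", "-"), ng, replace = TRUE)

  # effective CDS length after annotation-level defects
  L <- config$cds_length
  cds_bp <- rep(L, ng)
  trunc_sel <- all_copies$defect == "truncation"
  if (any(trunc_sel))
    cds_bp[trunc_sel] <- 3 * floor(stats::runif(sum(trunc_sel), 0.50, 0.65) *
                                     L / 3)
  fs_sel <- all_copies$defect == "frameshift"
  if (any(fs_sel))
    cds_bp[fs_sel] <- L - sample(1:2, sum(fs_sel), replace = TRUE)

  # exon structure per gene, in CDS-forward coordinates
  n_exons <- if (config$multi_exon) sample(2:4, ng, replace = TRUE)
  else rep(1L, ng)

  chrom_parts <- stats::setNames(vector("list", length(chroms)), chroms)
  chrom_pos <- stats::setNames(rep(0L, length(chroms)), chroms)
  g_start <- integer(ng)
  g_end <- integer(ng)
  tx_rows <- vector("list", ng)

  for (i in seq_len(ng)) {
    cn <- chroms[all_copies$chrom[i]]
    gap <- 100L + stats::rpois(1, config$intergenic_mean)
    if (config$sequences)
      chrom_parts[[cn]] <- c(chrom_parts[[cn]],
                             paste(sample(.BASE_CHARS, gap, replace = TRUE),
                                   collapse = ""))
    gstart <- chrom_pos[[cn]] + gap + 1L
    bp <- cds_bp[i]
    cds_fwd <- NA_character_
    if (config$sequences)
      cds_fwd <- paste(.BASE_CHARS[mat[i, seq_len(bp)] + 1L], collapse = "")
    # split CDS into exons with introns (forward orientation)
    nx <- n_exons[i]
    cuts <- if (nx > 1) sort(sample(seq_len(bp - 1), nx - 1)) else integer(0)
    ex_lens <- diff(c(0L, cuts, bp))
    intron_lens <- if (nx > 1) sample(60:200, nx - 1, replace = TRUE)
    else integer(0)
    block_len <- bp + sum(intron_lens)
    # forward-block coordinates of exons
    ex_start_f <- cumsum(c(1L, utils::head(ex_lens, -1) + intron_lens))
    ex_end_f <- ex_start_f + ex_lens - 1L
    if (config$sequences) {
      if (nx > 1) {
        pieces <- character(2 * nx - 1)
        p0 <- 1L
        for (x in seq_len(nx)) {
          pieces[2 * x - 1] <- substr(cds_fwd, p0, p0 + ex_lens[x] - 1L)
          p0 <- p0 + ex_lens[x]
          if (x < nx)
            pieces[2 * x] <- paste(sample(.BASE_CHARS, intron_lens[x],
                                          replace = TRUE), collapse = "")
        }
        block <- paste(pieces, collapse = "")
      } else block <- cds_fwd
      if (strand[i] == "-") block <- .revcomp_chr(block)
      chrom_parts[[cn]] <- c(chrom_parts[[cn]], block)
    }
    # genomic exon intervals
    if (strand[i] == "+") {
      ex_s <- gstart + ex_start_f - 1L
      ex_e <- gstart + ex_end_f - 1L
    } else {
      ex_s <- gstart + (block_len - ex_end_f)
      ex_e <- gstart + (block_len - ex_start_f)
    }
    gend <- gstart + block_len - 1L
    chrom_pos[[cn]] <- gend
    g_start[i] <- gstart
    g_end[i] <- gend
    exm <- cbind(as.integer(ex_s), as.integer(ex_e))
    exm <- exm[order(exm[, 1], decreasing = (strand[i] == "-")), ,
               drop = FALSE]
    dimnames(exm) <- NULL
    tx_rows[[i]] <- list(gene_id = gene_ids[i],
                         transcript_id = paste0(gene_ids[i], ".1"),
                         exons = exm, cds = exm,
                         cds_seq = cds_fwd,
                         protein = if (config$sequences)
                           translate_cds(cds_fwd) else NA_character_)
  }

  descriptions <- ifelse(is_te, "retrotransposon protein, putative",
                         sprintf("conserved hypothetical protein locus %s",
                                 ifelse(is.na(all_copies$locus), "decoy",
                                        all_copies$locus)))
  genes_df <- data.frame(
    gene_id = gene_ids, species = sp,
    chromosome = chroms[all_copies$chrom],
    start = as.integer(g_start), end = as.integer(g_end), strand = strand,
    is_te_related = is_te, description = descriptions,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    gene_id = gene_ids, species = sp,
    chromosome = chroms[all_copies$chrom],
    locus = all_copies$locus, copy_uid = all_copies$uid,
    parent_uid = all_copies$parent_uid,
    event_type = all_copies$event_type,
    birth_time = all_copies$birth_time,
    defect = all_copies$defect,
    anc_chrom = ifelse(is_te, NA_character_,
                       chroms[(all_copies$locus - 1L) %%
                                length(chroms) + 1L]),
    stringsAsFactors = FALSE)

  # ASV decoys: extra, shorter transcripts on a fraction of clean genes
  extra_tx <- list()
  asv_count <- stats::setNames(rep(0L, ng), gene_ids)
  cand <- which(!is_te & all_copies$defect == "none")
  n_asv <- round(config$asv_decoy_fraction * length(cand))
  if (n_asv > 0) {
    sel <- cand[sample.int(length(cand), n_asv)]
    for (i in sel) {
      k_extra <- sample(1:2, 1)
      asv_count[i] <- k_extra
      for (j in seq_len(k_extra)) {
        frac <- stats::runif(1, 0.4, 0.8)
        keep_bp <- max(6L, 3L * floor(frac * cds_bp[i] / 3))
        extra_tx[[length(extra_tx) + 1L]] <- .truncated_transcript(
          tx_rows[[i]], strand[i], keep_bp, j)
      }
    }
  }
  tx_all <- c(tx_rows, extra_tx)
  tx_df <- data.frame(
    gene_id = vapply(tx_all, `[[`, character(1), "gene_id"),
    transcript_id = vapply(tx_all, `[[`, character(1), "transcript_id"),
    stringsAsFactors = FALSE)
  tx_df$exons <- lapply(tx_all, `[[`, "exons")
  tx_df$cds <- lapply(tx_all, `[[`, "cds")
  tx_df$cds_seq <- vapply(tx_all, `[[`, character(1), "cds_seq")
  tx_df$protein <- vapply(tx_all, `[[`, character(1), "protein")

  chrom_lengths <- chrom_pos + 200L
  chrom_seqs <- NULL
  if (config$sequences) {
    seqs <- vapply(chroms, function(cn) paste(
      c(chrom_parts[[cn]],
        paste(sample(.BASE_CHARS, 200, replace = TRUE), collapse = "")),
      collapse = ""), character(1))
    chrom_seqs <- Biostrings::DNAStringSet(seqs)
    names(chrom_seqs) <- chroms
    chrom_lengths <- stats::setNames(Biostrings::width(chrom_seqs), chroms)
  }
  truth$n_asv <- asv_count[truth$gene_id]
  list(gene_set = gene_set(genes_df, tx_df, validate = FALSE),
       chromosomes = chrom_seqs,
       chrom_lengths = chrom_lengths,
       truth = truth)
}

# Build a shortened splice variant keeping the 5' keep_bp of the CDS.
.truncated_transcript <- function(tx, strand, keep_bp, idx) {
  exm <- tx$exons  # transcription order
  cds <- list()
  left <- keep_bp
  for (r in seq_len(nrow(exm))) {
    w <- exm[r, 2] - exm[r, 1] + 1L
    take <- min(w, left)
    if (take <= 0) break
    if (strand == "+") cds[[r]] <- c(exm[r, 1], exm[r, 1] + take - 1L)
    else cds[[r]] <- c(exm[r, 2] - take + 1L, exm[r, 2])
    left <- left - take
  }
  cdm <- do.call(rbind, cds)
  cds_seq <- if (!is.na(tx$cds_seq)) substr(tx$cds_seq, 1L, keep_bp)
  else NA_character_
  list(gene_id = tx$gene_id,
       transcript_id = sprintf("%s.%d", tx$gene_id, idx + 1L),
       exons = exm, cds = cdm, cds_seq = cds_seq,
       protein = if (!is.na(cds_seq)) translate_cds(cds_seq)
       else NA_character_)
}

# True class per emitted gene: apply the best-hit rule to the true copy
# genealogy. For each gene, the closest homolog in every other comparison
# species is the copy with the smallest divergence time (copy-tree MRCA,
# floored at the species split); the gene is syntenic if at least one
# closest homolog lies on the orthologous (same-named) chromosome.
.assign_true_classes <- function(truth, config, env) {
  div <- .divergence_matrix(config)
  comparison <- config$species
  parent <- env$copy_parent
  birth <- env$copy_birth
  chain <- function(uid) {
    uids <- integer(0)
    while (!is.na(uid)) {
      uids <- c(uids, uid)
      uid <- parent[[as.character(uid)]]
    }
    uids
  }
  # usable homolog targets: core-like genes (no defect, not TE)
  clean <- truth$event_type != "te_decoy" & truth$defect == "none"
  truth$true_class <- NA_character_
  truth$age_stratum <- NA_character_
  cand_split <- split(which(clean), paste(truth$species[clean],
                                          truth$locus[clean]))
  # loci never touched by an event have exactly their ancestral clean copy
  # in every species: syntenic by construction, no genealogy walk needed
  event_loci <- unique(truth$locus[truth$event_type %in%
                                     c("duplication", "translocation")])
  quiet <- truth$event_type == "ancestral" &
    !(truth$locus %in% event_loci) & truth$species %in% comparison
  truth$true_class[quiet] <- "syntenic"
  eligible <- which(truth$event_type != "te_decoy" &
                      truth$species %in% comparison & !quiet)
  chains <- lapply(stats::setNames(unique(truth$copy_uid[truth$event_type !=
                                                           "te_decoy"]),
                                   unique(truth$copy_uid[truth$event_type !=
                                                           "te_decoy"])),
                   chain)
  for (i in eligible) {
    u <- truth$copy_uid[i]
    ch_u <- chains[[as.character(u)]]
    sp_x <- truth$species[i]
    synt <- FALSE
    found_any <- FALSE
    for (sp_y in setdiff(comparison, sp_x)) {
      js <- cand_split[[paste(sp_y, truth$locus[i])]]
      if (is.null(js) || length(js) == 0L) next
      split_t <- div[sp_x, sp_y]
      best_d <- Inf
      best_chrom <- NA_character_
      best_uid <- Inf
      for (j in js) {
        v <- truth$copy_uid[j]
        ch_v <- chains[[as.character(v)]]
        w_pos <- match(ch_u, ch_v)
        ku <- which(!is.na(w_pos))[1]
        if (is.na(ku)) next  # disjoint chains (cannot happen within a locus)
        kv <- w_pos[ku]
        t_u <- if (ku == 1L) 0 else birth[[as.character(ch_u[ku - 1L])]]
        t_v <- if (kv == 1L) 0 else birth[[as.character(ch_v[kv - 1L])]]
        d <- max(t_u, t_v, split_t)
        if (d < best_d || (d == best_d && v < best_uid)) {
          best_d <- d
          best_chrom <- truth$chromosome[j]
          best_uid <- v
        }
      }
      if (!is.na(best_chrom)) {
        found_any <- TRUE
        if (best_chrom == truth$chromosome[i]) synt <- TRUE
      }
    }
    truth$true_class[i] <- if (!found_any) "unsupported"
    else if (synt) "syntenic" else "non-syntenic"
  }
  # sequence-presence rule: a gene whose locus has any copy (annotated or
  # not, pseudogenized or not) on the orthologous chromosome of another
  # compared species is syntenic by the operational definition - the
  # genomic reclassification search would find it
  all_copies <- truth[truth$event_type != "te_decoy", ,
                      drop = FALSE]
  key_any <- paste(all_copies$species, all_copies$locus,
                   all_copies$chromosome)
  ns <- which(!is.na(truth$true_class) & truth$true_class == "non-syntenic")
  for (i in ns) {
    others <- setdiff(comparison, truth$species[i])
    if (any(paste(others, truth$locus[i], truth$chromosome[i]) %in% key_any))
      truth$true_class[i] <- "syntenic"
  }
  # age stratum for focal non-syntenic genes (homeolog mode)
  if (config$homeolog_mode) {
    foc <- which(truth$species == config$focal &
                   !is.na(truth$true_class) &
                   truth$true_class == "non-syntenic")
    hs <- config$homeolog_splits[["homeolog"]]
    truth$age_stratum[foc] <- ifelse(
      !is.na(truth$birth_time[foc]) & truth$birth_time[foc] < hs,
      "recent", "old")
  }
  truth$moved <- !is.na(truth$anc_chrom) & truth$chromosome != truth$anc_chrom
  truth
}

#' @export
print.clade_sim <- function(x, ...) {
  cat("clade_sim:", length(x$genes), "species,",
      sum(vapply(x$genes, n_genes, integer(1))), "genes, seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Write a simulated clade to disk
#'
#' Emits, per species, `<species>.gff3`, `<species>.genome.fa`,
#' `<species>.cds.fa` and `<species>.prot.fa`, plus `truth.tsv`,
#' `events.tsv`, `synteny_blocks.tsv`, `centromeres.tsv` and a flat
#' `config.txt`.
#'
#' @param sim a `clade_sim` (simulated with sequences).
#' @param dir output directory (created if needed).
#' @export
write_clade <- function(sim, dir) {
  stopifnot(inherits(sim, "clade_sim"))
  if (is.null(sim$chromosomes))
    stop("clade was simulated without sequences; nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$genes)) {
    gs <- sim$genes[[sp]]
    write_gff3(gs, file.path(dir, paste0(sp, ".gff3")))
    Biostrings::writeXStringSet(sim$chromosomes[[sp]],
                                file.path(dir, paste0(sp, ".genome.fa")))
    cds <- Biostrings::DNAStringSet(stats::setNames(
      gs$transcripts$cds_seq, gs$transcripts$transcript_id))
    Biostrings::writeXStringSet(cds, file.path(dir, paste0(sp, ".cds.fa")))
    prot <- Biostrings::AAStringSet(stats::setNames(
      gs$transcripts$protein, gs$transcripts$transcript_id))
    Biostrings::writeXStringSet(prot, file.path(dir, paste0(sp, ".prot.fa")))
  }
  write_table(sim$truth, file.path(dir, "truth.tsv"))
  write_table(sim$events, file.path(dir, "events.tsv"))
  write_table(sim$map$blocks, file.path(dir, "synteny_blocks.tsv"))
  d <- sim$lineage$divergence
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  write_table(data.frame(species_a = rownames(d)[pairs[, 1]],
                         species_b = colnames(d)[pairs[, 2]],
                         my = d[pairs]),
              file.path(dir, "divergence.tsv"))
  if (!is.null(sim$map$centromeres))
    write_table(sim$map$centromeres, file.path(dir, "centromeres.tsv"))
  cfg <- sim$config
  scal <- vapply(cfg, function(v) length(v) == 1 && !is.list(v), logical(1))
  lines <- c(
    vapply(names(cfg)[scal], function(nm)
      paste0(nm, "=", format(cfg[[nm]])), character(1)),
    vapply(names(cfg)[!scal], function(nm)
      paste0(nm, "=", paste(format(cfg[[nm]]), collapse = ",")),
      character(1)))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Evolve a coding sequence for a given time
#'
#' Applies the simulator's codon substitution process (synonymous rate
#' `syn_rate_per_my` per site per MY, non-synonymous acceptance `omega`,
#' stop codons never created) to one CDS.
#'
#' @param cds nucleotide string (length a multiple of 3).
#' @param time_my branch length in MY.
#' @param omega target Ka/Ks.
#' @param syn_rate_per_my synonymous substitution rate per site per MY.
#' @param seed optional seed for a self-contained draw.
#' @return evolved CDS string.
#' @export
evolve_cds <- function(cds, time_my, omega = 0.3, syn_rate_per_my = 0.005,
                       seed = NULL) {
  cds <- toupper(cds)
  stopifnot(nchar(cds) %% 3 == 0, !grepl("[^ACGT]", cds))
  mat <- matrix(match(strsplit(cds, "")[[1]], .BASE_CHARS) - 1L, nrow = 1)
  run <- function() .evolve_matrix(mat, time_my, syn_rate_per_my, omega)
  out <- if (is.null(seed)) run() else .with_seed(seed, run())
  paste(.BASE_CHARS[out[1, ] + 1L], collapse = "")
}

#' Simulated per-gene expression table
#'
#' Stands in for an upstream expression-quantification step: per gene and
#' condition, an FPKM-like value. Expression probability, breadth and level
#' differ by true class according to the configuration, so class-wise
#' comparisons have a known direction (set the class parameters equal for a
#' null table).
#'
#' @param truth truth table from [simulate_clade()].
#' @param config the [simulation_config()].
#' @return data frame `gene_id`, `condition`, `fpkm` (full grid, zeros for
#'   silent gene/condition pairs).
#' @export
simulate_expression_table <- function(truth, config) {
  .with_seed(config$seed + 1000003L, {
    t <- truth[!is.na(truth$true_class) &
                 truth$true_class %in% c("syntenic", "non-syntenic"), ,
               drop = FALSE]
    cls <- ifelse(t$true_class == "syntenic", "syntenic", "nonsyntenic")
    nc <- config$n_conditions
    expressed <- stats::runif(nrow(t)) < config$expr_prob[cls]
    breadth <- ifelse(expressed,
                      1L + stats::rbinom(nrow(t), nc - 1L,
                                         config$expr_breadth[cls]), 0L)
    out <- data.frame(
      gene_id = rep(t$gene_id, each = nc),
      condition = rep(sprintf("cond%02d", seq_len(nc)), times = nrow(t)),
      fpkm = 0, stringsAsFactors = FALSE)
    lvl <- stats::rlnorm(nrow(t) * nc,
                         rep(config$fpkm_meanlog[cls], each = nc),
                         config$fpkm_sdlog)
    on_mask <- unlist(lapply(seq_len(nrow(t)), function(i) {
      m <- rep(FALSE, nc)
      if (breadth[i] > 0) m[sample.int(nc, breadth[i])] <- TRUE
      m
    }))
    out$fpkm[on_mask] <- lvl[on_mask]
    out
  })
}

#' Simulated functional annotation
#'
#' Assigns 0-4 random terms per gene; one designated term can be planted at
#' higher frequency in non-syntenic genes to create a known enrichment.
#'
#' @param truth truth table from [simulate_clade()].
#' @param n_terms vocabulary size.
#' @param enriched_term optional term id (e.g. `"T0001"`) to enrich.
#' @param enrich_prob probability that a non-syntenic gene carries the
#'   enriched term (background genes carry it at `base_prob`).
#' @param base_prob baseline probability per gene for the enriched term.
#' @param seed seed.
#' @return data frame `gene_id`, `term_id`, `term_name`.
#' @export
simulate_annotation <- function(truth, n_terms = 30, enriched_term = NULL,
                                enrich_prob = 0.3, base_prob = 0.05,
                                seed = 1) {
  .with_seed(seed, {
    t <- truth[!is.na(truth$true_class) &
                 truth$true_class %in% c("syntenic", "non-syntenic"), ,
               drop = FALSE]
    terms <- sprintf("T%04d", seq_len(n_terms))
    rows <- lapply(seq_len(nrow(t)), function(i) {
      k <- sample(0:4, 1)
      tt <- if (k > 0) sample(terms, k) else character(0)
      if (!is.null(enriched_term)) {
        p <- if (t$true_class[i] == "non-syntenic") enrich_prob else base_prob
        if (stats::runif(1) < p) tt <- union(tt, enriched_term)
        else tt <- setdiff(tt, enriched_term)
      }
      if (length(tt) == 0L) return(NULL)
      data.frame(gene_id = t$gene_id[i], term_id = tt,
                 term_name = paste("process", tt), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(out) <- NULL
    out
  })
}
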