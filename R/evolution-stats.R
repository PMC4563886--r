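# Fixation-rate statistics and cohort-level Ka/Ks comparisons.

#' Non-syntenic gene fixation rate
#'
#' `rate = n_nonsyntenic / n_total / divergence_my`, in events per locus per
#' million years: the number of non-syntenic genes fixed per core-set locus
#' since the divergence from the last common ancestor with the nearest
#' compared species.
#'
#' @param n_nonsyntenic number of non-syntenic core genes.
#' @param n_total total number of core genes.
#' @param divergence_my divergence time in million years (> 0).
#' @return object of class `fixation_rate` with fields `n_nonsyntenic`,
#'   `n_total`, `divergence_my`, `rate` and `percent_nonsyntenic`.
#' @examples
#' fixation_rate(1397, 5125, 39)
#' @export
fixation_rate <- function(n_nonsyntenic, n_total, divergence_my) {
  if (!is.numeric(divergence_my) || divergence_my <= 0)
    stop("divergence_my must be > 0")
  if (!is.numeric(n_total) || n_total == 0)
    stop("n_total must be a positive count")
  if (n_nonsyntenic < 0 || n_nonsyntenic > n_total)
    stop("n_nonsyntenic must lie in [0, n_total]")
  structure(list(n_nonsyntenic = n_nonsyntenic,
                 n_total = n_total,
                 divergence_my = divergence_my,
                 rate = n_nonsyntenic / n_total / divergence_my,
                 percent_nonsyntenic = 100 * n_nonsyntenic / n_total),
            class = "fixation_rate")
}

#' @export
print.fixation_rate <- function(x, ...) {
  cat(sprintf(
    "Fixation rate: %d / %d non-syntenic (%.1f%%) over %g MY = %s locus^-1 MY^-1\n",
    x$n_nonsyntenic, x$n_total, x$percent_nonsyntenic, x$divergence_my,
    format(signif(x$rate, 2), scientific = TRUE)))
  invisible(x)
}

#' Fixation-rate table and focal-lineage contrast
#'
#' Computes per-species fixation rates from a table of counts and divergence
#' times, plus the fold contrast between a focal species' rate and the mean
#' rate of the remaining species.
#'
#' @param counts data frame with columns `species`, `n_nonsyntenic`,
#'   `n_total`, `divergence_my`.
#' @param focal species name to contrast against the mean of the others;
#'   default the first row.
#' @return data frame with added `rate` and `percent_nonsyntenic` columns and
#'   attribute `fold_contrast`.
#' @export
fixation_rate_table <- function(counts, focal = counts$species[1]) {
  stopifnot(all(c("species", "n_nonsyntenic", "n_total", "divergence_my")
                %in% names(counts)))
  rates <- mapply(function(a, b, t) fixation_rate(a, b, t)$rate,
                  counts$n_nonsyntenic, counts$n_total, counts$divergence_my)
  counts$rate <- rates
  counts$percent_nonsyntenic <- 100 * counts$n_nonsyntenic / counts$n_total
  others <- counts$species != focal
  if (any(others))
    attr(counts, "fold_contrast") <- counts$rate[!others][1] /
      mean(counts$rate[others])
  counts
}

#' Cohort Ka/Ks: selection pressure of syntenic vs non-syntenic genes
#'
#' Pairs each classified gene with its best hit in a designated outgroup
#' species, aligns the proteins globally (BLOSUM62), back-translates to a
#' codon alignment and computes Nei-Gojobori Ka/Ks. Pairs with a frameshift
#' or internal stop codon are rejected; pairs with `Ks = 0` are excluded
#' from the ratio comparison. The two classes are compared with a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test on the Ka/Ks ratios.
#'
#' @param calls a `synteny_calls` data frame (columns `gene_id`, `class`).
#' @param genes [gene_set()] holding the query species' collapsed gene
#'   models (protein and CDS populated).
#' @param outgroup_genes [gene_set()] for the outgroup species.
#' @param best best-hit table from [best_hits()].
#' @param outgroup name of the outgroup species in `best$target_species`.
#' @param gap_opening,gap_extension protein alignment gap penalties.
#' @return object of class `kaks_cohort`: `results` per-pair data frame,
#'   `summary` per-class medians/means, `test` the `htest`, and exclusion
#'   counts.
#' @export
kaks_cohort <- function(calls, genes, outgroup_genes, best, outgroup,
                        gap_opening = 10, gap_extension = 0.5) {
  stopifnot(inherits(genes, "gene_set"), inherits(outgroup_genes, "gene_set"))
  b <- best[best$target_species == outgroup, , drop = FALSE]
  b <- b[b$query_id %in% calls$gene_id, , drop = FALSE]
  if (nrow(b) == 0L) stop("no best hits against outgroup '", outgroup, "'")
  tq <- genes$transcripts
  ts <- outgroup_genes$transcripts
  qi <- match(b$query_id, tq$gene_id)
  si <- match(b$subject_id, ts$gene_id)
  keep <- !is.na(qi) & !is.na(si)
  b <- b[keep, , drop = FALSE]
  qi <- qi[keep]
  si <- si[keep]
  res <- vector("list", nrow(b))
  n_reject <- 0L
  for (k in seq_len(nrow(b))) {
    cds_q <- tq$cds_seq[qi[k]]
    cds_s <- ts$cds_seq[si[k]]
    if (.has_coding_defect(cds_q) || .has_coding_defect(cds_s)) {
      n_reject <- n_reject + 1L
      next
    }
    pq <- .strip_stop(tq$protein[qi[k]])
    ps <- .strip_stop(ts$protein[si[k]])
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pq), Biostrings::AAString(ps),
      substitutionMatrix = "BLOSUM62", type = "global",
      gapOpening = gap_opening, gapExtension = gap_extension)
    kk <- nei_gojobori(back_translate(
      as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa)),
      cds_q, cds_s))
    res[[k]] <- data.frame(gene_id = b$query_id[k],
                           subject_id = b$subject_id[k],
                           class = calls$class[match(b$query_id[k],
                                                     calls$gene_id)],
                           S = kk$S, N = kk$N, Sd = kk$Sd, Nd = kk$Nd,
                           Ka = kk$Ka, Ks = kk$Ks, ratio = kk$ratio,
                           stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(results) || nrow(results) == 0L)
    stop("all pairs rejected (frameshift/stop) - no Ka/Ks computable")
  usable <- results[!is.na(results$ratio), , drop = FALSE]
  n_ks0 <- sum(!is.na(results$Ks) & results$Ks == 0)
  classes <- unique(usable$class)
  if (length(classes) < 2L)
    stop("need both syntenic and non-syntenic pairs with Ks > 0; got: ",
         paste(classes, collapse = ", "))
  smry <- do.call(rbind, lapply(split(usable$ratio, usable$class),
                                function(r) data.frame(
                                  n = length(r), median = stats::median(r),
                                  mean = mean(r))))
  smry <- cbind(class = rownames(smry), smry, row.names = NULL)
  test <- stats::wilcox.test(ratio ~ class, data = usable,
                             alternative = "two.sided", exact = FALSE)
  structure(list(results = results, summary = smry, test = test,
                 n_pairs = nrow(results), n_rejected = n_reject,
                 n_ks_zero = n_ks0),
            class = "kaks_cohort")
}

.has_coding_defect <- function(cds) {
  if (is.na(cds) || nchar(cds) < 6L) return(TRUE)
  if (nchar(cds) %% 3L != 0L) return(TRUE)          # frameshift
  codons <- .split_codons(toupper(cds))
  internal <- codons[-length(codons)]
  clean <- internal[!grepl("[^ACGT]", internal)]
  any(.is_stop(clean))
}

.strip_stop <- function(protein) sub("\\*$", "", protein)

#' @export
print.kaks_cohort <- function(x, ...) {
  cat("Ka/Ks cohort:", x$n_pairs, "pairs (", x$n_rejected,
      "rejected for frameshift/stop,", x$n_ks_zero, "with Ks = 0 excluded",
      ")\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("Mann-Whitney two-sided p = %.3g\n", x$test$p.value))
  invisible(x)
}
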