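# Term enrichment (one-sided hypergeometric / Fisher with BH-FDR) and
# class-wise comparisons of structural / expression features.

#' Term enrichment of a study set against a background
#'
#' Classic per-term Fisher test: for each term with at least one study gene,
#' the one-sided (upper tail) hypergeometric probability of observing at
#' least that many study genes annotated to the term, given the background
#' annotation; Benjamini-Hochberg adjustment across the tested terms.
#' Unannotated genes still count in the study/background totals.
#'
#' @param study character vector of study gene ids (subset of background).
#' @param background character vector of background gene ids.
#' @param annotation data frame `gene_id`, `term_id` and optionally
#'   `term_name`.
#' @return `enrichment` data frame sorted by p value: `term_id`,
#'   `term_name`, `annotated`, `significant`, `expected`, `p_value`,
#'   `adj_p`.
#' @export
enrich <- function(study, background, annotation) {
  study <- unique(study)
  background <- unique(background)
  if (length(study) == 0L) stop("empty study set")
  if (!all(study %in% background))
    stop("study set must be a subset of the background")
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann[, intersect(c("gene_id", "term_id", "term_name"),
                                names(ann))])
  if (!"term_name" %in% names(ann)) ann$term_name <- NA_character_
  N <- length(background)
  n <- length(study)
  in_study <- ann$gene_id %in% study
  annotated <- table(ann$term_id)
  significant <- table(ann$term_id[in_study])
  terms <- names(significant)  # one row per term with >= 1 study gene
  if (length(terms) == 0L) {
    warning("no study gene carries any annotation term")
    out <- data.frame(term_id = character(0), term_name = character(0),
                      annotated = integer(0), significant = integer(0),
                      expected = numeric(0), p_value = numeric(0),
                      adj_p = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("enrichment", "data.frame")
    return(out)
  }
  K <- as.integer(annotated[terms])
  k <- as.integer(significant[terms])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    term_id = terms,
    term_name = ann$term_name[match(terms, ann$term_id)],
    annotated = K, significant = k,
    expected = K * n / N,
    p_value = p,
    adj_p = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment", "data.frame")
  out
}

#' Compare per-gene features between synteny classes
#'
#' Per feature: class means and medians plus a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test for numeric features, or a 2x2 chi-squared test
#' (continuity correction off by default) for logical/binary features.
#' Features with fewer than 2 observations in a class are skipped.
#'
#' @param calls `synteny_calls` (columns `gene_id`, `class`).
#' @param features data frame with `gene_id` and one column per feature
#'   (numeric or logical).
#' @param correct continuity correction for the chi-squared test.
#' @return `feature_comparison` data frame: one row per feature with
#'   per-class summaries, the test used and its p value.
#' @export
compare_features <- function(calls, features, correct = FALSE) {
  stopifnot("gene_id" %in% names(features))
  m <- merge(calls[, c("gene_id", "class")], features, by = "gene_id")
  classes <- sort(unique(m$class))
  if (length(classes) < 2L)
    stop("need both classes present; got: ", paste(classes, collapse = ", "))
  feats <- setdiff(names(features), "gene_id")
  rows <- lapply(feats, function(f) {
    v <- m[[f]]
    ok <- !is.na(v)
    cl <- m$class[ok]
    v <- v[ok]
    if (min(table(cl)) < 2L) {
      message("feature '", f, "' skipped: a class has < 2 observations")
      return(NULL)
    }
    a <- v[cl == classes[1]]
    b <- v[cl == classes[2]]
    if (is.logical(v) || all(v %in% c(0, 1))) {
      tab <- rbind(c(sum(a), length(a) - sum(a)),
                   c(sum(b), length(b) - sum(b)))
      test <- "chi-squared"
      p <- suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
      stat_a <- mean(a)
      stat_b <- mean(b)
      med_a <- med_b <- NA_real_
    } else {
      test <- "mann-whitney"
      p <- stats::wilcox.test(a, b, alternative = "two.sided",
                              exact = FALSE)$p.value
      stat_a <- mean(a)
      stat_b <- mean(b)
      med_a <- stats::median(a)
      med_b <- stats::median(b)
    }
    out <- data.frame(feature = f, test = test, p_value = p,
                      stringsAsFactors = FALSE)
    out[[paste0("mean_", classes[1])]] <- stat_a
    out[[paste0("mean_", classes[2])]] <- stat_b
    out[[paste0("median_", classes[1])]] <- med_a
    out[[paste0("median_", classes[2])]] <- med_b
    out
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no comparable features")
  rownames(out) <- NULL
  class(out) <- c("feature_comparison", "data.frame")
  out
}

#' Per-gene feature table
#'
#' Assembles the structural and expression features compared between
#' classes: genomic size, CDS size, exon count, isoform count (from the
#' pre-collapse annotation), expressed flag, breadth (conditions expressed)
#' and mean level among expressed conditions.
#'
#' @param genes collapsed [gene_set()].
#' @param raw_genes optional pre-collapse [gene_set()] for isoform counts.
#' @param expression optional long table from
#'   [simulate_expression_table()] (or any `gene_id`/`condition`/`fpkm`).
#' @return data frame keyed by `gene_id`.
#' @export
gene_feature_table <- function(genes, raw_genes = NULL, expression = NULL) {
  g <- genes$genes
  t <- genes$transcripts[match(g$gene_id, genes$transcripts$gene_id), ]
  out <- data.frame(
    gene_id = g$gene_id,
    genomic_size = g$end - g$start + 1L,
    cds_size = t$cds_len,
    n_exons = vapply(t$exons, nrow, integer(1)),
    stringsAsFactors = FALSE)
  if (!is.null(raw_genes)) {
    iso <- table(raw_genes$transcripts$gene_id)
    out$n_isoforms <- as.integer(iso[out$gene_id])
    out$n_isoforms[is.na(out$n_isoforms)] <- 1L
  }
  if (!is.null(expression)) {
    e <- expression[expression$gene_id %in% out$gene_id, , drop = FALSE]
    on <- e$fpkm > 0
    breadth <- tapply(on, e$gene_id, sum)
    mean_on <- tapply(e$fpkm, e$gene_id, function(v)
      if (any(v > 0)) mean(v[v > 0]) else NA_real_)
    out$expressed <- FALSE
    idx <- match(out$gene_id, names(breadth))
    out$expressed[!is.na(idx)] <- breadth[idx[!is.na(idx)]] > 0
    out$n_conditions <- ifelse(out$expressed, as.numeric(breadth[idx]),
                               NA_real_)
    out$mean_fpkm <- ifelse(out$expressed, as.numeric(mean_on[idx]),
                            NA_real_)
  }
  out
}
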