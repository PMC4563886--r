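# Sliding-window chromosomal landscapes of non-syntenic gene proportion and
# their correlation with distance to the centromere.

#' Sliding-window proportion of non-syntenic genes
#'
#' Windows of `window` bp advance by `step` bp from position 1; a gene
#' belongs to a window when its midpoint lies in `[w_start, w_start +
#' window)`. The last window may be truncated at the chromosome end. Empty
#' windows are recorded with proportion `NA` (missing).
#'
#' @param positions gene midpoint positions (bp).
#' @param nonsyntenic logical vector (or a class vector where
#'   `"non-syntenic"` counts).
#' @param window,step window and step sizes in bp (`window >= step > 0`).
#' @param chrom_length chromosome length (bp).
#' @param centromere optional centromere position (bp); enables the
#'   correlation with centromere distance.
#' @param chromosome label stored in the profile.
#' @return `window_profile` data frame: `window_start`, `window_end`,
#'   `midpoint`, `n_genes`, `n_nonsyntenic`, `proportion`; attributes
#'   `window`, `step`, `centromere`, `chromosome`.
#' @export
sliding_proportion <- function(positions, nonsyntenic, window, step,
                               chrom_length, centromere = NULL,
                               chromosome = NA_character_) {
  stopifnot(window >= step, step > 0, chrom_length >= 1)
  if (is.character(nonsyntenic)) nonsyntenic <- nonsyntenic == "non-syntenic"
  stopifnot(length(positions) == length(nonsyntenic))
  if (any(positions < 1 | positions > chrom_length))
    stop("gene positions outside [1, chrom_length]")
  starts <- seq(1, chrom_length, by = step)
  nw <- length(starts)
  # windows covering position p: indices i with starts[i] <= p < starts[i]+window
  lo <- pmax(1L, as.integer(ceiling((positions - window) / step)) + 1L)
  hi <- pmin(nw, as.integer(floor((positions - 1) / step)) + 1L)
  n_genes <- integer(nw)
  n_ns <- integer(nw)
  for (g in seq_along(positions)) {
    if (hi[g] < lo[g]) next
    ix <- lo[g]:hi[g]
    n_genes[ix] <- n_genes[ix] + 1L
    if (nonsyntenic[g]) n_ns[ix] <- n_ns[ix] + 1L
  }
  ends <- pmin(starts + window - 1, chrom_length)
  out <- data.frame(window_start = starts, window_end = ends,
                    midpoint = (starts + ends) / 2,
                    n_genes = n_genes, n_nonsyntenic = n_ns,
                    proportion = ifelse(n_genes > 0, n_ns / n_genes,
                                        NA_real_))
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "centromere") <- centromere
  attr(out, "chromosome") <- chromosome
  class(out) <- c("window_profile", "data.frame")
  out
}

#' Pearson correlation of window proportion with centromere distance
#'
#' Correlates each non-missing window's proportion with the absolute
#' distance of its midpoint from the centromere.
#'
#' @param profile a [sliding_proportion()] profile.
#' @param centromere centromere position (bp); defaults to the profile's
#'   attribute.
#' @return Pearson r (`NA` with a warning when undefined: fewer than 3
#'   usable windows, or zero variance).
#' @export
centromere_distance_correlation <- function(profile, centromere = NULL) {
  if (is.null(centromere)) centromere <- attr(profile, "centromere")
  if (is.null(centromere)) stop("no centromere position available")
  ok <- !is.na(profile$proportion)
  if (sum(ok) < 3) {
    warning("fewer than 3 non-missing windows; correlation undefined")
    return(NA_real_)
  }
  d <- abs(profile$midpoint[ok] - centromere)
  p <- profile$proportion[ok]
  if (stats::sd(p) == 0 || stats::sd(d) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(d, p)
}

#' Age-stratified window profiles
#'
#' Separate recent / old landscapes of non-syntenic genes, counting one
#' random representative per duplicate family (to avoid intrachromosomal
#' duplicate clusters biasing the distribution) against all genes in the
#' denominator.
#'
#' @param calls `synteny_calls` with `age_stratum` filled (see
#'   [stratify_age()]), restricted to one chromosome.
#' @param families output of [build_duplicate_families()].
#' @param window,step,chrom_length,centromere as in [sliding_proportion()].
#' @return list of two `window_profile`s: `recent`, `old`.
#' @export
age_stratified_profiles <- function(calls, families, window, step,
                                    chrom_length, centromere = NULL) {
  rep_ids <- families$gene_id[families$representative]
  keep <- calls$class != "non-syntenic" | calls$gene_id %in% rep_ids
  cc <- calls[keep, , drop = FALSE]
  mk <- function(stratum) {
    flag <- cc$class == "non-syntenic" & !is.na(cc$age_stratum) &
      cc$age_stratum == stratum
    sliding_proportion(cc$position, flag, window, step, chrom_length,
                       centromere, chromosome = cc$chromosome[1])
  }
  list(recent = mk("recent"), old = mk("old"))
}

#' @export
plot.window_profile <- function(x, ..., smooth = TRUE) {
  ok <- !is.na(x$proportion)
  graphics::plot(x$midpoint[ok] / 1e6, x$proportion[ok], type = "l",
                 col = "grey40",
                 xlab = "Position (Mb)", ylab = "Proportion non-syntenic",
                 main = attr(x, "chromosome"), ...)
  if (smooth && sum(ok) > 10) {
    lo <- stats::loess(proportion ~ midpoint, data = x[ok, ])
    graphics::lines(x$midpoint[ok] / 1e6, stats::predict(lo), col = "red3",
                    lwd = 2)
  }
  cent <- attr(x, "centromere")
  if (!is.null(cent))
    graphics::abline(v = cent / 1e6, lty = 2, col = "grey60")
  invisible(x)
}
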