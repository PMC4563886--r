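# Nei-Gojobori (1986) synonymous / non-synonymous machinery on codon
# alignments, with Jukes-Cantor multiple-hit correction.

.syn_cache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings GENETIC_CODE
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
}

.sense_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc != "*"]
}

.is_stop <- function(codon) {
  gc <- .genetic_code()
  !is.na(match(codon, names(gc))) & gc[codon] == "*"
}

#' Synonymous and non-synonymous site counts of a codon
#'
#' Counts synonymous (s) and non-synonymous (n) sites of a single codon under
#' the Nei-Gojobori method with the standard genetic code. Each codon position
#' contributes one site, split as the fraction of its possible single-base
#' changes that are synonymous; changes creating a stop codon are excluded
#' from the denominator (the convention used by codeml's NG implementation),
#' so `s + n = 3` for every sense codon.
#'
#' @param codon a string of 3 unambiguous bases (ACGT), not a stop codon.
#' @return named numeric vector `c(s = ..., n = ...)`.
#' @examples
#' count_sites("TTT")  # c(s = 1/3, n = 8/3)
#' count_sites("GGG")  # c(s = 1,   n = 2)
#' @export
count_sites <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("codon must be 3 unambiguous bases (ACGT): ", codon)
  gc <- .genetic_code()
  if (gc[[codon]] == "*")
    stop("stop codon has no defined site counts: ", codon)
  aa0 <- gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    base0 <- substr(codon, pos, pos)
    syn <- 0L
    valid <- 0L
    for (b in setdiff(.BASES, base0)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      aa1 <- gc[[mut]]
      if (aa1 == "*") next
      valid <- valid + 1L
      if (aa1 == aa0) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(s = s, n = 3 - s)
}

#' Pathway-averaged substitution differences between two codons
#'
#' Average numbers of synonymous (`sd`) and non-synonymous (`nd`)
#' substitutions over all minimal mutational pathways between two sense
#' codons, each pathway weighted equally. Pathways passing through a stop
#' codon are excluded; if every pathway does, all pathways are used instead
#' (with a warning) so that `sd + nd` always equals the number of differing
#' positions.
#'
#' @param codon_a,codon_b strings of 3 unambiguous bases, neither a stop.
#' @return named numeric vector `c(sd = ..., nd = ...)`.
#' @export
count_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  for (cd in c(codon_a, codon_b)) {
    if (nchar(cd) != 3L || grepl("[^ACGT]", cd))
      stop("codon must be 3 unambiguous bases (ACGT): ", cd)
    if (.genetic_code()[[cd]] == "*")
      stop("stop codons are not comparable: ", cd)
  }
  diffs <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  if (length(diffs) == 0L) return(c(sd = 0, nd = 0))
  gc <- .genetic_code()
  paths <- .permutations(diffs)
  walk <- function(order, allow_stop) {
    cur <- codon_a
    sd <- 0
    nd <- 0
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      aa_cur <- gc[[cur]]
      aa_nxt <- gc[[nxt]]
      if (aa_nxt == "*" && !allow_stop) return(NULL)
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(paths, walk, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    warning("all pathways between ", codon_a, " and ", codon_b,
            " pass through a stop codon; including them")
    res <- lapply(paths, walk, allow_stop = TRUE)
  }
  m <- colMeans(do.call(rbind, res))
  c(sd = m[1], nd = m[2])
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (tail in .permutations(x[-i]))
      out <- c(out, list(c(x[i], tail)))
  out
}

# Memoised lookup tables over the 61 sense codons: per-codon (s, n) and
# 61 x 61 pathway-averaged (sd, nd). Built once per session.
.ng_tables <- function() {
  if (!is.null(.syn_cache$tables)) return(.syn_cache$tables)
  codons <- .sense_codons()
  sites <- t(vapply(codons, count_sites, numeric(2)))
  n <- length(codons)
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- sd
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (i == j) next
      d <- suppressWarnings(count_differences(codons[i], codons[j]))
      sd[i, j] <- sd[j, i] <- d[["sd"]]
      nd[i, j] <- nd[j, i] <- d[["nd"]]
    }
  }
  .syn_cache$tables <- list(codons = codons, sites = sites, sd = sd, nd = nd)
  .syn_cache$tables
}

#' Jukes-Cantor correction of a proportion of differences
#'
#' `d = -(3/4) log(1 - (4/3) p)`. Returns `NA` (with attribute
#' `saturated = TRUE`) when `p >= 0.75`, where the correction is undefined.
#'
#' @param p observed proportion of differences per site.
#' @return corrected distance, or `NA` when saturated.
#' @export
jukes_cantor <- function(p) {
  stopifnot(is.numeric(p), p >= 0)
  out <- ifelse(p < 0.75, -0.75 * log(1 - (4 / 3) * p), NA_real_)
  if (anyNA(out)) attr(out, "saturated") <- TRUE
  out
}

#' Codon alignment of two coding sequences
#'
#' Container for a pair of gap-aligned CDS strings whose gaps come in whole
#' codons. Validated so that removing gaps recovers the input sequences and
#' no codon column mixes gap and base.
#'
#' @param a,b aligned nucleotide strings of equal length (multiples of 3),
#'   gaps as `-`.
#' @return object of class `codon_alignment`.
#' @export
codon_alignment <- function(a, b) {
  a <- toupper(a)
  b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("aligned length not a multiple of 3")
  ca <- .split_codons(a)
  cb <- .split_codons(b)
  mixed <- function(x) grepl("-", x) & x != "---"
  if (any(mixed(ca)) || any(mixed(cb)))
    stop("codon column mixes gap and base")
  structure(list(a = a, b = b, codons_a = ca, codons_b = cb),
            class = "codon_alignment")
}

.split_codons <- function(x) {
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$codons_a), "codon columns\n")
  invisible(x)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Expands each aligned amino-acid column to its source codon (or a 3-base
#' gap), after verifying that each CDS translates to its ungapped protein.
#' A trailing stop codon on either CDS is tolerated and dropped.
#'
#' @param protein_a,protein_b gap-aligned amino-acid strings of equal length.
#' @param cds_a,cds_b ungapped coding sequences for the two proteins.
#' @return a [codon_alignment()].
#' @export
back_translate <- function(protein_a, protein_b, cds_a, cds_b) {
  if (nchar(protein_a) != nchar(protein_b))
    stop("protein alignment rows differ in length")
  expand <- function(prot_aln, cds, label) {
    cds <- toupper(cds)
    if (nchar(cds) %% 3L != 0L)
      stop(label, ": CDS length not a multiple of 3 (frameshift?)")
    codons <- .split_codons(cds)
    # drop one trailing stop codon if present
    if (length(codons) > 0L && .is_stop(codons[length(codons)]))
      codons <- codons[-length(codons)]
    res <- strsplit(prot_aln, "")[[1]]
    ungapped <- res[res != "-"]
    if (length(ungapped) != length(codons))
      stop(label, ": protein has ", length(ungapped),
           " residues but CDS has ", length(codons), " codons")
    gc <- .genetic_code()
    k <- 0L
    out <- character(length(res))
    for (i in seq_along(res)) {
      if (res[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        tr <- if (grepl("[^ACGT]", codons[k])) "X" else gc[[codons[k]]]
        if (!identical(tr, res[i]) && res[i] != "X")
          stop(label, ": residue ", res[i], " at alignment position ", i,
               " does not match codon ", codons[k], " (translates to ",
               tr, ")")
        out[i] <- codons[k]
      }
    }
    paste(out, collapse = "")
  }
  codon_alignment(expand(protein_a, cds_a, "sequence a"),
                  expand(protein_b, cds_b, "sequence b"))
}

#' Nei-Gojobori Ka/Ks of a codon alignment
#'
#' Implements the Nei-Gojobori (1986) method: fractional synonymous (S) and
#' non-synonymous (N) site counts averaged over the two sequences,
#' pathway-averaged difference counts (Sd, Nd) over comparable codon columns,
#' proportions `ps = Sd/S` and `pd = Nd/N`, and Jukes-Cantor corrected rates
#' Ks and Ka. Codon columns containing gaps, ambiguous bases, or a stop codon
#' in either sequence are skipped. The Ka/Ks ratio is reported only when
#' `Ks > 0`; a proportion at or beyond 0.75 leaves the corresponding rate
#' undefined (saturated).
#'
#' @param aln a [codon_alignment()], or an aligned CDS string when `b` given.
#' @param b optional second aligned CDS string.
#' @return object of class `kaks` with fields `S`, `N`, `Sd`, `Nd`, `ps`,
#'   `pd`, `Ka`, `Ks`, `ratio`, `n_codons` (comparable columns) and
#'   `n_skipped`.
#' @export
nei_gojobori <- function(aln, b = NULL) {
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln, b)
  tab <- .ng_tables()
  ca <- aln$codons_a
  cb <- aln$codons_b
  ok <- ca %in% tab$codons & cb %in% tab$codons
  if (!any(ok))
    stop("no comparable codon columns (gap/stop/ambiguity-free) in alignment")
  ca <- ca[ok]
  cb <- cb[ok]
  S <- (sum(tab$sites[ca, "s"]) + sum(tab$sites[cb, "s"])) / 2
  N <- (sum(tab$sites[ca, "n"]) + sum(tab$sites[cb, "n"])) / 2
  idx <- cbind(match(ca, tab$codons), match(cb, tab$codons))
  Sd <- sum(tab$sd[idx])
  Nd <- sum(tab$nd[idx])
  ps <- if (S > 0) Sd / S else NA_real_
  pd <- if (N > 0) Nd / N else NA_real_
  Ks <- if (is.na(ps)) NA_real_ else as.numeric(jukes_cantor(ps))
  Ka <- if (is.na(pd)) NA_real_ else as.numeric(jukes_cantor(pd))
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pd = pd,
                 Ka = Ka, Ks = Ks, ratio = ratio,
                 n_codons = sum(ok), n_skipped = sum(!ok),
                 saturated_s = !is.na(ps) && ps >= 0.75,
                 saturated_n = !is.na(pd) && pd >= 0.75),
            class = "kaks")
}

#' @export
print.kaks <- function(x, ...) {
  cat("Nei-Gojobori Ka/Ks over", x$n_codons, "codon columns",
      if (x$n_skipped > 0) sprintf("(%d skipped)", x$n_skipped) else "", "\n")
  cat(sprintf("  S = %.2f  N = %.2f  Sd = %.2f  Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  Ks = %s  Ka = %s  Ka/Ks = %s\n",
              format(x$Ks, digits = 4), format(x$Ka, digits = 4),
              if (is.na(x$ratio)) {
                if (!is.na(x$Ks) && x$Ks == 0) "excluded (Ks = 0)" else "NA"
              } else format(x$ratio, digits = 4)))
  if (isTRUE(x$saturated_s) || isTRUE(x$saturated_n))
    cat("  warning: proportion >= 0.75, Jukes-Cantor correction saturated\n")
  invisible(x)
}
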