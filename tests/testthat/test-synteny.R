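# Synteny classification, reclassification, duplicate origin, age strata,
# duplicate families.

toy_map <- function() identity_synteny_map(c("spA", "spB", "spC", "spD"),
                                           c(chr1 = 1e6, chr2 = 1e6,
                                             chr3 = 1e6))

toy_gene <- function(id = "g1", chrom = "chr1") {
  mk_gene_set(list(gene_id = id, chromosome = chrom, start = 1000,
                   end = 1899,
                   transcripts = list(list(id = paste0(id, ".1"),
                                           cds_seq = random_cds(100,
                                                                seed = 1)))),
              species = "spA")
}

test_that("classification rule verified over the full 3-species pattern space", {
  m <- toy_map()
  gs <- toy_gene()
  for (pat in 0:7) {
    on_synt <- as.logical(bitwAnd(pat, c(1, 2, 4)))
    best <- do.call(rbind, Map(function(sp, syn)
      mk_hit("g1", paste0(sp, "_gene"), subject_species = sp,
             subject_chromosome = if (syn) "chr1" else "chr2",
             subject_pos = 5e5),
      c("spB", "spC", "spD"), on_synt))
    best$target_species <- best$subject_species
    call <- classify_genes(gs, best, m)
    oracle <- if (any(on_synt)) "syntenic" else "non-syntenic"
    expect_equal(call$class, oracle, info = paste("pattern", pat))
  }
})

test_that("best hits on unmapped chromosomes count as non-syntenic evidence", {
  m <- toy_map()
  gs <- toy_gene()
  best <- mk_hit("g1", "b1", subject_species = "spB",
                 subject_chromosome = "chrUn", subject_pos = 100)
  best$target_species <- "spB"
  call <- classify_genes(gs, best, m)
  expect_equal(call$class, "non-syntenic")
  expect_match(call$evidence, "chrUn=other")
})

test_that("genomic search reclassifies genes present but unannotated", {
  m <- identity_synteny_map(c("spA", "spB"), c(chr1 = 1e6, chr2 = 1e6))
  set.seed(5)
  cds <- random_cds(150)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  gs <- mk_gene_set(list(gene_id = "g1", chromosome = "chr1", start = 1000,
                         end = 1000 + nchar(cds) - 1,
                         transcripts = list(list(id = "g1.1",
                                                 cds_seq = cds))),
                    species = "spA")
  # spB's chr1 carries the (unannotated, reverse-strand) ortholog
  chrB1 <- Biostrings::DNAStringSet(c(
    chr1 = paste0(flank(5000),
                  chartr("ACGT", "TGCA",
                         paste(rev(strsplit(cds, "")[[1]]), collapse = "")),
                  flank(5000)),
    chr2 = flank(8000)))
  calls <- data.frame(gene_id = "g1", species = "spA", chromosome = "chr1",
                      position = 1200, class = "non-syntenic",
                      reclassified = FALSE, origin = NA_character_,
                      age_stratum = NA_character_, evidence = "",
                      stringsAsFactors = FALSE)
  out <- reclassify_by_genomic_search(calls, gs, list(spB = chrB1), m)
  expect_equal(out$class, "syntenic")
  expect_true(out$reclassified)
  # scrambled query: no hit anywhere, stays non-syntenic
  gs2 <- mk_gene_set(list(gene_id = "g1", chromosome = "chr1", start = 1000,
                          end = 1000 + nchar(cds) - 1,
                          transcripts = list(list(
                            id = "g1.1", cds_seq = random_cds(150,
                                                              seed = 999)))),
                     species = "spA")
  out2 <- reclassify_by_genomic_search(calls, gs2, list(spB = chrB1), m)
  expect_equal(out2$class, "non-syntenic")
  expect_false(out2$reclassified)
  # missing pseudomolecule leaves the call unchanged with a warning
  expect_warning(
    out3 <- reclassify_by_genomic_search(calls, gs, list(spB = chrB1["chr2"]),
                                         m),
    "missing pseudomolecule")
  expect_equal(out3$class, "non-syntenic")
})

test_that("duplicate origin follows surviving copies on other chromosomes", {
  cfg <- simulation_config(n_ancestral_genes = 120, cds_length = 300,
                           duplication_rate = c(taes = 0.02, bdis = 0,
                                                osat = 0, sbic = 0),
                           p_duplication = 1, pseudogenization_prob = 0,
                           te_decoy_fraction = 0, asv_decoy_fraction = 0,
                           seed = 41)
  sim <- suppressWarnings(simulate_clade(cfg))
  tr <- sim$truth[sim$truth$species == "taes", ]
  ns_ids <- tr$gene_id[tr$true_class == "non-syntenic"]
  calls <- data.frame(gene_id = ns_ids, species = "taes",
                      chromosome = tr$chromosome[match(ns_ids, tr$gene_id)],
                      position = 1, class = "non-syntenic",
                      reclassified = FALSE, origin = NA_character_,
                      age_stratum = NA_character_, evidence = "",
                      stringsAsFactors = FALSE)
  out <- detect_duplicate_origin(calls, collapse_isoforms(sim$genes$taes),
                                 sim$chromosomes$taes)
  # every event retained its ancestral copy, so every non-syntenic gene has
  # a surviving copy elsewhere
  expect_true(all(out$origin == "duplication"))

  # pure translocation: ancestral copies removed, nothing to find
  cfg2 <- cfg
  cfg2$p_duplication <- 0
  sim2 <- suppressWarnings(simulate_clade(cfg2))
  tr2 <- sim2$truth[sim2$truth$species == "taes", ]
  ns2 <- tr2$gene_id[tr2$true_class == "non-syntenic"]
  calls2 <- data.frame(gene_id = ns2, species = "taes",
                       chromosome = tr2$chromosome[match(ns2, tr2$gene_id)],
                       position = 1, class = "non-syntenic",
                       reclassified = FALSE, origin = NA_character_,
                       age_stratum = NA_character_, evidence = "",
                       stringsAsFactors = FALSE)
  out2 <- detect_duplicate_origin(calls2, collapse_isoforms(sim2$genes$taes),
                                  sim2$chromosomes$taes)
  expect_true(all(out2$origin == "unresolved"))
})

test_that("age stratification against close relatives matches truth", {
  cfg <- simulation_config(n_ancestral_genes = 150, cds_length = 300,
                           duplication_rate = c(taes = 0.02, bdis = 2e-3,
                                                osat = 1.7e-3, sbic = 2.3e-3),
                           pseudogenization_prob = 0, te_decoy_fraction = 0,
                           asv_decoy_fraction = 0, homeolog_mode = TRUE,
                           seed = 23)
  sim <- suppressWarnings(simulate_clade(cfg))
  scan <- suppressWarnings(suppressMessages(
    synteny_scan(sim, params = scan_params(window = 5e4, step = 5e3))))
  calls <- scan$calls[scan$calls$species == "taes", ]
  strat <- stratify_age(calls, scan$core$taes, scan$hits,
                        c("relA", "relD", "sister"), sim$map)
  ns <- strat[strat$class == "non-syntenic", ]
  tr <- sim$truth
  truth_stratum <- tr$age_stratum[match(ns$gene_id, tr$gene_id)]
  comparable <- !is.na(truth_stratum)
  expect_gt(sum(comparable), 5)
  expect_gte(mean(ns$age_stratum[comparable] == truth_stratum[comparable]),
             0.95)
})

test_that("duplicate families are single-linkage with seeded representatives", {
  cds <- random_cds(100, seed = 3)
  mk <- function(id) list(gene_id = id, chromosome = "chr1",
                          start = 1, end = 300,
                          transcripts = list(list(id = paste0(id, ".1"),
                                                  cds_seq = cds)))
  gs <- mk_gene_set(mk("a"), mk("b"), mk("c"), mk("lone"), species = "spA")
  gs$genes$start <- c(1, 1000, 2000, 5000)
  gs$genes$end <- gs$genes$start + 299
  hits <- rbind(
    mk_hit("a", "b", subject_species = "spA"),
    mk_hit("b", "c", subject_species = "spA"))
  g <- gs$genes
  hits$subject_chromosome <- "chr1"
  fam <- build_duplicate_families(gs, hits, seed = 9)
  fid <- stats::setNames(fam$family_id, fam$gene_id)
  expect_equal(fid[["a"]], fid[["b"]])
  expect_equal(fid[["b"]], fid[["c"]])
  expect_false(fid[["lone"]] == fid[["a"]])
  # one representative per family; singletons represent themselves
  expect_equal(sum(fam$representative[fam$gene_id %in% c("a", "b", "c")]), 1L)
  expect_true(fam$representative[fam$gene_id == "lone"])
  # determinism under the same seed
  fam2 <- build_duplicate_families(gs, hits, seed = 9)
  expect_identical(fam, fam2)
})
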