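# The four sequential filters and their report.

test_that("isoform collapse keeps the longest CDS with documented ties", {
  gs <- mk_gene_set(
    list(gene_id = "g1", start = 1, end = 5000, transcripts = list(
      list(id = "g1.a", exons = cbind(1, 3000), cds = cbind(1, 900)),
      list(id = "g1.b", exons = cbind(1, 4000), cds = cbind(1, 1200)),
      list(id = "g1.c", exons = cbind(1, 2000), cds = cbind(1, 600)))),
    # tie on CDS length: longer genomic span wins
    list(gene_id = "g2", start = 1, end = 5000, transcripts = list(
      list(id = "g2.a", exons = cbind(1, 2000), cds = cbind(1, 900)),
      list(id = "g2.b", exons = cbind(1, 2500), cds = cbind(101, 1000)))),
    # tie on both: lexicographically smaller transcript id
    list(gene_id = "g3", start = 1, end = 5000, transcripts = list(
      list(id = "g3.b", exons = cbind(1, 2000), cds = cbind(1, 300)),
      list(id = "g3.a", exons = cbind(1, 2000), cds = cbind(1, 300)))),
    # single transcript unchanged
    list(gene_id = "g4", start = 1, end = 100,
         transcripts = list(list(id = "g4.only"))))
  col <- collapse_isoforms(gs)
  keep <- stats::setNames(col$transcripts$transcript_id,
                          col$transcripts$gene_id)
  expect_equal(unname(keep[c("g1", "g2", "g3", "g4")]),
               c("g1.b", "g2.b", "g3.a", "g4.only"))
  expect_equal(n_genes(col), 4L)
})

test_that("TE removal uses flags and description substrings", {
  gs <- mk_gene_set(
    list(gene_id = "g1", start = 1, end = 10,
         description = "retrotransposon protein, putative",
         transcripts = list(list(id = "t1"))),
    list(gene_id = "g2", start = 1, end = 10, te = TRUE,
         transcripts = list(list(id = "t2"))),
    list(gene_id = "g3", start = 1, end = 10, description = "kinase",
         transcripts = list(list(id = "t3"))))
  out <- remove_te_genes(gs)
  expect_equal(out$genes$gene_id, "g3")
  expect_setequal(attr(out, "removed"), c("g1", "g2"))
})

test_that("homology support applies all three thresholds jointly", {
  cds <- strrep("ATG", 100)   # 100-aa protein
  gs <- mk_gene_set(
    list(gene_id = "q1", start = 1, end = 300,
         transcripts = list(list(id = "q1.1", cds_seq = cds))),
    list(gene_id = "q2", start = 1, end = 300,
         transcripts = list(list(id = "q2.1", cds_seq = cds))),
    list(gene_id = "q3", start = 1, end = 300,
         transcripts = list(list(id = "q3.1", cds_seq = cds))),
    list(gene_id = "q4", start = 1, end = 300,
         transcripts = list(list(id = "q4.1", cds_seq = cds))))
  hits <- rbind(
    # identity below 35: removed even with strong overlap
    mk_hit("q1", "s1", pct_identity = 34.9, q_start = 1, q_end = 80),
    # qualifies: 40% identity, 36% overlap, e-value 1e-6
    mk_hit("q2", "s1", pct_identity = 40, q_start = 1, q_end = 36,
           evalue = 1e-6),
    # hit in the same species only: removed
    mk_hit("q3", "s2", pct_identity = 90, q_start = 1, q_end = 90,
           subject_species = "spA"))
  out <- homology_support_filter(gs, hits, other_species = "spB")
  expect_equal(out$genes$gene_id, "q2")
  expect_setequal(attr(out, "removed"), c("q1", "q3", "q4"))
  sup <- attr(out, "support")
  expect_equal(sup$supported[sup$gene_id == "q2"], TRUE)
  # boundary: exactly 35/35 qualifies (Methods wording, >= not >)
  hits2 <- mk_hit("q1", "s1", pct_identity = 35, q_start = 1, q_end = 35)
  out2 <- homology_support_filter(gs, hits2, other_species = "spB")
  expect_true("q1" %in% out2$genes$gene_id)
})

test_that("pseudogene detection covers all three rules", {
  # internal stop at codon 2
  r <- detect_pseudogene(paste0("ATGTAA", strrep("GGG", 50), "TAA"))
  expect_true(r$pseudogene)
  expect_equal(r$reason, "internal_stop")
  # frameshift: length not a multiple of 3
  r2 <- detect_pseudogene(paste0(strrep("ATG", 20), "AC"))
  expect_true(r2$pseudogene)
  expect_equal(r2$reason, "frameshift")
  # truncation below 70% of the homolog: 199 aa protein
  cds200 <- random_cds(200, seed = 1)
  r3 <- detect_pseudogene(cds200, homolog_len = 250)
  expect_false(r3$pseudogene)   # 199 >= 0.7 * 250
  r4 <- detect_pseudogene(cds200, homolog_len = 300)
  expect_true(r4$pseudogene)    # 199 < 0.7 * 300
  expect_equal(r4$reason, "truncation")
  # 950 vs 1000: kept
  r5 <- detect_pseudogene(random_cds(951, seed = 2), homolog_len = 1000)
  expect_false(r5$pseudogene)
  expect_error(detect_pseudogene(NA), "CDS")
})

test_that("full filtration matches truth-predicted counts on simulations", {
  cfg <- simulation_config(n_ancestral_genes = 150, cds_length = 300,
                           duplication_rate = c(taes = 0.015, bdis = 2e-3,
                                                osat = 1.7e-3, sbic = 2.3e-3),
                           pseudogenization_prob = 0.3, seed = 77)
  sim <- simulate_clade(cfg)
  scan <- suppressWarnings(suppressMessages(
    synteny_scan(sim, params = scan_params(window = 5e4, step = 5e3),
                 reclassify = FALSE)))
  tr <- sim$truth
  for (sp in names(scan$reports)) {
    counts <- scan$reports[[sp]]$counts
    trs <- tr[tr$species == sp, ]
    # monotone non-increasing stage counts
    expect_true(all(diff(counts) <= 0), label = sp)
    # TE stage removes exactly the TE decoys
    expect_equal(unname(counts["raw"] - counts["no_asv_te"]),
                 sum(trs$event_type == "te_decoy"), label = sp)
    # pseudogene stage removes exactly the defect copies not already gone.
    # Truncated copies whose event is shared by several lineages are
    # excluded: their only surviving homologs are equally truncated, so the
    # 70%-of-best-hit rule is undetermined for them by construction.
    reasons <- scan$reports[[sp]]$reasons
    pg <- reasons$gene_id[grepl("^pseudogene", reasons$reason)]
    removed_earlier <- reasons$gene_id[!grepl("^pseudogene", reasons$reason)]
    expected_pg <- trs$gene_id[trs$defect != "none" &
                                 !(trs$gene_id %in% removed_earlier)]
    shared_uid <- names(which(table(tr$copy_uid[tr$event_type !=
                                                  "te_decoy"]) > 1))
    ambiguous <- trs$gene_id[trs$defect == "truncation" &
                               trs$copy_uid %in% as.integer(shared_uid)]
    expect_setequal(setdiff(pg, ambiguous), setdiff(expected_pg, ambiguous))
  }
})

test_that("filtration is idempotent and reports one reason per gene", {
  cfg <- simulation_config(n_ancestral_genes = 80, cds_length = 300,
                           pseudogenization_prob = 0.3,
                           duplication_rate = c(taes = 0.01, bdis = 2e-3,
                                                osat = 1.7e-3, sbic = 2.3e-3),
                           seed = 13)
  sim <- simulate_clade(cfg)
  collapsed <- lapply(sim$genes, collapse_isoforms)
  prots <- stats::setNames(
    unlist(lapply(collapsed, function(g) sub("\\*$", "", g$transcripts$protein)),
           use.names = FALSE),
    unlist(lapply(collapsed, function(g) g$transcripts$gene_id),
           use.names = FALSE))
  hits <- annotate_hits(
    search_proteins(prots, prots, word_size = 5, min_seed_hits = 2),
    collapsed)
  plen <- stats::setNames(nchar(prots), names(prots))
  f1 <- run_filtration(collapsed$taes, hits, c("bdis", "osat", "sbic"),
                       subject_lengths = plen)
  expect_false(any(duplicated(f1$report$reasons$gene_id)))
  expect_true(all(diff(f1$report$counts) <= 0))
  # second pass on the survivors changes nothing
  f2 <- run_filtration(f1$core, hits, c("bdis", "osat", "sbic"),
                       subject_lengths = plen)
  expect_equal(sort(f2$core$genes$gene_id), sort(f1$core$genes$gene_id))
  expect_equal(unname(f2$report$counts["raw"]),
               unname(f2$report$counts["non_pseudogene"]))
  # empty input yields zeros
  f0 <- run_filtration(subset_genes(collapsed$taes, character(0)),
                       hits, c("bdis"), subject_lengths = plen)
  expect_true(all(f0$report$counts == 0))
})
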