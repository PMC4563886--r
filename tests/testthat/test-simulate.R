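# Clade simulator: determinism, event bookkeeping, expected counts, decoys,
# expression tables.

test_that("identical seeds give byte-identical bundles", {
  cfg <- simulation_config(n_ancestral_genes = 25, cds_length = 120,
                           seed = 17)
  d1 <- tempfile()
  d2 <- tempfile()
  write_clade(simulate_clade(cfg), d1)
  write_clade(simulate_clade(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("zero rates give an all-syntenic clade", {
  cfg <- simulation_config(n_ancestral_genes = 40, cds_length = 120,
                           duplication_rate = c(taes = 0, bdis = 0,
                                                osat = 0, sbic = 0),
                           pseudogenization_prob = 0, seed = 2)
  sim <- simulate_clade(cfg)
  cls <- sim$truth$true_class[sim$truth$event_type != "te_decoy"]
  expect_true(all(cls == "syntenic"))
  expect_equal(nrow(sim$events), 0L)
})

test_that("non-syntenic count matches the analytic mean over seeds", {
  # events only on the focal terminal branch: expected count = n * r * T
  n <- 150
  r <- 0.004
  T <- 39
  counts <- vapply(1:100, function(s) {
    cfg <- simulation_config(
      n_ancestral_genes = n, duplication_rate = c(taes = r, bdis = 0,
                                                  osat = 0, sbic = 0),
      pseudogenization_prob = 0, te_decoy_fraction = 0,
      asv_decoy_fraction = 0, sequences = FALSE, seed = 5000 + s)
    sim <- simulate_clade(cfg)
    sum(sim$truth$species == "taes" &
          sim$truth$true_class == "non-syntenic")
  }, numeric(1))
  expected <- n * r * T   # 23.4
  se_mean <- sqrt(expected / 100)  # Poisson counts, 100 seeds
  expect_lt(abs(mean(counts) - expected), 3 * se_mean)
})

test_that("truth classes equal an independent set-logic oracle", {
  cfg <- simulation_config(n_ancestral_genes = 200,
                           duplication_rate = c(taes = 0.01, bdis = 2e-3,
                                                osat = 1.7e-3, sbic = 2.3e-3),
                           pseudogenization_prob = 0.1, sequences = FALSE,
                           seed = 31)
  sim <- simulate_clade(cfg)
  tr <- sim$truth[sim$truth$event_type != "te_decoy", ]
  # oracle: a gene is syntenic iff any copy of its locus (clean or
  # pseudogenized - the sequence is present either way) sits on the
  # same-named chromosome in another compared species; unsupported iff no
  # other species has a clean copy of the locus at all
  species <- c("taes", "bdis", "osat", "sbic")
  for (i in which(tr$species %in% species)) {
    others <- tr[tr$species != tr$species[i] & tr$species %in% species &
                   tr$locus == tr$locus[i], ]
    want <- if (nrow(others[others$defect == "none", ]) == 0) "unsupported"
    else if (any(others$chromosome == tr$chromosome[i])) "syntenic"
    else "non-syntenic"
    if (!identical(tr$true_class[i], want))
      fail(paste("class mismatch for", tr$gene_id[i], ":",
                 tr$true_class[i], "vs oracle", want))
  }
  succeed()
  # the event log covers every emitted event copy
  ev_copies <- unique(tr$copy_uid[tr$event_type %in%
                                    c("duplication", "translocation")])
  expect_true(all(ev_copies %in% sim$events$copy_uid))
  expect_lte(length(ev_copies), nrow(sim$events))
})

test_that("pseudogenized copies carry detectable defects", {
  cfg <- simulation_config(n_ancestral_genes = 120, cds_length = 300,
                           duplication_rate = c(taes = 0.02, bdis = 0,
                                                osat = 0, sbic = 0),
                           pseudogenization_prob = 1, te_decoy_fraction = 0,
                           asv_decoy_fraction = 0, seed = 8)
  sim <- suppressWarnings(simulate_clade(cfg))
  tr <- sim$truth
  bad <- tr[tr$defect != "none", ]
  expect_gt(nrow(bad), 0)
  expect_true(all(bad$defect %in% c("internal_stop", "frameshift",
                                    "truncation")))
  gs <- sim$genes$taes
  for (i in seq_len(nrow(bad))) {
    if (bad$species[i] != "taes") next
    cds <- gs$transcripts$cds_seq[gs$transcripts$gene_id == bad$gene_id[i]]
    res <- detect_pseudogene(cds, homolog_len = 99)
    expect_true(res$pseudogene, label = paste(bad$gene_id[i], bad$defect[i]))
  }
})

test_that("TE and splice-variant decoys are injected as configured", {
  cfg <- simulation_config(n_ancestral_genes = 100, cds_length = 120,
                           te_decoy_fraction = 0.1,
                           asv_decoy_fraction = 0.3, seed = 12)
  sim <- simulate_clade(cfg)
  tr <- sim$truth[sim$truth$species == "bdis", ]
  n_te <- sum(tr$event_type == "te_decoy")
  expect_equal(n_te, round(0.1 * nrow(tr) / 1.1), tolerance = 1)
  gs <- sim$genes$bdis
  multi <- table(gs$transcripts$gene_id)
  expect_equal(sum(tr$n_asv > 0), sum(multi > 1))
  # extra isoforms are strictly shorter, so collapse keeps the original
  col <- collapse_isoforms(gs)
  expect_true(all(grepl("\\.1$", col$transcripts$transcript_id)))
})

test_that("homeolog mode adds relatives and age strata", {
  cfg <- simulation_config(n_ancestral_genes = 100, cds_length = 120,
                           duplication_rate = c(taes = 0.02, bdis = 2e-3,
                                                osat = 1.7e-3, sbic = 2.3e-3),
                           homeolog_mode = TRUE, sequences = FALSE, seed = 4)
  sim <- suppressWarnings(simulate_clade(cfg))
  expect_setequal(names(sim$genes),
                  c("taes", "bdis", "osat", "sbic", "relA", "relD", "sister"))
  ns <- sim$truth[sim$truth$species == "taes" &
                    !is.na(sim$truth$true_class) &
                    sim$truth$true_class == "non-syntenic", ]
  expect_true(all(ns$age_stratum %in% c("recent", "old")))
  # strata agree with event times
  expect_true(all(ns$age_stratum[ns$birth_time < 6.5] == "recent"))
  expect_true(all(ns$age_stratum[ns$birth_time >= 6.5] == "old"))
  d <- sim$lineage$divergence
  expect_equal(d["taes", "relA"], 6.5)
  expect_equal(d["taes", "sister"], 11.6)
  expect_equal(d["relD", "bdis"], 39)
})

test_that("expression tables are deterministic and class-null when configured", {
  cfg <- simulation_config(n_ancestral_genes = 150, sequences = FALSE,
                           seed = 3)
  sim <- simulate_clade(cfg)
  e1 <- simulate_expression_table(sim$truth, sim$config)
  e2 <- simulate_expression_table(sim$truth, sim$config)
  expect_identical(e1, e2)

  # equal class parameters: Mann-Whitney on breadth non-significant in
  # >= 90% of seeds
  null_cfg <- sim$config
  null_cfg$expr_prob <- c(syntenic = 0.8, nonsyntenic = 0.8)
  null_cfg$expr_breadth <- c(syntenic = 0.7, nonsyntenic = 0.7)
  null_cfg$fpkm_meanlog <- c(syntenic = log(100), nonsyntenic = log(100))
  tr <- sim$truth
  cls <- tr$true_class[match(unique(tr$gene_id), tr$gene_id)]
  pvals <- vapply(1:100, function(s) {
    null_cfg$seed <- 7000 + s
    e <- simulate_expression_table(tr, null_cfg)
    breadth <- tapply(e$fpkm > 0, e$gene_id, sum)
    cl <- tr$true_class[match(names(breadth), tr$gene_id)]
    stats::wilcox.test(breadth ~ cl, exact = FALSE)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)

  # zero expression probability: nothing expressed
  off <- sim$config
  off$expr_prob <- c(syntenic = 0, nonsyntenic = 0)
  e0 <- simulate_expression_table(sim$truth, off)
  expect_true(all(e0$fpkm == 0))
})

test_that("high configured rates warn instead of erroring", {
  cfg <- simulation_config(n_ancestral_genes = 10, sequences = FALSE,
                           duplication_rate = c(taes = 0.05, bdis = 0,
                                                osat = 0, sbic = 0),
                           seed = 1)
  expect_warning(simulate_clade(cfg), "multiple events")
})
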