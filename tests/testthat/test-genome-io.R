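# GFF3/FASTA parsing, hit tables, generic TSV round trips.

write_toy_gff <- function(lines, genome = NULL) {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), gff)
  fa <- tempfile(fileext = ".fa")
  if (is.null(genome))
    genome <- c(chr1 = paste(rep("ACGT", 300), collapse = ""))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fa)
  list(gff = gff, fa = fa)
}

test_that("minus-strand gene parses with exons in transcription order", {
  # CDS split over two exons: 60 bp total on the minus strand
  genome <- c(chr1 = paste(c(rep("A", 100),
                             "ATGGCTGCTAAAGCTGCTAAAGCTGCTAAA",  # placeholder
                             rep("A", 200)), collapse = ""))
  # construct the gene so the minus-strand CDS translates cleanly:
  # put reverse-complemented codons on the chromosome
  cds <- "ATGGCTAAACCCGGGTTTACACATGAA"  # 27 bp, 9 codons
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cds, "")[[1]]),
                                     collapse = ""))
  genome <- c(chr1 = paste0(paste(rep("C", 100), collapse = ""), rc,
                            paste(rep("C", 100), collapse = "")))
  # exons: split the 27 bp block at genomic position 101..127 into two
  f <- write_toy_gff(c(
    "chr1\ttest\tgene\t101\t127\t.\t-\t.\tID=g1;description=toy gene",
    "chr1\ttest\tmRNA\t101\t127\t.\t-\t.\tID=g1.1;Parent=g1",
    "chr1\ttest\texon\t113\t127\t.\t-\t.\tParent=g1.1",
    "chr1\ttest\texon\t101\t112\t.\t-\t.\tParent=g1.1",
    "chr1\ttest\tCDS\t113\t127\t.\t-\t0\tParent=g1.1",
    "chr1\ttest\tCDS\t101\t112\t.\t-\t0\tParent=g1.1"), genome)
  gs <- read_gff3(f$gff, f$fa)
  expect_equal(n_genes(gs), 1L)
  tx <- gs$transcripts
  # transcription order on '-': higher coordinates first
  expect_equal(tx$exons[[1]][, 1], c(113, 101))
  expect_equal(tx$cds_seq[1], cds)
  expect_equal(tx$protein[1], translate_cds(cds))
  expect_equal(gs$genes$strand, "-")
})

test_that("parse errors are structured", {
  f <- write_toy_gff(c(
    "chr1\ttest\tgene\t10\t40\t.\t+\t.\tID=g1",
    "chr1\ttest\tgene\t50\t90\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t10\t40\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\ttest\texon\t10\t40\t.\t+\t.\tParent=g1.1"))
  expect_error(read_gff3(f$gff, f$fa), "duplicate gene ID 'g1' at line")

  f2 <- write_toy_gff(c(
    "chr1\ttest\tgene\t10\t40\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t10\t40\t.\t+\t.\tID=g1.1;Parent=gX",
    "chr1\ttest\texon\t10\t40\t.\t+\t.\tParent=g1.1"))
  expect_error(read_gff3(f2$gff, f2$fa), "missing or unknown Parent")

  f3 <- write_toy_gff(c(
    "chr9\ttest\tgene\t10\t39\t.\t+\t.\tID=g1",
    "chr9\ttest\tmRNA\t10\t39\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr9\ttest\texon\t10\t39\t.\t+\t.\tParent=g1.1",
    "chr9\ttest\tCDS\t10\t39\t.\t+\t0\tParent=g1.1"))
  expect_error(read_gff3(f3$gff, f3$fa), "absent from FASTA")
})

test_that("TE flags come from attributes and description text", {
  f <- write_toy_gff(c(
    "chr1\ttest\tgene\t10\t39\t.\t+\t.\tID=g1;description=putative Transposon protein",
    "chr1\ttest\tmRNA\t10\t39\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\ttest\texon\t10\t39\t.\t+\t.\tParent=g1.1",
    "chr1\ttest\tgene\t50\t79\t.\t+\t.\tID=g2;te_related=true",
    "chr1\ttest\tmRNA\t50\t79\t.\t+\t.\tID=g2.1;Parent=g2",
    "chr1\ttest\texon\t50\t79\t.\t+\t.\tParent=g2.1",
    "chr1\ttest\tgene\t90\t119\t.\t+\t.\tID=g3;description=kinase",
    "chr1\ttest\tmRNA\t90\t119\t.\t+\t.\tID=g3.1;Parent=g3",
    "chr1\ttest\texon\t90\t119\t.\t+\t.\tParent=g3.1"))
  gs <- read_gff3(f$gff, f$fa)
  expect_equal(gs$genes$is_te_related[match(c("g1", "g2", "g3"),
                                            gs$genes$gene_id)],
               c(TRUE, TRUE, FALSE))
})

test_that("hit tables parse, validate and annotate", {
  p <- tempfile()
  writeLines(c("g1\tg2\t98.5\t200\t3\t0\t1\t200\t1\t200\t1e-50\t380",
               "g1\tg3\t55\t150\t60\t2\t10\t160\t5\t155\t2e-9\t90"), p)
  h <- read_hit_table(p)
  expect_equal(nrow(h), 2L)
  expect_equal(h$pct_identity[1], 98.5)
  expect_equal(h$evalue[1], 1e-50)
  expect_equal(h$bitscore[2], 90)

  # empty file
  pe <- tempfile()
  file.create(pe)
  expect_equal(nrow(read_hit_table(pe)), 0L)

  # 11 columns
  p11 <- tempfile()
  writeLines("g1\tg2\t98.5\t200\t3\t0\t1\t200\t1\t200\t1e-50", p11)
  expect_error(read_hit_table(p11), ">= 12")

  # non-numeric e-value names the row
  pbad <- tempfile()
  writeLines(c("g1\tg2\t98.5\t200\t3\t0\t1\t200\t1\t200\t1e-50\t380",
               "g1\tg3\t55\t150\t60\t2\t10\t160\t5\t155\tNOPE\t90"), pbad)
  expect_error(read_hit_table(pbad), "row 2")

  # 13th column carries the subject chromosome
  p13 <- tempfile()
  writeLines("g1\tg2\t98.5\t200\t3\t0\t1\t200\t1\t200\t1e-50\t380\tchr7", p13)
  expect_equal(read_hit_table(p13)$subject_chromosome, "chr7")
})

test_that("annotate_hits resolves subject location from gene sets", {
  gs <- mk_gene_set(list(gene_id = "g2", start = 1000, end = 2000,
                         chromosome = "chr3",
                         transcripts = list(list(id = "g2.1"))),
                    species = "spB")
  h <- data.frame(query_id = "g1", subject_id = "g2", pct_identity = 90,
                  aln_length = 10, mismatches = 0, gap_opens = 0,
                  q_start = 1, q_end = 10, s_start = 1, s_end = 10,
                  evalue = 1e-10, bitscore = 50, stringsAsFactors = FALSE)
  a <- annotate_hits(h, gs)
  expect_equal(a$subject_chromosome, "chr3")
  expect_equal(a$subject_pos, 1500)
  expect_equal(a$subject_species, "spB")
  # unknown subject marked unplaced
  h$subject_id <- "nope"
  expect_equal(annotate_hits(h, gs)$subject_chromosome, "unplaced")
})

test_that("write_table round-trips and writes header-only for empty input", {
  df <- data.frame(a = c(1L, 2L), b = c("x", "y"), stringsAsFactors = FALSE)
  p <- tempfile()
  write_table(df, p)
  expect_equal(read_table(p), df)
  write_table(df[0, ], p)
  expect_equal(length(readLines(p)), 1L)
  expect_equal(names(read_table(p)), c("a", "b"))
})

test_that("simulated bundles round-trip through GFF3 + FASTA exactly", {
  cfg <- simulation_config(n_ancestral_genes = 30, cds_length = 150,
                           multi_exon = TRUE, seed = 99)
  sim <- simulate_clade(cfg)
  d <- tempfile()
  write_clade(sim, d)
  gs2 <- read_gff3(file.path(d, "bdis.gff3"), file.path(d, "bdis.genome.fa"))
  g1 <- sim$genes$bdis$genes
  g2 <- gs2$genes[match(g1$gene_id, gs2$genes$gene_id), ]
  expect_equal(g2$start, g1$start)
  expect_equal(g2$end, g1$end)
  expect_equal(g2$strand, g1$strand)
  expect_equal(g2$chromosome, g1$chromosome)
  t1 <- sim$genes$bdis$transcripts
  t2 <- gs2$transcripts[match(t1$transcript_id, gs2$transcripts$transcript_id), ]
  expect_equal(t2$cds_seq, t1$cds_seq)
  # translation of every simulated CDS equals the recorded protein
  expect_equal(vapply(t2$cds_seq, translate_cds, character(1),
                      USE.NAMES = FALSE),
               t1$protein)
})
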