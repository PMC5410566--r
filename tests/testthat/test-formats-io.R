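test_that("FASTA reading validates records and preserves order", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1 first gene", "MKT", ">g2", "GG", "G"), fa)
  recs <- read_fasta(fa, "protein")
  expect_equal(recs$id, c("g1", "g2"))
  expect_equal(recs$residues, c("MKT", "GGG"))
  expect_equal(recs$description[1], "first gene")

  writeLines(character(), fa)
  expect_equal(nrow(read_fasta(fa, "protein")), 0L)

  writeLines(c(">g1", "MKT", ">g1", "AA"), fa)
  expect_error(read_fasta(fa, "protein"), "g1")

  writeLines(c(">g1", "MK1T"), fa)
  expect_error(read_fasta(fa, "protein"), "position 3")

  writeLines(c(">g1", "ACGU"), fa)
  expect_error(read_fasta(fa, "nucleotide"), "illegal")
})

test_that("FASTA round-trips through write_fasta", {
  set.seed(42)
  recs <- data.frame(
    id = paste0("p", 1:8),
    description = c("", "desc one", rep("", 6)),
    residues = vapply(sample(5:200, 8), rand_protein, ""),
    stringsAsFactors = FALSE)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, fa)
  back <- read_fasta(fa, "protein")
  expect_equal(back, recs)
})

test_that("GFF3 reading picks the longest isoform and validates spans", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=e1;Parent=gA.t1",
    "chr1\tsrc\texon\t300\t500\t.\t+\t.\tID=e2;Parent=gA.t1"), gff)
  g <- read_gff3(gff)
  expect_equal(nrow(g), 1L)
  expect_equal(nrow(g$exons[[1]]), 2L)
  expect_equal(g$exons[[1]][, "start"], c(100L, 300L))
  expect_equal(g$protein_id, "gA.t1")

  # two isoforms: summed exon lengths 300 vs 450 -> the longer one wins
  writeLines(c(
    "chr1\tsrc\tgene\t100\t1000\t.\t+\t.\tID=gB",
    "chr1\tsrc\tmRNA\t100\t1000\t.\t+\t.\tID=gB.t1;Parent=gB",
    "chr1\tsrc\texon\t100\t399\t.\t+\t.\tID=x1;Parent=gB.t1",
    "chr1\tsrc\tmRNA\t100\t1000\t.\t+\t.\tID=gB.t2;Parent=gB",
    "chr1\tsrc\texon\t100\t399\t.\t+\t.\tID=y1;Parent=gB.t2",
    "chr1\tsrc\texon\t500\t649\t.\t+\t.\tID=y2;Parent=gB.t2"), gff)
  g <- read_gff3(gff)
  expect_equal(g$protein_id, "gB.t2")
  expect_equal(nrow(g$exons[[1]]), 2L)

  writeLines(c(
    "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=gC",
    "chr1\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=gC.t1;Parent=gC",
    "chr1\tsrc\texon\t600\t700\t.\t+\t.\tID=e1;Parent=gC.t1"), gff)
  expect_error(read_gff3(gff), "outside parent gene span")

  writeLines(c(
    "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=gD",
    "chr1\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=gD.t1",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=e1;Parent=gD.t1"), gff)
  expect_error(read_gff3(gff), "Parent")
})

test_that("domain table parsing computes profile coverage", {
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# target_id domain_id i_evalue hmm_from hmm_to ali_from ali_to hmm_len",
    "p1 PF00226 1e-20 1 63 10 72 63",
    "p2 PF00226 1e-08 10 40 5 35 63"), tab)
  hits <- read_domain_table(tab)
  expect_equal(hits$profile_cov, c(1.0, 31 / 63))
  expect_equal(hits$protein_id, c("p1", "p2"))

  writeLines(c("p1 PF00226 1e-20 1 xx 10 72 63"), tab)
  expect_error(read_domain_table(tab), "line 1")

  writeLines("# only comments", tab)
  expect_equal(nrow(read_domain_table(tab)), 0L)
})

test_that("BED output converts 1-based inclusive to 0-based half-open", {
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(data.frame(chrom = "chr1", start = 11L, end = 20L), bed)
  lines <- grep("^#", readLines(bed), value = TRUE, invert = TRUE)
  f <- strsplit(lines, "\t")[[1]]
  expect_equal(as.integer(f[2:3]), c(10L, 20L))
  # span length preserved
  expect_equal(as.integer(f[3]) - as.integer(f[2]), 20L - 11L + 1L)

  write_bed(data.frame(chrom = character(), start = integer(),
                       end = integer()), bed)
  expect_true(all(grepl("^#", readLines(bed))))
})

test_that("TSV tables round-trip losslessly", {
  set.seed(7)
  tab <- data.frame(gene = paste0("g", 1:10),
                    value = round(rnorm(10), 6),
                    n = sample.int(100, 10),
                    label = sample(letters, 10),
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(tab, f)
  expect_equal(read_tsv(f), tab)
})

test_that("the bundled pepper catalog matches its published shape", {
  cat76 <- load_catalog()
  expect_equal(nrow(cat76), 76L)
  expect_equal(cat76$gene_name, sprintf("CaDnaJ%02d", 1:76))
  expect_equal(cat76$group[cat76$gene_name == "CaDnaJ36"], "D")
  expect_equal(cat76$size_aa[cat76$gene_name == "CaDnaJ23"], 130L)
  expect_equal(sum(cat76$chromosome == "00"), 5L)
  expect_equal(sum(cat76$chromosome %in% as.character(1:12)), 71L)
  expect_true(all(is.na(cat76$start[cat76$chromosome == "00"])))
  # constant fixture: repeated loads identical
  expect_identical(cat76, load_catalog())
})
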