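test_that("simulation is byte-identical for a fixed seed", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  tiny <- simulation_design(seed = 5L, n_chromosomes = 1L,
                            group_counts = c(A = 1L, B = 1L, C = 3L,
                                             D = 1L, E = 1L),
                            n_decoys = 1L, n_tandem_pairs = 1L,
                            n_segmental_pairs = 1L,
                            intergenic_bp = c(4000L, 6000L))
  s1 <- simulate_family(tiny, d1)
  s2 <- simulate_family(tiny, d2)
  for (nm in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[nm]]), readLines(s2$paths[[nm]]),
                     info = nm)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("infeasible designs are rejected", {
  expect_error(simulation_design(group_counts = c(A = 1L, B = 1L, C = 1L,
                                                  D = 1L, E = 1L),
                                 n_tandem_pairs = 1L), "infeasible")
  expect_error(simulation_design(tandem_identity = 0.6), "tandem_identity")
})

test_that("every generated file parses with the package readers", {
  sim <- shared_sim()
  genome <- read_fasta(sim$paths$genome, "nucleotide")
  expect_equal(nrow(genome), sim$design$n_chromosomes)
  genes <- read_gff3(sim$paths$gff)
  expect_equal(nrow(genes), nrow(sim$truth$genes))
  proteins <- read_fasta(sim$paths$proteins, "protein")
  expect_equal(sort(proteins$id), sort(sim$truth$genes$protein_id))
  hits <- read_domain_table(sim$paths$domains)
  expect_equal(nrow(hits), nrow(sim$truth$genes))
  proms <- read_fasta(sim$paths$promoters, "nucleotide")
  expect_equal(nrow(proms), nrow(sim$truth$genes))
  m <- read_expression(sim$paths$expression)
  expect_equal(nrow(m), sum(sim$truth$genes$role == "family"))
  ct <- read_qpcr(sim$paths$qpcr)
  expect_true("UBI" %in% ct$gene)
})

test_that("planted architectures, groups and introns are recovered exactly", {
  sim <- shared_sim()
  proteins <- read_fasta(sim$paths$proteins, "protein")
  hits <- read_domain_table(sim$paths$domains)
  arch <- assemble_architectures(proteins, hits)
  flt <- filter_complete(arch)
  truth <- sim$truth$genes
  fam <- truth[truth$role == "family", ]
  # the filter separates family from decoys perfectly (noise-free plants)
  expect_equal(sort(flt$retained$protein_id), sort(fam$protein_id))
  expect_equal(nrow(flt$removed), sim$design$n_decoys)
  classified <- classify_architectures(flt$retained)
  k <- match(classified$protein_id, fam$protein_id)
  expect_equal(classified$group, fam$group[k])
  # intron counts from the GFF equal the planted exon structure
  genes <- read_gff3(sim$paths$gff)
  k2 <- match(genes$gene_id, truth$locus)
  expect_equal(intron_count(genes), truth$introns[k2])
})

test_that("planted tandem pairs are recovered and no others are called", {
  sim <- shared_sim()
  truth <- sim$truth$genes
  fam <- truth[truth$role == "family", ]
  genes <- read_gff3(sim$paths$gff)
  proteins <- read_fasta(sim$paths$proteins, "protein")
  k <- match(fam$protein_id, genes$protein_id)
  members <- data.frame(gene_name = fam$locus,
                        chromosome = genes$chromosome[k],
                        start = genes$start[k], end = genes$end[k])
  seqs <- stats::setNames(
    proteins$residues[match(fam$protein_id, proteins$id)], fam$locus)
  calls <- call_tandem(members, seqs)
  want <- sim$truth$pairs
  expect_equal(nrow(calls), nrow(want))
  got_pairs <- paste(calls$gene_a, calls$gene_b)
  want_pairs <- vapply(seq_len(nrow(want)), function(i) {
    paste(sort(c(want$locus_a[i], want$locus_b[i])), collapse = " ")
  }, "")
  expect_setequal(got_pairs, want_pairs)
  # called identity is close to the planted identity
  expect_equal(calls$identity[order(got_pairs)],
               want$identity[order(want_pairs)], tolerance = 0.05)
  expect_true(all(calls$distance_bp < 100000L))
})

test_that("planted promoter motifs are recovered exactly", {
  sim <- shared_sim()
  proms <- read_fasta(sim$paths$promoters, "nucleotide")
  hits <- scan_motifs(proms)
  truth <- sim$truth$motifs
  for (i in seq_len(nrow(truth))) {
    got <- sum(hits$gene == truth$locus[i] & hits$motif == truth$motif[i])
    expect_equal(got, truth$copies[i],
                 info = paste(truth$locus[i], truth$motif[i]))
  }
  # and extracting windows from the genome reproduces the bundled FASTA
  genome <- read_fasta(sim$paths$genome, "nucleotide")
  genes <- read_gff3(sim$paths$gff)
  prom2 <- extract_promoters(genome, genes, sim$design$upstream_bp)
  k <- match(proms$id, prom2$id)
  expect_equal(prom2$residues[k], proms$residues)
})

test_that("planted expression patterns and qPCR folds are recovered", {
  sim <- shared_sim()
  truth <- sim$truth$genes
  fam <- truth[truth$role == "family", ]
  m <- read_expression(sim$paths$expression)
  calls <- classify_pattern(m)
  k <- match(calls$gene, fam$locus)
  expect_equal(calls$pattern, fam$pattern[k])
  ct <- read_qpcr(sim$paths$qpcr)
  folds <- qpcr_foldchanges(ct, "UBI")
  k2 <- match(folds$gene, fam$locus)
  # estimates track the planted folds (shared reference noise allowed for)
  expect_gt(cor(folds$log2_fold, fam$log2_fold[k2]), 0.97)
  expect_lt(median(abs(folds$log2_fold - fam$log2_fold[k2])), 0.6)
})
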