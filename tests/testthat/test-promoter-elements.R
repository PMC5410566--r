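toy_genome <- function(seqs) {
  data.frame(id = names(seqs), description = "", residues = unname(seqs),
             stringsAsFactors = FALSE)
}

test_that("promoter windows obey the upstream arithmetic and truncation", {
  set.seed(61)
  contig <- rand_dna(5000)
  genome <- toy_genome(c("1" = contig))
  genes <- data.frame(gene_id = "g1", chromosome = "1", start = 2001L,
                      end = 3000L, strand = "+")
  prom <- extract_promoters(genome, genes)
  expect_equal(prom$length, 1500L)
  expect_equal(prom$residues, substr(contig, 501, 2000))

  genes$start <- 1001L
  prom <- extract_promoters(genome, genes)
  expect_equal(prom$length, 1000L)
  expect_equal(prom$residues, substr(contig, 1, 1000))

  # minus strand on a 30 bp toy contig, checked by hand
  toy <- "AAACCCGGGTTTACGTACGTAAACCCGGGT"
  genome <- toy_genome(c("c" = toy))
  genes <- data.frame(gene_id = "g2", chromosome = "c", start = 1L,
                      end = 10L, strand = "-")
  prom <- extract_promoters(genome, genes, upstream_bp = 8L)
  expect_equal(prom$residues, reverse_complement(substr(toy, 11, 18)))
  expect_equal(prom$residues, "GTACGTAA")

  genes$chromosome <- "missing"
  expect_error(extract_promoters(genome, genes), "missing contig")
})

test_that("motif scanning finds the HSE core on both strands", {
  hse <- "AAAAAATTTC"
  # flanks chosen so no junction creates another bundled-motif match
  prom <- data.frame(id = "g1", residues = paste0(strrep("G", 40), hse,
                                                  strrep("C", 40)))
  hits <- scan_motifs(prom)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif, "HSE")
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 41L)
  expect_equal(hits$matched_seq, hse)

  # reverse complement of the core: a minus-strand hit in forward coords
  prom$residues <- paste0(strrep("G", 40), reverse_complement(hse),
                          strrep("C", 40))
  hits <- scan_motifs(prom)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$matched_seq, hse)

  # all-G promoter: nothing matches any bundled motif
  prom$residues <- strrep("G", 200)
  expect_equal(nrow(scan_motifs(prom)), 0L)
})

test_that("IUPAC matching agrees with a naive oracle on all 15 codes", {
  set.seed(67)
  motifs <- c("ACGT", "RYSWKM", "BDHVN", "ANNT", "CWWG", "NRYN")
  for (rep in 1:30) {
    s <- rand_dna(sample(50:300, 1))
    m <- sample(motifs, 1)
    prom <- data.frame(id = "p", residues = s)
    got <- scan_motifs(prom, data.frame(name = "m", sequence = m,
                                        category = "x", response = "y"),
                       both_strands = FALSE)
    expect_equal(got$start, naive_iupac_positions(s, m), info = paste(s, m))
  }
})

test_that("strand symmetry: scanning S equals scanning its reverse complement", {
  set.seed(71)
  motifs <- default_motifs()
  for (rep in 1:10) {
    s <- rand_dna(400)
    p1 <- data.frame(id = "p", residues = s)
    p2 <- data.frame(id = "p", residues = reverse_complement(s))
    h1 <- scan_motifs(p1, motifs)
    h2 <- scan_motifs(p2, motifs)
    expect_equal(nrow(h1), nrow(h2))
    # mirrored coordinates match per motif
    for (mn in unique(h1$motif)) {
      a <- h1[h1$motif == mn, ]
      b <- h2[h2$motif == mn, ]
      expect_equal(sort(nchar(s) - a$end + 1L), sort(b$start), info = mn)
    }
  }
})

test_that("element census conserves totals", {
  set.seed(73)
  proms <- data.frame(id = paste0("g", 1:5),
                      residues = vapply(rep(600, 5), rand_dna, ""))
  # plant two HSEs in g1, one MBS in g2
  substr(proms$residues[1], 11, 20) <- "AAAAAATTTC"
  substr(proms$residues[1], 101, 110) <- "AAAAAATTTC"
  substr(proms$residues[2], 51, 56) <- "CAACTG"
  hits <- scan_motifs(proms)
  cen <- element_census(hits, proms$id)
  expect_equal(sum(cen$per_motif$total_hits), nrow(hits))
  expect_equal(sum(cen$per_gene$n_elements), nrow(hits))
  expect_true(all(cen$per_motif$genes_with_hit <= nrow(proms)))
  expect_gte(cen$per_motif$total_hits[cen$per_motif$motif == "HSE"], 2L)
  expect_gte(cen$per_gene$n_elements[cen$per_gene$gene == "g1"], 2L)
  # genes with zero hits still appear
  expect_equal(nrow(cen$per_gene), 5L)

  none <- element_census(hits[0, ], proms$id)
  expect_true(all(none$per_motif$total_hits == 0L))
  expect_true(all(none$per_gene$n_elements == 0L))
})
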