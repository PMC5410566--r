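test_that("chromosome distribution matches the published counts", {
  dist <- chromosome_distribution(load_catalog())
  expect_equal(unname(dist["8"]), 11L)
  expect_equal(unname(dist["5"]), 9L)
  expect_equal(unname(dist["6"]), 3L)
  expect_equal(unname(dist["10"]), 3L)
  expect_equal(unname(dist["00"]), 5L)
  expect_equal(sum(dist), 76L)
  expect_equal(length(chromosome_distribution(load_catalog()[0, ])), 0L)
})

test_that("the catalog yields exactly the published 100-kb candidate pair", {
  cand <- tandem_candidates(load_catalog())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$gene_a, "CaDnaJ41")
  expect_equal(cand$gene_b, "CaDnaJ42")
  expect_equal(cand$chromosome, "7")
  expect_equal(cand$distance_bp, 230043861L - 230039930L)

  far <- data.frame(gene_name = c("g1", "g2"), chromosome = "1",
                    start = c(1000L, 301000L), end = c(2000L, 302000L))
  expect_equal(nrow(tandem_candidates(far)), 0L)
})

test_that("candidate detection agrees with an all-pairs brute force", {
  set.seed(43)
  crit <- duplication_criteria(max_intervening_genes = NA)
  for (rep in 1:5) {
    n <- 30L
    start <- sort(sample.int(3e6, n))
    members <- data.frame(gene_name = sprintf("g%02d", 1:n),
                          chromosome = sample(c("1", "2"), n, replace = TRUE),
                          start = start, end = start + sample(500:3000, n,
                                                              replace = TRUE))
    got <- tandem_candidates(members, crit)
    # quadratic oracle
    want <- 0L
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (members$chromosome[i] != members$chromosome[j]) next
        lo <- if (members$start[i] <= members$start[j]) i else j
        hi <- if (lo == i) j else i
        gap <- max(0L, members$start[hi] - members$end[lo])
        if (gap <= crit$max_distance_bp) want <- want + 1L
      }
    }
    expect_equal(nrow(got), want)
    # symmetric, canonical, unique
    expect_true(all(got$gene_a < got$gene_b))
    expect_equal(anyDuplicated(paste(got$gene_a, got$gene_b)), 0L)
    perm <- members[sample(n), ]
    got2 <- tandem_candidates(perm, crit)
    expect_equal(got2, got)
  }
})

test_that("global alignment reports exact coverage and identity", {
  al <- global_align(strrep("K", 50), strrep("K", 50))
  expect_equal(al$coverage_of_longer, 1.0)
  expect_equal(al$identity_of_aligned, 1.0)
  al <- global_align("ACGT", "ACGA")
  expect_equal(al$identity_of_aligned, 0.75)
  expect_equal(al$aligned_pairs, 4L)
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("alignment DP equals a memoized exhaustive oracle", {
  set.seed(47)
  for (rep in 1:40) {
    a <- rand_dna(sample(1:12, 1))
    b <- rand_dna(sample(1:12, 1))
    expect_equal(global_align(a, b)$score, nw_score_oracle(a, b),
                 info = paste(a, b))
  }
  for (rep in 1:10) {
    a <- rand_protein(sample(1:12, 1))
    b <- rand_protein(sample(1:12, 1))
    expect_equal(global_align(a, b)$score, nw_score_oracle(a, b),
                 info = paste(a, b))
  }
})

test_that("coverage and identity stay within [0,1] on random pairs", {
  set.seed(53)
  for (rep in 1:20) {
    al <- global_align(rand_protein(sample(1:60, 1)),
                       rand_protein(sample(1:60, 1)))
    expect_gte(al$coverage_of_longer, 0)
    expect_lte(al$coverage_of_longer, 1)
    expect_gte(al$identity_of_aligned, 0)
    expect_lte(al$identity_of_aligned, 1)
  }
})

test_that("tandem calling applies the strict 70% rules", {
  members <- data.frame(gene_name = c("g1", "g2"), chromosome = "1",
                        start = c(1000L, 6000L), end = c(2000L, 7000L))
  set.seed(59)
  base <- rand_protein(200)
  mut <- strsplit(base, "")[[1]]
  idx <- sample(200, 30)  # 85% identity
  for (i in idx) mut[i] <- sample(setdiff(AA20, mut[i]), 1)
  seqs <- c(g1 = base, g2 = paste(mut, collapse = ""))
  calls <- call_tandem(members, seqs)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$kind, "tandem")
  expect_gt(calls$identity, 0.8)

  # identity exactly 0.70 is NOT more than 70%
  seqs_edge <- c(g1 = strrep("A", 10),
                 g2 = paste0(strrep("A", 7), "WWW"))
  expect_equal(global_align(seqs_edge[[1]],
                            seqs_edge[[2]])$identity_of_aligned, 0.7)
  expect_equal(nrow(call_tandem(members, seqs_edge)), 0L)

  # unrelated random neighbours are far below the identity rule
  seqs_rand <- c(g1 = rand_protein(200), g2 = rand_protein(210))
  expect_equal(nrow(call_tandem(members, seqs_rand)), 0L)

  expect_error(call_tandem(members, seqs["g1"]), "g2")
})

test_that("segmental pair ingestion maps loci and skips unknowns", {
  members <- data.frame(gene_name = c("CaDnaJ04", "CaDnaJ44"),
                        locus = c("CA01g22020", "CA08g04550"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# locus_a\tlocus_b", "CA01g22020\tCA08g04550"), f)
  seg <- read_segmental_pairs(f, members)
  expect_equal(seg$gene_a, "CaDnaJ04")
  expect_equal(seg$gene_b, "CaDnaJ44")
  expect_equal(seg$kind, "segmental")

  writeLines("# header only", f)
  expect_equal(nrow(read_segmental_pairs(f, members)), 0L)

  writeLines(c("CA01g22020\tCAXXg00000"), f)
  expect_warning(seg <- read_segmental_pairs(f, members), "unknown locus")
  expect_equal(nrow(seg), 0L)
})
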