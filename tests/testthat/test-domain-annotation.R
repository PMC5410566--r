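test_that("find_pattern locates literal and wildcard motifs", {
  expect_equal(find_pattern("AHPDA", "HPD"), data.frame(start = 2L, end = 4L))
  expect_equal(find_pattern("CAACAGAG", "CxxCxGxG"),
               data.frame(start = 1L, end = 8L))
  expect_equal(nrow(find_pattern("MMMM", "HPD")), 0L)
})

test_that("find_pattern agrees with a naive character-by-character oracle", {
  set.seed(11)
  patterns <- c("HPD", "CxxCxGxG", "AxA", "GG", "KxxxK")
  for (rep in 1:40) {
    s <- rand_protein(sample(10:150, 1))
    p <- sample(patterns, 1)
    expect_equal(find_pattern(s, p), naive_find_pattern(s, p),
                 info = paste(s, p))
  }
})

test_that("profile scanner recovers planted consensus and stays quiet on background", {
  model <- jdomain_profile()
  set.seed(5)
  # planted, lightly mutated consensus inside random background
  for (rep in 1:10) {
    plant_at <- sample(30:80, 1)
    cons <- model$consensus
    seq <- paste0(rand_protein(plant_at - 1L), cons,
                  rand_protein(sample(20:60, 1)))
    hits <- scan_profile(seq, model)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$ali_from, plant_at)
    expect_equal(hits$ali_to, plant_at + model$length - 1L)
  }
  # background false-positive rate: no hits over 200 random 200-mers
  n_hits <- sum(vapply(1:200, function(i) {
    nrow(scan_profile(rand_protein(200), model))
  }, 0L))
  expect_equal(n_hits, 0L)
  # sequence shorter than the model: empty result, not an error
  expect_equal(nrow(scan_profile(rand_protein(10), model)), 0L)
})

test_that("profile scanner's best placement matches brute-force scoring", {
  model <- profile_model("ACDEFGHIKL", name = "TOY")
  set.seed(13)
  brute_best <- function(seq) {
    idx <- match(strsplit(seq, "")[[1]], AA20)
    L <- model$length
    scores <- vapply(seq_len(nchar(seq) - L + 1L), function(i) {
      sum(model$scores[cbind(idx[i:(i + L - 1L)], seq_len(L))])
    }, 0)
    c(which.max(scores), max(scores))
  }
  for (rep in 1:25) {
    seq <- paste0(rand_protein(sample(0:40, 1)), "ACDEFGHIKL",
                  rand_protein(sample(0:40, 1)))
    hits <- scan_profile(seq, model)
    bb <- brute_best(seq)
    expect_equal(hits$ali_from[which.max(hits$score)], as.integer(bb[1]))
    expect_equal(max(hits$score), bb[2], tolerance = 1e-10)
  }
  # the consensus itself attains the maximal score
  hit <- scan_profile("ACDEFGHIKL", model)
  expect_equal(hit$score, 10 * log2(0.6 / 0.05), tolerance = 1e-10)
})

test_that("architecture assembly applies containment and threshold rules", {
  cfg <- arch_config()
  jhit <- function(from, to, cov = 1, e = 1e-20) {
    data.frame(protein_id = "p", domain_id = "PF00226", e_value = e,
               ali_from = from, ali_to = to, profile_cov = cov)
  }
  # complete J + internal HPD + 2 ZF repeats + long tail; the filler is
  # alanine so no accidental motifs appear
  ala <- function(n) strrep("A", n)
  seq <- paste0(ala(10), "AAHPDAA", ala(10),
                "CAACAGAG", "WWWWW", "CTTCTGTG", ala(200))
  arch <- assemble_architecture("p", seq, jhit(5, 30), cfg)
  expect_true(arch$j_complete)
  expect_true(arch$has_hpd)
  expect_equal(arch$zf_repeats, 2L)
  expect_true(arch$has_zinc_finger)
  expect_true(arch$has_cterm)

  # half-coverage J hit is not complete
  arch <- assemble_architecture("p", seq, jhit(5, 30, cov = 0.5), cfg)
  expect_false(arch$j_complete)

  # HPD outside the J span does not count
  arch <- assemble_architecture("p", seq, jhit(30, 60), cfg)
  expect_false(arch$has_hpd)

  # failing the E-value screen removes the hit entirely
  arch <- assemble_architecture("p", seq, jhit(5, 30, e = 1e-3), cfg)
  expect_equal(arch$n_j, 0L)

  expect_error(
    assemble_architecture("p", "MKT", jhit(1, 70), cfg),
    "beyond protein length")
})

test_that("architecture assembly is deterministic and total", {
  set.seed(17)
  model <- jdomain_profile()
  for (rep in 1:10) {
    seq <- paste0(rand_protein(20), model$consensus, rand_protein(50))
    hits <- scan_profile(seq, model)
    hits$protein_id <- "p"
    a1 <- assemble_architecture("p", seq, hits)
    a2 <- assemble_architecture("p", seq, hits)
    expect_identical(a1, a2)
  }
})
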