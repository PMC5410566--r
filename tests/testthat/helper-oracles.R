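# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# naive non-overlapping left-to-right matcher for residue patterns with 'x'
naive_find_pattern <- function(seq, pattern) {
  sv <- strsplit(seq, "")[[1]]
  pv <- strsplit(pattern, "")[[1]]
  n <- length(sv); m <- length(pv)
  out <- NULL
  i <- 1L
  while (i <= n - m + 1L) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (pv[j] != "x" && sv[i + j - 1L] != pv[j]) { ok <- FALSE; break }
    }
    if (ok) {
      out <- rbind(out, c(i, i + m - 1L))
      i <- i + m
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) data.frame(start = integer(), end = integer())
  else data.frame(start = out[, 1L], end = out[, 2L])
}

IUPAC_SETS <- c(A = "A", C = "C", G = "G", T = "T",
                R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# all (overlapping) forward-strand match positions of an IUPAC motif
naive_iupac_positions <- function(seq, motif) {
  sv <- strsplit(seq, "")[[1]]
  mv <- strsplit(motif, "")[[1]]
  n <- length(sv); m <- length(mv)
  if (n < m) return(integer())
  hits <- integer()
  for (i in seq_len(n - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!grepl(sv[i + j - 1L], IUPAC_SETS[[mv[j]]], fixed = TRUE)) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

naive_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# exhaustive global-alignment score by memoized recursion
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == 0L && j == 0L) 0
    else if (i == 0L) j * gap
    else if (j == 0L) i * gap
    else max(rec(i - 1L, j - 1L) + if (av[i] == bv[j]) match else mismatch,
             rec(i - 1L, j) + gap,
             rec(i, j - 1L) + gap)
    memo[[key]] <- v
    v
  }
  rec(length(av), length(bv))
}

# fine-grid scan for the isoelectric point, independent of the bisection
grid_pi_oracle <- function(seq, step = 1e-4) {
  ph <- seq(0, 14, by = step)
  q <- dnajfam::net_charge(seq, ph)
  ph[which.min(abs(q))]
}

# brute-force average-linkage agglomeration: returns merge heights and the
# member sets created at each step
brute_average_linkage <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- lapply(seq_len(nrow(m)), identity)
  heights <- numeric(0)
  sets <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, bestd)
    sets[[length(sets) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, sets = sets)
}

# one shared small-simulation bundle, built lazily and reused across files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_family(small_design(),
                                file.path(tempdir(), "dnajfam-shared-sim"))
    }
    cache
  }
})

# small, fast simulation design shared by the synthetic-data tests
small_design <- function(seed = 101L, ...) {
  simulation_design(
    seed = seed, n_chromosomes = 2L,
    group_counts = c(A = 2L, B = 2L, C = 6L, D = 1L, E = 2L),
    n_decoys = 3L, n_tandem_pairs = 1L, n_segmental_pairs = 1L,
    intergenic_bp = c(4000L, 8000L),
    pattern_props = c(barely_expressed = 0.3, constitutive = 0.2,
                      tissue_specific = 0.2, other = 0.3),
    ...)
}
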