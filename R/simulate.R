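# Minimal codon map for reverse translation (one codon per residue).
.CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
            G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
            M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
            S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

.rand_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.rand_aa <- function(n) {
  paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

# substitute a fraction of positions (never to the same residue),
# protecting the given positions
.mutate_protein <- function(seq, rate, protect = integer()) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    ch[i] <- sample(setdiff(.AA20, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# count occurrences (overlaps included, both strands) of a plain or IUPAC
# motif in a window; naive position-by-position matcher, deliberately
# independent of the scanning implementation used by the pipeline
.naive_motif_count <- function(window, motif) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T",
             R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
             B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  count_one <- function(w, m) {
    wv <- strsplit(w, "")[[1]]
    mv <- strsplit(m, "")[[1]]
    n <- length(wv)
    L <- length(mv)
    if (n < L) return(0L)
    hits <- 0L
    for (i in seq_len(n - L + 1L)) {
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!grepl(wv[i + j - 1L], iupac[[mv[j]]], fixed = TRUE)) {
          ok <- FALSE
          break
        }
      }
      if (ok) hits <- hits + 1L
    }
    hits
  }
  count_one(window, motif) + count_one(window, reverse_complement(motif))
}

#' Simulation design for the synthetic-data generator
#'
#' Defines the study conditions emulated by [simulate_family()]. The
#' defaults mirror the published pepper survey: 76 family genes in groups
#' A-E at 9/8/53/1/5, nine decoy candidates whose J-domain evidence covers
#' less than the completeness threshold, one planted tandem pair under
#' 100 kb with ~85% protein identity, two precomputed segmental pairs,
#' promoter motif rates echoing the printed per-gene element tallies,
#' expression archetypes in the printed 29/10/3/34 proportions, and qPCR
#' log2 fold changes drawn uniformly from [-3, 3] with 0.2-cycle replicate
#' noise.
#'
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @param n_chromosomes Number of chromosomes.
#' @param group_counts Named integer vector of family members per group
#'   A-E.
#' @param n_decoys Candidates with incomplete J-domain evidence.
#' @param n_tandem_pairs Planted tandem duplicate pairs (drawn from group
#'   C members).
#' @param tandem_identity Target protein identity of planted duplicates,
#'   in (0.7, 1].
#' @param n_segmental_pairs Locus pairs written to the synteny input file.
#' @param intergenic_bp Range (lo, hi) of intergenic gaps in bp; planted
#'   tandem pairs use a 3.2-6 kb gap instead.
#' @param upstream_bp Promoter window length.
#' @param motif_rates Named mean planted copies per promoter for each
#'   bundled motif.
#' @param pattern_props Proportions of expression archetypes
#'   (`barely_expressed`, `constitutive`, `tissue_specific`, `other`).
#' @param qpcr_log2fold_range Range of true log2 fold changes.
#' @param ct_noise_sd Replicate Ct noise (cycles).
#' @param n_replicates qPCR replicates per condition.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(seed = 1L,
                              n_chromosomes = 12L,
                              group_counts = c(A = 9L, B = 8L, C = 53L,
                                               D = 1L, E = 5L),
                              n_decoys = 9L,
                              n_tandem_pairs = 1L,
                              tandem_identity = 0.85,
                              n_segmental_pairs = 2L,
                              intergenic_bp = c(30000L, 60000L),
                              upstream_bp = 1500L,
                              motif_rates = c(
                                "HSE" = 1.0, "TC-rich" = 1.4, "LTR" = 0.45,
                                "MBS" = 1.3, "ABRE" = 0.75,
                                "TCA-element" = 1.05, "TGA-element" = 0.5,
                                "GARE-motif" = 1.2, "CGTCA-motif" = 1.85,
                                "ERE" = 0.5),
                              pattern_props = c(barely_expressed = 29,
                                                constitutive = 10,
                                                tissue_specific = 3,
                                                other = 34) / 76,
                              qpcr_log2fold_range = c(-3, 3),
                              ct_noise_sd = 0.2,
                              n_replicates = 3L) {
  stopifnot(length(group_counts) == 5L,
            identical(sort(names(group_counts)), c("A", "B", "C", "D", "E")),
            all(group_counts >= 0L), sum(group_counts) >= 1L,
            n_chromosomes >= 1L, n_decoys >= 0L,
            tandem_identity > 0.7, tandem_identity <= 1,
            abs(sum(pattern_props) - 1) < 1e-8,
            ct_noise_sd >= 0, n_replicates >= 1L)
  if (2L * n_tandem_pairs > group_counts[["C"]]) {
    stop("infeasible design: not enough group C members for ",
         n_tandem_pairs, " tandem pair(s)")
  }
  structure(list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                 group_counts = group_counts, n_decoys = as.integer(n_decoys),
                 n_tandem_pairs = as.integer(n_tandem_pairs),
                 tandem_identity = tandem_identity,
                 n_segmental_pairs = as.integer(n_segmental_pairs),
                 intergenic_bp = as.integer(intergenic_bp),
                 upstream_bp = as.integer(upstream_bp),
                 motif_rates = motif_rates, pattern_props = pattern_props,
                 qpcr_log2fold_range = qpcr_log2fold_range,
                 ct_noise_sd = ct_noise_sd,
                 n_replicates = as.integer(n_replicates)),
            class = "simulation_design")
}

# build one family protein with the architecture its group requires;
# validated by construction (resampled until pattern checks pass)
.make_protein <- function(group, model) {
  cons <- model$consensus
  L <- model$length
  hpd_at <- as.integer(regexpr("HPD", cons))
  repeat {
    # long, variable N-terminal region (J-proteins place the J-domain
    # N-proximally but not terminally); keeps the conserved J-domain a
    # minority of the protein so unrelated members stay well below the
    # duplication identity threshold
    pad <- paste0("M", .rand_aa(sample(40:200, 1L)))
    jd <- if (group == "E") {
      alt <- sample(c("HPN", "QPD", "RPD", "HAD"), 1L)
      j <- paste0(substr(cons, 1L, hpd_at - 1L), alt,
                  substr(cons, hpd_at + 3L, L))
      .mutate_protein(j, 0.05, protect = hpd_at:(hpd_at + 2L))
    } else {
      .mutate_protein(cons, 0.05, protect = hpd_at:(hpd_at + 2L))
    }
    zf <- ""
    if (group %in% c("A", "D")) {
      reps <- vapply(1:4, function(i) {
        r <- function(n) .rand_aa(n)
        paste0("C", r(2L), "C", r(1L), "G", r(1L), "G")
      }, character(1L))
      zf <- paste0(.rand_aa(sample(8:15, 1L)),
                   paste(reps, collapse = .rand_aa(9L)))
    }
    tail_len <- switch(group,
                       A = sample(60:150, 1L), B = sample(60:150, 1L),
                       C = sample(5:30, 1L), D = sample(5:15, 1L),
                       E = sample(5:30, 1L))
    seq <- paste0(pad, jd, zf, .rand_aa(tail_len))
    j_from <- nchar(pad) + 1L
    j_to <- nchar(pad) + L
    # construction checks: HPD containment, zinc-finger repeat count,
    # and C-terminal extent must match the group exactly
    hpd <- find_pattern(seq, "HPD")
    has_hpd <- nrow(hpd) > 0L &&
      any(hpd$start >= j_from & hpd$end <= j_to)
    zfm <- find_pattern(seq, "CxxCxGxG")
    want_zf <- if (group %in% c("A", "D")) 4L else 0L
    dom_end <- max(c(j_to, zfm$end))
    has_ct <- (nchar(seq) - dom_end) >= 40L
    ok <- nrow(zfm) == want_zf &&
      has_hpd == (group != "E") &&
      has_ct == (group %in% c("A", "B"))
    if (ok) {
      return(list(seq = seq, j_from = j_from, j_to = j_to,
                  zf_repeats = nrow(zfm), has_hpd = has_hpd,
                  has_cterm = has_ct))
    }
  }
}

# decoy: a J-domain fragment covering `cov` of the profile
.make_decoy <- function(model, cov) {
  L <- model$length
  k <- max(5L, as.integer(round(cov * L)))
  pad <- paste0("M", .rand_aa(sample(40:200, 1L)))
  frag <- .mutate_protein(substr(model$consensus, 1L, k), 0.05)
  seq <- paste0(pad, frag, .rand_aa(sample(50:150, 1L)))
  list(seq = seq, j_from = nchar(pad) + 1L, j_to = nchar(pad) + k,
       hmm_to = k)
}

# split a CDS into exon pieces and interleave GT..AG introns;
# returns the composite (transcription orientation) and exon offsets
.make_gene_structure <- function(cds, n_exons) {
  n <- nchar(cds)
  if (n_exons > 1L) {
    cuts <- sort(sample(seq(3L, n - 3L, by = 3L), n_exons - 1L))
  } else {
    cuts <- integer()
  }
  bounds <- cbind(start = c(1L, cuts + 1L), end = c(cuts, n))
  pieces <- character(0)
  offsets <- matrix(0L, nrow = n_exons, ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
  pos <- 0L
  for (e in seq_len(n_exons)) {
    ex <- substr(cds, bounds[e, 1L], bounds[e, 2L])
    pieces <- c(pieces, ex)
    offsets[e, ] <- c(pos + 1L, pos + nchar(ex))
    pos <- pos + nchar(ex)
    if (e < n_exons) {
      intron <- paste0("GT", .rand_nt(sample(96:396, 1L)), "AG")
      pieces <- c(pieces, intron)
      pos <- pos + nchar(intron)
    }
  }
  list(composite = paste(pieces, collapse = ""), exon_offsets = offsets)
}

.TISSUES <- c("root", "stem", "leaf", "PC-6DPA", "PC-16DPA", "PC-25DPA",
              "MG", "B", "B5", "B10")

#' Generate a synthetic gene-family dataset with ground truth
#'
#' Builds a fully self-contained toy dataset for the whole pipeline: a
#' random genome with planted family genes whose proteins carry exactly
#' the domain architecture their group requires, decoy candidates whose
#' J-domain hits cover less than the completeness threshold, tandem
#' duplicate pairs placed within the distance criterion, promoter windows
#' with planted cis-element copies, a tissue expression matrix built from
#' known archetypes, and a qPCR Ct table with known log2 fold changes.
#' Every output file parses with the package readers, and a truth table
#' covers every generated gene. The bundle is byte-identical for a fixed
#' seed.
#'
#' @param design A [simulation_design()].
#' @param dir Output directory (created if needed).
#' @return A list: `dir`, `paths` (named file paths), `truth` (list of
#'   data.frames `genes`, `pairs`, `motifs`), and `design`.
#' @export
simulate_family <- function(design = simulation_design(), dir = tempfile("sim")) {
  stopifnot(inherits(design, "simulation_design"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(design$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- jdomain_profile()
  motifs <- default_motifs()
  rates <- design$motif_rates

  gc <- design$group_counts
  n_fam <- sum(gc)
  n_all <- n_fam + design$n_decoys
  groups <- sample(rep(names(gc), gc))

  # proteins for family genes
  prot <- vector("list", n_all)
  for (i in seq_len(n_fam)) prot[[i]] <- .make_protein(groups[i], model)
  # tandem pairs: overwrite the partner's protein with a mutated copy of
  # its mate, both group C so architecture survives mutation checks
  c_idx <- which(groups == "C")
  pair_src <- integer(0)
  pair_dst <- integer(0)
  if (design$n_tandem_pairs > 0L) {
    picks <- sample(c_idx, 2L * design$n_tandem_pairs)
    pair_src <- picks[seq_len(design$n_tandem_pairs)]
    pair_dst <- picks[design$n_tandem_pairs + seq_len(design$n_tandem_pairs)]
    for (p in seq_len(design$n_tandem_pairs)) {
      src <- prot[[pair_src[p]]]
      hpd <- find_pattern(src$seq, "HPD")
      hpd <- hpd[hpd$start >= src$j_from & hpd$end <= src$j_to, , drop = FALSE]
      protect <- hpd$start[1L]:hpd$end[1L]
      repeat {
        mseq <- .mutate_protein(src$seq, 1 - design$tandem_identity,
                                protect = protect)
        zfm <- find_pattern(mseq, "CxxCxGxG")
        dom_end <- max(c(src$j_to, zfm$end))
        if (nrow(zfm) == 0L && (nchar(mseq) - dom_end) < 40L) break
      }
      prot[[pair_dst[p]]] <- list(seq = mseq, j_from = src$j_from,
                                  j_to = src$j_to, zf_repeats = 0L,
                                  has_hpd = TRUE, has_cterm = FALSE)
    }
  }
  for (i in n_fam + seq_len(design$n_decoys)) {
    prot[[i]] <- .make_decoy(model, stats::runif(1L, 0.3, 0.7))
  }

  # order genes along the genome: random, but tandem partners adjacent
  order_idx <- sample(setdiff(seq_len(n_all), pair_dst))
  for (p in seq_len(design$n_tandem_pairs)) {
    at <- match(pair_src[p], order_idx)
    order_idx <- append(order_idx, pair_dst[p], after = at)
  }
  # assign to chromosomes contiguously, never splitting a tandem pair
  per_chrom <- ceiling(n_all / design$n_chromosomes)
  chrom_of <- integer(n_all)
  cur <- 1L
  count <- 0L
  for (k in seq_along(order_idx)) {
    i <- order_idx[k]
    if (count >= per_chrom && cur < design$n_chromosomes &&
        !(i %in% pair_dst)) {
      cur <- cur + 1L
      count <- 0L
    }
    chrom_of[i] <- cur
    count <- count + 1L
  }

  # lay out chromosomes
  gene <- data.frame(idx = order_idx, stringsAsFactors = FALSE)
  gene$chromosome <- as.character(chrom_of[order_idx])
  gene$locus <- NA_character_
  gene$strand <- NA_character_
  gene$start <- NA_integer_
  gene$end <- NA_integer_
  gene$n_exons <- NA_integer_
  exon_tbl <- list()
  chrom_seq <- character(design$n_chromosomes)
  for (cc in seq_len(design$n_chromosomes)) {
    rows <- which(gene$chromosome == as.character(cc))
    pieces <- character(0)
    pos <- 0L
    num <- 0L
    for (k in rows) {
      i <- gene$idx[k]
      tandem_follow <- k > 1L && gene$idx[k] %in% pair_dst &&
        gene$idx[k - 1L] %in% pair_src
      gap <- if (tandem_follow) {
        sample(3200:6000, 1L)
      } else {
        sample(design$intergenic_bp[1L]:design$intergenic_bp[2L], 1L)
      }
      pieces <- c(pieces, .rand_nt(gap))
      pos <- pos + gap
      strand <- if (tandem_follow) {
        gene$strand[k - 1L]
      } else {
        sample(c("+", "-"), 1L, prob = c(0.7, 0.3))
      }
      cds <- paste0(paste(.CODON[strsplit(prot[[i]]$seq, "")[[1]]],
                          collapse = ""), "TAA")
      ne <- sample(1:6, 1L, prob = c(0.3, 0.2, 0.15, 0.15, 0.1, 0.1))
      gs <- .make_gene_structure(cds, ne)
      Lg <- nchar(gs$composite)
      seg <- if (strand == "+") gs$composite else
        reverse_complement(gs$composite)
      start <- pos + 1L
      end <- pos + Lg
      ex <- gs$exon_offsets
      gex <- if (strand == "+") {
        cbind(start = start + ex[, "start"] - 1L,
              end = start + ex[, "end"] - 1L)
      } else {
        m <- cbind(start = start + (Lg - ex[, "end"]),
                   end = start + (Lg - ex[, "start"]))
        m[order(m[, "start"]), , drop = FALSE]
      }
      num <- num + 1L
      gene$locus[k] <- sprintf("SIM%02dg%04d", cc, num * 10L)
      gene$strand[k] <- strand
      gene$start[k] <- start
      gene$end[k] <- end
      gene$n_exons[k] <- ne
      exon_tbl[[k]] <- gex
      pieces <- c(pieces, seg)
      pos <- pos + Lg
    }
    pieces <- c(pieces, .rand_nt(2000L))
    chrom_seq[cc] <- paste(pieces, collapse = "")
  }

  # plant promoter motifs by overwriting the upstream window in place
  motif_truth <- list()
  promoter_rec <- list()
  up <- design$upstream_bp
  for (k in seq_len(nrow(gene))) {
    w <- .rand_nt(up)
    placed <- matrix(0L, nrow = 0L, ncol = 2L)
    for (mn in motifs$name) {
      rate <- if (mn %in% names(rates)) rates[[mn]] else 0
      ncopy <- stats::rpois(1L, rate)
      L <- nchar(motifs$sequence[motifs$name == mn])
      tries <- 0L
      while (ncopy > 0L && tries < 200L) {
        at <- sample(up - L + 1L, 1L)
        if (!nrow(placed) ||
            all(at + L - 1L < placed[, 1L] | at > placed[, 2L])) {
          content <- motifs$sequence[motifs$name == mn]
          if (stats::runif(1L) < 0.5) content <- reverse_complement(content)
          substr(w, at, at + L - 1L) <- content
          placed <- rbind(placed, c(at, at + L - 1L))
          ncopy <- ncopy - 1L
        }
        tries <- tries + 1L
      }
    }
    cc <- as.integer(gene$chromosome[k])
    if (gene$strand[k] == "+") {
      from <- gene$start[k] - up
      substr(chrom_seq[cc], from, from + up - 1L) <- w
    } else {
      from <- gene$end[k] + 1L
      substr(chrom_seq[cc], from, from + up - 1L) <- reverse_complement(w)
    }
    # truth = occurrences actually present in the emitted window (planted
    # plus incidental background matches), counted naively
    cnt <- vapply(seq_len(nrow(motifs)), function(j) {
      .naive_motif_count(w, motifs$sequence[j])
    }, 0L)
    motif_truth[[k]] <- data.frame(locus = gene$locus[k],
                                   motif = motifs$name, copies = cnt,
                                   stringsAsFactors = FALSE)
    promoter_rec[[k]] <- data.frame(id = gene$locus[k],
                                    description = sprintf("promoter %dbp", up),
                                    residues = w, stringsAsFactors = FALSE)
  }

  # domain-hit table (external-scanner shape)
  L <- model$length
  hit_rows <- lapply(seq_len(nrow(gene)), function(k) {
    i <- gene$idx[k]
    p <- prot[[i]]
    fam <- i <= n_fam
    data.frame(protein_id = paste0(gene$locus[k], ".t1"),
               domain_id = model$name,
               e_value = 10^(-stats::runif(1L, 10, 30)),
               hmm_from = 1L,
               hmm_to = if (fam) L else p$hmm_to,
               ali_from = p$j_from, ali_to = p$j_to, hmm_len = L,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hit_rows)

  # expression archetypes for family genes
  fam_rows <- which(gene$idx <= n_fam)
  nT <- length(.TISSUES)
  props <- design$pattern_props
  n_by_pat <- floor(props * length(fam_rows))
  rem <- length(fam_rows) - sum(n_by_pat)
  if (rem > 0L) {
    extra <- order(props * length(fam_rows) - n_by_pat,
                   decreasing = TRUE)[seq_len(rem)]
    n_by_pat[extra] <- n_by_pat[extra] + 1L
  }
  pat_lab <- sample(rep(names(n_by_pat), n_by_pat))
  expr <- matrix(0, nrow = length(fam_rows), ncol = nT,
                 dimnames = list(gene$locus[fam_rows], .TISSUES))
  for (r in seq_along(fam_rows)) {
    expr[r, ] <- switch(pat_lab[r],
      barely_expressed = stats::runif(nT, 0, 0.8),
      constitutive = stats::runif(nT, 1.5, 80),
      tissue_specific = {
        v <- stats::runif(nT, 0, 0.5)
        v[sample(nT, sample(1:2, 1L))] <- stats::runif(1L, 10, 80)
        v
      },
      other = {
        v <- stats::runif(nT, 0, 0.5)
        on <- sample(nT, sample(3:(nT - 1L), 1L))
        v[on] <- stats::runif(length(on), 2, 50)
        v
      })
  }

  # qPCR Ct table with known log2 fold changes
  reps <- design$n_replicates
  l2f <- stats::runif(length(fam_rows), design$qpcr_log2fold_range[1L],
                      design$qpcr_log2fold_range[2L])
  ct_rows <- list()
  for (cond in c("control", "treatment")) {
    ct_rows[[cond]] <- data.frame(gene = "UBI", condition = cond,
                                  replicate = seq_len(reps),
                                  ct = 20 + stats::rnorm(reps, 0, design$ct_noise_sd),
                                  stringsAsFactors = FALSE)
  }
  base_ct <- stats::runif(length(fam_rows), 22, 28)
  for (r in seq_along(fam_rows)) {
    locus <- gene$locus[fam_rows[r]]
    for (cond in c("control", "treatment")) {
      mu <- if (cond == "control") base_ct[r] else base_ct[r] - l2f[r]
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        gene = locus, condition = cond, replicate = seq_len(reps),
        ct = mu + stats::rnorm(reps, 0, design$ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  ct_tab <- do.call(rbind, ct_rows)
  rownames(ct_tab) <- NULL

  # segmental-pair input file: family locus pairs on distinct chromosomes
  seg <- data.frame(locus_a = character(), locus_b = character(),
                    stringsAsFactors = FALSE)
  fam_loci <- gene$locus[fam_rows]
  fam_chrom <- gene$chromosome[fam_rows]
  for (s in seq_len(design$n_segmental_pairs)) {
    a <- sample(seq_along(fam_loci), 1L)
    bpool <- which(fam_chrom != fam_chrom[a])
    if (!length(bpool)) next
    b <- sample(bpool, 1L)
    seg <- rbind(seg, data.frame(locus_a = fam_loci[a],
                                 locus_b = fam_loci[b],
                                 stringsAsFactors = FALSE))
  }

  # ---- write the bundle ----
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff = file.path(dir, "genes.gff3"),
    proteins = file.path(dir, "proteins.fa"),
    domains = file.path(dir, "domains.tsv"),
    promoters = file.path(dir, "promoters.fa"),
    expression = file.path(dir, "expression.tsv"),
    qpcr = file.path(dir, "qpcr_ct.tsv"),
    segmental = file.path(dir, "segmental_pairs.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    truth_motifs = file.path(dir, "truth_motifs.tsv"))

  write_fasta(stats::setNames(chrom_seq, as.character(seq_len(design$n_chromosomes))),
              paths$genome)
  gff <- c("##gff-version 3")
  for (k in seq_len(nrow(gene))) {
    at <- function(type, s, e, id, parent = NULL) {
      attrs <- paste0("ID=", id)
      if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
      paste(gene$chromosome[k], "dnajfam-sim", type, s, e, ".",
            gene$strand[k], ".", attrs, sep = "\t")
    }
    mid <- paste0(gene$locus[k], ".t1")
    gff <- c(gff, at("gene", gene$start[k], gene$end[k], gene$locus[k]),
             at("mRNA", gene$start[k], gene$end[k], mid, gene$locus[k]))
    ex <- exon_tbl[[k]]
    for (e in seq_len(nrow(ex))) {
      gff <- c(gff, at("exon", ex[e, "start"], ex[e, "end"],
                       paste0(mid, ".e", e), mid))
    }
  }
  writeLines(gff, paths$gff)
  write_fasta(stats::setNames(
    vapply(gene$idx, function(i) prot[[i]]$seq, character(1L)),
    paste0(gene$locus, ".t1")), paths$proteins)
  write_domain_table(hits, paths$domains)
  write_fasta(do.call(rbind, promoter_rec), paths$promoters)
  expr_out <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                         stringsAsFactors = FALSE)
  write_tsv(expr_out, paths$expression)
  write_tsv(ct_tab, paths$qpcr)
  writeLines(c("# locus_a\tlocus_b",
               if (nrow(seg)) paste(seg$locus_a, seg$locus_b, sep = "\t")),
             paths$segmental)

  fam_of <- function(k) gene$idx[k] <= n_fam
  truth_genes <- data.frame(
    locus = gene$locus,
    protein_id = paste0(gene$locus, ".t1"),
    chromosome = gene$chromosome, start = gene$start, end = gene$end,
    strand = gene$strand,
    role = ifelse(vapply(seq_len(nrow(gene)), fam_of, TRUE),
                  "family", "decoy"),
    group = NA_character_, introns = gene$n_exons - 1L,
    pattern = NA_character_, log2_fold = NA_real_,
    stringsAsFactors = FALSE)
  truth_genes$group[gene$idx <= n_fam] <- groups[gene$idx[gene$idx <= n_fam]]
  truth_genes$pattern[fam_rows] <- pat_lab
  truth_genes$log2_fold[fam_rows] <- l2f
  truth_pairs <- if (design$n_tandem_pairs > 0L) {
    data.frame(
      locus_a = gene$locus[match(pair_src, gene$idx)],
      locus_b = gene$locus[match(pair_dst, gene$idx)],
      kind = "tandem",
      identity = vapply(seq_len(design$n_tandem_pairs), function(p) {
        a <- strsplit(prot[[pair_src[p]]]$seq, "")[[1]]
        b <- strsplit(prot[[pair_dst[p]]]$seq, "")[[1]]
        mean(a == b)
      }, 0),
      stringsAsFactors = FALSE)
  } else {
    data.frame(locus_a = character(), locus_b = character(),
               kind = character(), identity = numeric(),
               stringsAsFactors = FALSE)
  }
  truth_motifs <- do.call(rbind, motif_truth)
  write_tsv(truth_genes, paths$truth_genes)
  write_tsv(truth_pairs, paths$truth_pairs)
  write_tsv(truth_motifs, paths$truth_motifs)

  list(dir = dir, paths = paths,
       truth = list(genes = truth_genes, pairs = truth_pairs,
                    motifs = truth_motifs),
       design = design)
}
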