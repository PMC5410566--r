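#' Tandem-duplication criteria
#'
#' The three-part rule used to call tandem duplicates in gene-family
#' surveys: the genes lie within `max_distance_bp` of each other on one
#' chromosome (measured as the gap between the gene intervals, zero when
#' they overlap), the alignment covers *more than* `min_coverage` of the
#' longer gene, and the aligned region is *more than* `min_identity`
#' identical. Both fractions are strict inequalities. Optionally, at most
#' `max_intervening_genes` other family members may lie between the pair
#' (non-family genes are invisible to the pipeline).
#'
#' @param max_distance_bp Maximum inter-gene gap in bp.
#' @param min_coverage Coverage fraction of the longer sequence (strict >).
#' @param min_identity Identity fraction of the aligned region (strict >).
#' @param max_intervening_genes Maximum family members between the pair,
#'   or `NA` to disable the check.
#' @return A `duplication_criteria` list.
#' @export
duplication_criteria <- function(max_distance_bp = 100000L,
                                 min_coverage = 0.70,
                                 min_identity = 0.70,
                                 max_intervening_genes = 1L) {
  stopifnot(max_distance_bp > 0, min_coverage > 0, min_coverage <= 1,
            min_identity > 0, min_identity <= 1)
  structure(list(max_distance_bp = as.integer(max_distance_bp),
                 min_coverage = min_coverage, min_identity = min_identity,
                 max_intervening_genes = max_intervening_genes),
            class = "duplication_criteria")
}

#' Chromosome distribution of family members
#'
#' @param members Data.frame with a `chromosome` column (`"00"` for
#'   unplaced members).
#' @return Named integer vector of member counts per chromosome label;
#'   counts sum to the member count.
#' @export
chromosome_distribution <- function(members) {
  if (!nrow(members)) return(stats::setNames(integer(), character()))
  tab <- table(members$chromosome)
  lev <- names(tab)
  num <- suppressWarnings(as.integer(lev))
  ord <- order(is.na(num), num, lev)
  stats::setNames(as.integer(tab[ord]), lev[ord])
}

#' Tandem-duplication candidate pairs by distance
#'
#' All unordered same-chromosome pairs of placed members whose inter-gene
#' gap (end of the upstream gene to start of the downstream gene; 0 when
#' the intervals overlap) is at most the distance criterion, and with at
#' most the allowed number of other family members between them. Output is
#' invariant under permutation of the input, with each pair reported once
#' in canonical (name-sorted) order.
#'
#' @param members Data.frame with columns `gene_name`, `chromosome`,
#'   `start`, `end`.
#' @param criteria A [duplication_criteria()].
#' @return Data.frame: `gene_a`, `gene_b`, `chromosome`, `distance_bp`,
#'   `intervening`.
#' @export
tandem_candidates <- function(members, criteria = duplication_criteria()) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      chromosome = character(), distance_bp = integer(),
                      intervening = integer(), stringsAsFactors = FALSE)
  placed <- members[members$chromosome != "00" & !is.na(members$start), ,
                    drop = FALSE]
  out <- list(empty)
  for (chrom in unique(placed$chromosome)) {
    cm <- placed[placed$chromosome == chrom, , drop = FALSE]
    cm <- cm[order(cm$start, cm$end), , drop = FALSE]
    n <- nrow(cm)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        gap <- max(0L, cm$start[j] - cm$end[i])
        if (gap > criteria$max_distance_bp) next
        intervening <- j - i - 1L
        if (!is.na(criteria$max_intervening_genes) &&
            intervening > criteria$max_intervening_genes) next
        nm <- sort(c(cm$gene_name[i], cm$gene_name[j]))
        out[[length(out) + 1L]] <- data.frame(
          gene_a = nm[1L], gene_b = nm[2L], chromosome = chrom,
          distance_bp = as.integer(gap), intervening = intervening,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$gene_a, res$gene_b), , drop = FALSE]
}

#' Global (Needleman-Wunsch) alignment with coverage and identity
#'
#' Optimal global alignment under a linear gap penalty, with the two
#' summary fractions used by the tandem-duplication rule:
#' `coverage_of_longer`, the fraction of the longer sequence's residues
#' sitting in columns paired with a residue of the other sequence, and
#' `identity_of_aligned`, the fraction of those paired columns that are
#' identical.
#'
#' @param a,b Sequence strings (protein or nucleotide).
#' @param match,mismatch Scores used when `submat` is `NULL`.
#' @param gap Per-position gap penalty (negative).
#' @param submat Optional substitution matrix with residue dimnames
#'   (e.g. a BLOSUM table); identity is always exact residue equality.
#' @return A list: `score`, `aligned_pairs`, `identical`,
#'   `coverage_of_longer`, `identity_of_aligned`, and `alignment` (the two
#'   gapped strings).
#' @examples
#' global_align("ACGT", "ACGA")$identity_of_aligned  # 0.75
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2,
                         submat = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  H[1L, ] <- gap * (0:m)
  H[, 1L] <- gap * (0:n)
  j0 <- 0:m
  for (i in seq_len(n)) {
    subs <- if (is.null(submat)) {
      ifelse(bv == av[i], match, mismatch)
    } else {
      submat[av[i], bv]
    }
    prev <- H[i, ]
    M <- pmax(prev[1:m] + subs, prev[2:(m + 1L)] + gap)
    cand <- c(gap * i, M)
    H[i + 1L, ] <- gap * j0 + cummax(cand - gap * j0)
  }
  # traceback (prefer diagonal, then up, then left)
  eps <- 1e-9
  i <- n
  j <- m
  ga <- character(0)
  gb <- character(0)
  while (i > 0L || j > 0L) {
    s <- if (i > 0L && j > 0L) {
      if (is.null(submat)) {
        if (av[i] == bv[j]) match else mismatch
      } else submat[av[i], bv[j]]
    } else NA_real_
    if (i > 0L && j > 0L && abs(H[i + 1L, j + 1L] - (H[i, j] + s)) < eps) {
      ga <- c(av[i], ga); gb <- c(bv[j], gb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && abs(H[i + 1L, j + 1L] - (H[i, j + 1L] + gap)) < eps) {
      ga <- c(av[i], ga); gb <- c("-", gb); i <- i - 1L
    } else {
      ga <- c("-", ga); gb <- c(bv[j], gb); j <- j - 1L
    }
  }
  paired <- ga != "-" & gb != "-"
  aligned_pairs <- sum(paired)
  identical_cols <- sum(paired & ga == gb)
  list(score = H[n + 1L, m + 1L],
       aligned_pairs = aligned_pairs,
       identical = identical_cols,
       coverage_of_longer = aligned_pairs / max(n, m),
       identity_of_aligned = if (aligned_pairs > 0) {
         identical_cols / aligned_pairs
       } else 0,
       alignment = c(a = paste(ga, collapse = ""),
                     b = paste(gb, collapse = "")))
}

#' Call tandem duplications among candidate pairs
#'
#' Aligns each distance candidate (see [tandem_candidates()]) and keeps
#' pairs whose alignment coverage of the longer sequence and identity of
#' the aligned region both *exceed* the criteria thresholds (strict
#' inequalities). Alignment is on protein sequences by default; pass
#' nucleotide sequences and scoring to work at the gene level.
#'
#' @param members Data.frame with `gene_name`, `chromosome`, `start`,
#'   `end`.
#' @param sequences Named character vector of sequences, names matching
#'   `gene_name`.
#' @param criteria A [duplication_criteria()].
#' @param ... Scoring arguments passed to [global_align()].
#' @return Data.frame of calls: `gene_a`, `gene_b`, `kind`, `chromosome`,
#'   `distance_bp`, `coverage`, `identity`.
#' @export
call_tandem <- function(members, sequences,
                        criteria = duplication_criteria(), ...) {
  cand <- tandem_candidates(members, criteria)
  out <- data.frame(gene_a = character(), gene_b = character(),
                    kind = character(), chromosome = character(),
                    distance_bp = integer(), coverage = numeric(),
                    identity = numeric(), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cand))) {
    pair <- c(cand$gene_a[k], cand$gene_b[k])
    missing <- pair[!(pair %in% names(sequences))]
    if (length(missing)) {
      stop("no sequence available for candidate gene '", missing[1L], "'")
    }
    al <- global_align(sequences[[pair[1L]]], sequences[[pair[2L]]], ...)
    if (al$coverage_of_longer > criteria$min_coverage &&
        al$identity_of_aligned > criteria$min_identity) {
      out <- rbind(out, data.frame(
        gene_a = pair[1L], gene_b = pair[2L], kind = "tandem",
        chromosome = cand$chromosome[k], distance_bp = cand$distance_bp[k],
        coverage = al$coverage_of_longer, identity = al$identity_of_aligned,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Read precomputed segmental-duplication (synteny) pairs
#'
#' Ingests a two-column TSV of locus pairs from an external synteny
#' resource and maps them onto family member names. Lines naming a locus
#' absent from the family are skipped with a warning; this module does not
#' discover synteny itself.
#'
#' @param path Path to a two-column TSV (`#` comment lines allowed).
#' @param members Data.frame with `gene_name` and `locus` columns.
#' @return Data.frame of calls: `gene_a`, `gene_b`, `kind = "segmental"`.
#' @export
read_segmental_pairs <- function(path, members) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      kind = character(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  f <- strsplit(trimws(lines), "\\s+")
  out <- empty
  for (x in f) {
    idx <- match(x[1:2], members$locus)
    if (anyNA(idx)) {
      warning("unknown locus in segmental pair file: ",
              paste(x[1:2][is.na(idx)], collapse = ", "), " (line skipped)")
      next
    }
    nm <- sort(members$gene_name[idx])
    out <- rbind(out, data.frame(gene_a = nm[1L], gene_b = nm[2L],
                                 kind = "segmental", stringsAsFactors = FALSE))
  }
  out
}
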