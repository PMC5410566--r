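# J-domain consensus used by the bundled profile model. ~70 residues,
# modelled on the canonical bacterial DnaJ J-domain, with the invariant
# HPD tripeptide roughly one third in from the helix-II end.
.JDOMAIN_CONSENSUS <- paste0(
  "DYYEILGVSKTAEEREIRKAYKRLAMKYHPDRNQGDKEAEAKFKEIKEAYEVLTDSQKRAAYDQYGHAAF"
)

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Find occurrences of a simple residue pattern
#'
#' Locates all non-overlapping, left-to-right occurrences of a motif
#' pattern in a protein sequence. The pattern uses residue letters plus
#' `x`, which matches any residue (e.g. the zinc-finger repeat
#' `"CxxCxGxG"`, or the literal `"HPD"`).
#'
#' @param seq A protein sequence string.
#' @param pattern Pattern string over residue letters and `x`.
#' @return A data.frame with columns `start`, `end` (1-based inclusive);
#'   zero rows when there is no match.
#' @examples
#' find_pattern("AHPDA", "HPD")
#' find_pattern("CAACAGAG", "CxxCxGxG")
#' @export
find_pattern <- function(seq, pattern) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(pattern))
  if (!grepl("^[A-WYZx]+$", pattern)) {
    stop("pattern may contain only residue letters and 'x'")
  }
  rx <- gsub("x", ".", pattern, fixed = TRUE)
  m <- gregexpr(rx, seq)[[1]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Build an ungapped profile model from a consensus sequence
#'
#' Constructs a simple position-specific scoring model: at each column the
#' consensus residue has emission probability `p_consensus` and the
#' remaining 19 residues share the rest uniformly; scores are log2-odds
#' against a uniform background. The default score threshold is half the
#' maximum attainable score, which on random background keeps the false
#' positive rate far below 1% per 200 residues (the consensus scores
#' roughly +3.3 per column while random sequence averages about -1).
#'
#' @param consensus Consensus residue string.
#' @param name Model name used as the `domain_id` of reported hits.
#' @param p_consensus Per-column emission probability of the consensus
#'   residue.
#' @param threshold_frac Score threshold as a fraction of the maximum
#'   (consensus) score.
#' @return A `profile_model` list: `name`, `length`, `consensus`, `scores`
#'   (20 x L log2-odds matrix), `score_threshold`.
#' @export
profile_model <- function(consensus, name = "PF00226",
                          p_consensus = 0.6, threshold_frac = 0.5) {
  stopifnot(nchar(consensus) >= 1L, p_consensus > 0.05, p_consensus < 1)
  cons <- strsplit(toupper(consensus), "")[[1]]
  if (!all(cons %in% .AA20)) stop("consensus must use the 20 standard residues")
  L <- length(cons)
  p_other <- (1 - p_consensus) / 19
  scores <- matrix(log2(p_other / 0.05), nrow = 20L, ncol = L,
                   dimnames = list(.AA20, NULL))
  scores[cbind(match(cons, .AA20), seq_len(L))] <- log2(p_consensus / 0.05)
  max_score <- L * log2(p_consensus / 0.05)
  structure(list(name = name, length = L, consensus = consensus,
                 scores = scores,
                 score_threshold = threshold_frac * max_score),
            class = "profile_model")
}

#' The bundled J-domain profile model
#'
#' A ~70-column ungapped profile built from a canonical J-domain consensus
#' (HPD tripeptide included), used by the internal scanner and by the
#' synthetic-data generator. Real-data users typically bypass it by
#' supplying an external per-domain hit table instead.
#'
#' @return A `profile_model` (see [profile_model()]).
#' @export
jdomain_profile <- function() {
  profile_model(.JDOMAIN_CONSENSUS, name = "PF00226")
}

#' Scan a protein with an ungapped profile model
#'
#' Slides the profile along the sequence, scoring each placement as the sum
#' of per-column log2-odds. Placements scoring at least the model threshold
#' are reported as hits with full profile coverage; overlapping placements
#' are merged keeping the best-scoring one. A sequence shorter than the
#' model yields no hits.
#'
#' @param seq Protein sequence string.
#' @param model A [profile_model()].
#' @return A data.frame of hits: `domain_id`, `ali_from`, `ali_to`,
#'   `score`, `hmm_from`, `hmm_to`, `hmm_len`, `profile_cov`, `e_value`.
#'   The `e_value` column is a nominal placeholder (the scanner thresholds
#'   on score, not on an E-value theory) set low enough to pass downstream
#'   E-value screens.
#' @export
scan_profile <- function(seq, model) {
  stopifnot(inherits(model, "profile_model"))
  L <- model$length
  empty <- data.frame(domain_id = character(), ali_from = integer(),
                      ali_to = integer(), score = numeric(),
                      hmm_from = integer(), hmm_to = integer(),
                      hmm_len = integer(), profile_cov = numeric(),
                      e_value = numeric())
  n <- nchar(seq)
  if (n < L) return(empty)
  idx <- match(strsplit(toupper(seq), "")[[1]], .AA20)
  if (anyNA(idx)) stop("sequence contains non-standard residues")
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    sc <- sc + model$scores[, j][idx[j:(j + nw - 1L)]]
  }
  pass <- which(sc >= model$score_threshold)
  if (!length(pass)) return(empty)
  # merge runs of overlapping passing windows, keep the best per run
  grp <- cumsum(c(TRUE, diff(pass) >= L))
  starts <- vapply(split(pass, grp), function(w) w[which.max(sc[w])], 0L)
  data.frame(domain_id = model$name, ali_from = as.integer(starts),
             ali_to = as.integer(starts) + L - 1L,
             score = sc[starts], hmm_from = 1L, hmm_to = L, hmm_len = L,
             profile_cov = 1.0, e_value = 1e-12, row.names = NULL)
}

#' Architecture assembly configuration
#'
#' Thresholds used when turning raw domain evidence into a per-protein
#' architecture: the E-value screen for J-domain hits, the profile-coverage
#' fraction defining a *complete* J-domain, the minimum number of CxxCxGxG
#' repeats that constitutes a zinc-finger domain, and the minimum number of
#' residues downstream of the last domain that counts as a conserved
#' C-terminal extent.
#'
#' @param e_threshold J-domain hits must have E-value strictly below this.
#' @param cov_complete Minimum profile coverage for a complete J-domain.
#' @param zf_min_repeats Minimum CxxCxGxG repeat count for zinc-finger
#'   presence.
#' @param cterm_min Minimum residues after the last domain for C-terminal
#'   presence (an operational convention, not a published rule).
#' @param jdomain_id Domain id recognised as the J-domain.
#' @return A named list of class `arch_config`.
#' @export
arch_config <- function(e_threshold = 1e-5, cov_complete = 0.8,
                        zf_min_repeats = 2L, cterm_min = 40L,
                        jdomain_id = "PF00226") {
  stopifnot(e_threshold > 0, cov_complete > 0, cov_complete <= 1,
            zf_min_repeats >= 1L, cterm_min >= 0L)
  structure(list(e_threshold = e_threshold, cov_complete = cov_complete,
                 zf_min_repeats = as.integer(zf_min_repeats),
                 cterm_min = as.integer(cterm_min), jdomain_id = jdomain_id),
            class = "arch_config")
}

#' Assemble a per-protein domain architecture
#'
#' Combines J-domain hits (internal scan or external table) with pattern
#' evidence into one architecture record: J-domain spans passing the
#' E-value screen, J-domain completeness (profile coverage), presence of
#' the HPD tripeptide *inside* a J-domain span, CxxCxGxG zinc-finger repeat
#' count, and presence of a C-terminal extent downstream of the last
#' annotated domain.
#'
#' @param protein_id Protein identifier.
#' @param residues Protein sequence string.
#' @param hits Data.frame of domain hits for this protein (columns
#'   `domain_id`, `ali_from`, `ali_to`, `e_value`, `profile_cov`).
#' @param config An [arch_config()].
#' @return One-row data.frame: `protein_id`, `length`, `n_j`, `j_complete`,
#'   `has_hpd`, `zf_repeats`, `has_zinc_finger`, `has_cterm`, plus a
#'   list-column `j_domains` of (start, end) matrices.
#' @export
assemble_architecture <- function(protein_id, residues, hits,
                                  config = arch_config()) {
  stopifnot(inherits(config, "arch_config"))
  len <- nchar(residues)
  if (nrow(hits) && any(hits$ali_to > len | hits$ali_from < 1L)) {
    stop("domain hit coordinates beyond protein length for '", protein_id, "'")
  }
  jh <- hits[hits$domain_id == config$jdomain_id &
               hits$e_value < config$e_threshold, , drop = FALSE]
  j_spans <- cbind(start = jh$ali_from, end = jh$ali_to)
  j_complete <- nrow(jh) > 0L && any(jh$profile_cov >= config$cov_complete)
  hpd <- find_pattern(residues, "HPD")
  has_hpd <- FALSE
  if (nrow(hpd) && nrow(jh)) {
    for (k in seq_len(nrow(hpd))) {
      if (any(hpd$start[k] >= jh$ali_from & hpd$end[k] <= jh$ali_to)) {
        has_hpd <- TRUE
        break
      }
    }
  }
  zf <- find_pattern(residues, "CxxCxGxG")
  zf_repeats <- nrow(zf)
  domain_ends <- c(jh$ali_to, zf$end)
  has_cterm <- length(domain_ends) > 0L &&
    (len - max(domain_ends)) >= config$cterm_min
  out <- data.frame(protein_id = protein_id, length = len,
                    n_j = nrow(jh), j_complete = j_complete,
                    has_hpd = has_hpd, zf_repeats = zf_repeats,
                    has_zinc_finger = zf_repeats >= config$zf_min_repeats,
                    has_cterm = has_cterm, stringsAsFactors = FALSE)
  out$j_domains <- list(j_spans)
  out
}

#' Assemble architectures for a whole proteome
#'
#' @param proteins Data.frame from [read_fasta()] (`id`, `residues`).
#' @param hits Data.frame of domain hits (`protein_id`, `domain_id`,
#'   `ali_from`, `ali_to`, `e_value`, `profile_cov`), e.g. from
#'   [read_domain_table()] or [scan_profile()].
#' @param config An [arch_config()].
#' @return Row-bound architecture records (see [assemble_architecture()]).
#' @export
assemble_architectures <- function(proteins, hits, config = arch_config()) {
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    h <- hits[hits$protein_id == proteins$id[i], , drop = FALSE]
    assemble_architecture(proteins$id[i], proteins$residues[i], h, config)
  })
  do.call(rbind, rows)
}
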