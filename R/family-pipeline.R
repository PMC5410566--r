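#' Filter candidates on J-domain completeness
#'
#' Splits candidate architectures into those with a complete J-domain
#' (retained family members) and those without (removed). This mirrors the
#' standard family-survey step in which candidates passing the initial
#' E-value screen are discarded when their J-domain evidence covers too
#' little of the profile.
#'
#' @param architectures Architecture data.frame (see
#'   [assemble_architectures()]).
#' @return A list with elements `retained` and `removed`; their row counts
#'   always sum to the input's.
#' @export
filter_complete <- function(architectures) {
  keep <- architectures$j_complete
  list(retained = architectures[keep, , drop = FALSE],
       removed = architectures[!keep, , drop = FALSE])
}

#' Classify a domain architecture into groups A-E
#'
#' Five-group scheme over (HPD, zinc finger, C-terminal extent), applied in
#' a fixed decision order: proteins whose J-domain lacks the HPD tripeptide
#' are J-like proteins (group E) regardless of other domains; otherwise
#' zinc finger + C-terminal gives A, zinc finger alone gives D, C-terminal
#' alone gives B, and a bare J-domain gives C. The HPD test comes first
#' because J-like proteins may still carry zinc fingers or long tails.
#'
#' @param has_hpd,has_zinc_finger,has_cterm Logical vectors (recycled to a
#'   common length).
#' @return A character vector of group labels in `c("A","B","C","D","E")`.
#' @examples
#' classify_protein(TRUE, TRUE, TRUE)    # "A"
#' classify_protein(FALSE, TRUE, TRUE)   # "E"
#' @export
classify_protein <- function(has_hpd, has_zinc_finger, has_cterm) {
  n <- max(length(has_hpd), length(has_zinc_finger), length(has_cterm))
  has_hpd <- rep_len(as.logical(has_hpd), n)
  has_zinc_finger <- rep_len(as.logical(has_zinc_finger), n)
  has_cterm <- rep_len(as.logical(has_cterm), n)
  out <- ifelse(!has_hpd, "E",
         ifelse(has_zinc_finger & has_cterm, "A",
         ifelse(has_zinc_finger, "D",
         ifelse(has_cterm, "B", "C"))))
  out
}

#' Classify assembled architectures
#'
#' Adds a `group` column to an architecture table. Architectures without
#' any J-domain hit are an error: they should have been removed upstream.
#'
#' @param architectures Architecture data.frame.
#' @return The input with a `group` column appended.
#' @export
classify_architectures <- function(architectures) {
  if (any(architectures$n_j == 0L)) {
    bad <- architectures$protein_id[architectures$n_j == 0L][1L]
    stop("cannot classify '", bad, "': no J-domain evidence ",
         "(should have been filtered)")
  }
  architectures$group <- classify_protein(architectures$has_hpd,
                                          architectures$has_zinc_finger,
                                          architectures$has_cterm)
  architectures
}

#' Assign chromosome-ordered family names
#'
#' Orders members by chromosome (numeric ascending) then start coordinate,
#' appends unplaced members (chromosome `"00"`) ordered by locus id, and
#' names each member `prefix` plus a zero-padded rank (width at least 2,
#' growing with family size). Naming is order-independent: permuting the
#' input yields the same name for each locus.
#'
#' @param members Data.frame with columns `locus`, `chromosome`, `start`
#'   (start may be `NA` for unplaced members).
#' @param prefix Name prefix (e.g. `"CaDnaJ"`).
#' @return The input, reordered, with a `gene_name` column prepended.
#' @export
assign_names <- function(members, prefix = "CaDnaJ") {
  stopifnot(all(c("locus", "chromosome", "start") %in% names(members)))
  if (anyDuplicated(members$locus)) {
    stop("duplicate locus id: '", members$locus[duplicated(members$locus)][1L], "'")
  }
  placed <- members$chromosome != "00" & !is.na(members$start)
  chr_num <- suppressWarnings(as.integer(members$chromosome))
  ord <- c(which(placed)[order(chr_num[placed], members$start[placed])],
           which(!placed)[order(members$locus[!placed])])
  members <- members[ord, , drop = FALSE]
  n <- nrow(members)
  width <- max(2L, nchar(as.character(n)))
  members <- cbind(gene_name = sprintf("%s%0*d", prefix, width, seq_len(n)),
                   members, stringsAsFactors = FALSE)
  rownames(members) <- NULL
  members
}

#' Tally family members per architecture group
#'
#' @param groups Character vector of group labels (or a data.frame with a
#'   `group` column).
#' @return Named integer vector over A-E; the counts always sum to the
#'   number of members.
#' @export
group_census <- function(groups) {
  if (is.data.frame(groups)) groups <- groups$group
  out <- table(factor(groups, levels = c("A", "B", "C", "D", "E")))
  stats::setNames(as.integer(out), names(out))
}
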