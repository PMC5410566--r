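#' Average residue mass table
#'
#' Loads the bundled average (not monoisotopic) residue masses, ProtParam
#' convention. The table is a plain TSV under `extdata` so alternative mass
#' sets can be dropped in.
#'
#' @param path Optional path to a replacement TSV (`residue`, `mass`).
#' @return A list with `residues` (named numeric, Da) and `water` (Da).
#' @export
average_masses <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mass_table.tsv", package = "dnajfam",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- stats::setNames(tab$mass, tab$residue)
  if (any(m <= 0)) stop("masses must be positive")
  list(residues = m[names(m) != "water"], water = unname(m[["water"]]))
}

#' Side-chain and termini pKa table
#'
#' Loads the bundled Bjellqvist pKa set (the values behind ProtParam-style
#' theoretical pI). Editable TSV resource; e.g. an EMBOSS set is a drop-in
#' replacement.
#'
#' @param path Optional path to a replacement TSV (`group`, `pka`, `sign`).
#' @return Data.frame with columns `group`, `pka`, `sign` (+1 basic,
#'   -1 acidic).
#' @export
pka_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pka_table.tsv", package = "dnajfam",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (any(tab$pka <= 0 | tab$pka >= 14)) stop("pKa values must lie in (0, 14)")
  tab
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water. Strictly additive:
#' `mw(ab) == mw(a) + mw(b) - water`. Ambiguous residues (X, B, Z, U) are
#' rejected rather than approximated.
#'
#' @param seq Protein sequence string.
#' @param masses A mass table from [average_masses()].
#' @return Molecular weight in Daltons.
#' @examples
#' molecular_weight("G")  # glycine residue + water, ~75.07 Da
#' @export
molecular_weight <- function(seq, masses = average_masses()) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("sequence must be a non-empty string")
  }
  ch <- strsplit(toupper(seq), "")[[1]]
  m <- masses$residues[ch]
  if (anyNA(m)) {
    stop("unknown residue '", ch[which(is.na(m))[1L]], "' in sequence")
  }
  sum(m) + masses$water
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over ionisable side chains and the two
#' termini: basic groups contribute `1/(1+10^(pH-pKa))`, acidic groups
#' `-1/(1+10^(pKa-pH))`. Strictly decreasing in pH, which guarantees a
#' unique isoelectric point.
#'
#' @param seq Protein sequence string.
#' @param pH pH value (vectorised).
#' @param pkas A pKa table from [pka_table()].
#' @return Net charge (same length as `pH`).
#' @export
net_charge <- function(seq, pH, pkas = pka_table()) {
  ch <- strsplit(toupper(seq), "")[[1]]
  counts <- stats::setNames(rep(1L, nrow(pkas)), pkas$group)
  for (g in pkas$group) {
    if (nchar(g) == 1L) counts[[g]] <- sum(ch == g)
  }
  vapply(pH, function(p) {
    q <- 0
    for (i in seq_len(nrow(pkas))) {
      n <- counts[[pkas$group[i]]]
      if (n == 0L) next
      if (pkas$sign[i] > 0) {
        q <- q + n / (1 + 10^(p - pkas$pka[i]))
      } else {
        q <- q - n / (1 + 10^(pkas$pka[i] - p))
      }
    }
    q
  }, numeric(1L))
}

#' Theoretical isoelectric point
#'
#' The unique pH in [0, 14] at which [net_charge()] is zero, found by
#' bisection. Monotonicity of the charge curve guarantees existence and
#' uniqueness of the root.
#'
#' @param seq Protein sequence string.
#' @param pkas A pKa table from [pka_table()].
#' @param tol Bisection tolerance on pH.
#' @return The pI as a numeric pH value.
#' @export
isoelectric_point <- function(seq, pkas = pka_table(), tol = 1e-3) {
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, pkas) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Intron count of a gene model
#'
#' @param exons A two-column (start, end) exon matrix, or a gene record
#'   row with an `exons` entry.
#' @return `max(0, number of exons - 1)`.
#' @export
intron_count <- function(exons) {
  if (is.data.frame(exons) && "exons" %in% names(exons)) {
    return(vapply(exons$exons, function(e) max(0L, nrow(e) - 1L), 0L))
  }
  max(0L, nrow(exons) - 1L)
}

#' Summary statistics of a family catalog
#'
#' Min/max of protein length, molecular weight and pI (with the gene
#' attaining each extremum), the intron-count histogram, and per-chromosome
#' member counts.
#'
#' @param catalog A catalog data.frame (see [load_catalog()]) with columns
#'   `gene_name`, `chromosome`, `size_aa`, `mw_da`, `pi`, `introns`.
#' @return A list: `size`, `mw`, `pi` (each `list(min, min_gene, max,
#'   max_gene)`), `intron_hist` (named counts), `chromosomes` (named
#'   counts).
#' @export
catalog_stats <- function(catalog) {
  if (!nrow(catalog)) stop("empty catalog")
  extremum <- function(x) {
    list(min = min(x), min_gene = catalog$gene_name[which.min(x)],
         max = max(x), max_gene = catalog$gene_name[which.max(x)])
  }
  hist <- table(catalog$introns)
  list(size = extremum(catalog$size_aa),
       mw = extremum(catalog$mw_da),
       pi = extremum(catalog$pi),
       intron_hist = stats::setNames(as.integer(hist), names(hist)),
       chromosomes = chromosome_distribution(catalog))
}
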