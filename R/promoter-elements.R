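#' Bundled cis-element motif table
#'
#' Ten stress- and hormone-responsive promoter elements with IUPAC
#' consensi: the heat-shock element (HSE) core plus TC-rich, LTR, MBS,
#' ABRE, TCA-element, TGA-element, GARE-motif, CGTCA-motif and ERE. The
#' table is editable data (`extdata/motif_table.tsv`): occurrence tallies
#' are meaningful only relative to the motif library in use.
#'
#' @param path Optional path to a replacement TSV (`name`, `sequence`,
#'   `category`, `response`).
#' @return Data.frame of motif definitions.
#' @export
default_motifs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motif_table.tsv", package = "dnajfam",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$sequence <- toupper(tab$sequence)
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", tab$sequence)
  if (any(bad)) stop("motif '", tab$name[bad][1L], "' is not IUPAC nucleotide")
  if (anyDuplicated(tab$name)) stop("duplicate motif name")
  tab
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Nucleotide string (ACGTN and IUPAC ambiguity codes).
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "")[[1]]), collapse = "")
         }, character(1L), USE.NAMES = FALSE))
}

#' Extract promoter windows upstream of genes
#'
#' For a plus-strand gene the window is `[start - upstream_bp, start - 1]`;
#' for a minus-strand gene it is the reverse complement of
#' `[end + 1, end + upstream_bp]`. Windows are truncated at contig edges
#' (the realised length is recorded); the transcription start base itself
#' is excluded.
#'
#' @param genome Data.frame from [read_fasta()] (nucleotide records).
#' @param genes Data.frame with `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @param upstream_bp Window length in bp (default 1500).
#' @return A data.frame of promoter records: `id` (the gene id),
#'   `description`, `residues`, `length`.
#' @export
extract_promoters <- function(genome, genes, upstream_bp = 1500L) {
  stopifnot(upstream_bp > 0)
  out <- vector("list", nrow(genes))
  keep <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    k <- match(g$chromosome, genome$id)
    if (is.na(k)) stop("gene '", g$gene_id, "' lies on missing contig '",
                       g$chromosome, "'")
    contig <- genome$residues[[k]]
    clen <- nchar(contig)
    if (g$strand == "+") {
      from <- max(1L, g$start - upstream_bp)
      to <- g$start - 1L
      if (to < from) next
      win <- substr(contig, from, to)
    } else {
      from <- g$end + 1L
      to <- min(clen, g$end + upstream_bp)
      if (to < from) next
      win <- reverse_complement(substr(contig, from, to))
    }
    keep[i] <- TRUE
    out[[i]] <- data.frame(id = g$gene_id,
                           description = sprintf("promoter %dbp", nchar(win)),
                           residues = win, length = nchar(win),
                           stringsAsFactors = FALSE)
  }
  dropped <- genes$gene_id[!keep]
  if (length(dropped)) {
    warning("no promoter window for gene(s) at contig edge: ",
            paste(dropped, collapse = ", "))
  }
  res <- do.call(rbind, out[keep])
  if (is.null(res)) {
    res <- data.frame(id = character(), description = character(),
                      residues = character(), length = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Scan promoter windows for cis-element motifs
#'
#' Reports every position (overlaps included) where an IUPAC motif matches
#' a promoter window: the forward strand always, and the reverse strand
#' when `both_strands` is `TRUE`. Reverse-strand hits are reported in
#' forward coordinates with strand `"-"`, and `matched_seq` is given in
#' strand orientation. Matching uses [Biostrings::matchPattern()] with the
#' subject taken literally and the pattern interpreted as IUPAC.
#'
#' @param promoters Data.frame of promoter records (see
#'   [extract_promoters()]; any data.frame with `id` and `residues`
#'   works).
#' @param motifs Motif table (see [default_motifs()]).
#' @param both_strands Scan the reverse strand too?
#' @return Data.frame of hits: `gene`, `motif`, `start`, `end`, `strand`,
#'   `matched_seq` (1-based inclusive, promoter-window coordinates).
#' @export
scan_motifs <- function(promoters, motifs = default_motifs(),
                        both_strands = TRUE) {
  rows <- list(data.frame(gene = character(), motif = character(),
                          start = integer(), end = integer(),
                          strand = character(), matched_seq = character(),
                          stringsAsFactors = FALSE))
  for (i in seq_len(nrow(promoters))) {
    subject <- Biostrings::DNAString(promoters$residues[[i]])
    for (k in seq_len(nrow(motifs))) {
      pat <- Biostrings::DNAString(motifs$sequence[[k]])
      fwd <- Biostrings::matchPattern(pat, subject, fixed = "subject")
      if (length(fwd)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = promoters$id[[i]], motif = motifs$name[[k]],
          start = BiocGenerics::start(fwd), end = BiocGenerics::end(fwd),
          strand = "+", matched_seq = as.character(fwd),
          stringsAsFactors = FALSE)
      }
      if (both_strands) {
        rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                        subject, fixed = "subject")
        if (length(rev)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = promoters$id[[i]], motif = motifs$name[[k]],
            start = BiocGenerics::start(rev), end = BiocGenerics::end(rev),
            strand = "-",
            matched_seq = reverse_complement(as.character(rev)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$gene, out$start, out$motif), , drop = FALSE]
}

#' Census of cis-element hits
#'
#' Per-motif totals (occurrences and number of genes carrying at least one
#' occurrence) and per-gene totals (distinct element types and total
#' elements). Totals are conserved: summing per-gene elements recovers the
#' overall hit count.
#'
#' @param hits Hit table from [scan_motifs()].
#' @param genes Character vector of all gene ids surveyed (so genes with
#'   zero hits appear in the per-gene table).
#' @param motifs Motif table defining the rows of the per-motif census.
#' @return A list with data.frames `per_motif` (`motif`, `total_hits`,
#'   `genes_with_hit`) and `per_gene` (`gene`, `n_types`, `n_elements`).
#' @export
element_census <- function(hits, genes, motifs = default_motifs()) {
  per_motif <- data.frame(
    motif = motifs$name,
    total_hits = vapply(motifs$name,
                        function(m) sum(hits$motif == m), 0L),
    genes_with_hit = vapply(motifs$name, function(m) {
      length(unique(hits$gene[hits$motif == m]))
    }, 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  per_gene <- data.frame(
    gene = genes,
    n_types = vapply(genes, function(g) {
      length(unique(hits$motif[hits$gene == g]))
    }, 0L),
    n_elements = vapply(genes, function(g) sum(hits$gene == g), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_motif = per_motif, per_gene = per_gene)
}
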