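# Validation alphabets. Proteins admit the 20 standard residues plus X
# (unknown); nucleotide sequences admit ACGT plus N.
.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
.NT_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file into a sequence record table
#'
#' Parses a (possibly gzipped) FASTA file and returns one row per record
#' with the residues uppercased and validated against the declared
#' alphabet. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either `"protein"` (20 amino acids + X) or
#'   `"nucleotide"` (ACGT + N).
#' @return A data.frame with columns `id`, `description`, `residues`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 toy", "MKT"), fa)
#' read_fasta(fa, "protein")
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(), description = character(),
                      residues = character(), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate sequence id in ", path, ": '", dup, "'")
  }
  residues <- toupper(as.character(set))
  allowed <- if (alphabet == "protein") .AA_ALPHABET else .NT_ALPHABET
  for (i in seq_along(residues)) {
    if (!nzchar(residues[[i]])) stop("empty sequence for id '", ids[[i]], "'")
    ch <- strsplit(residues[[i]], "")[[1]]
    bad <- which(!(ch %in% allowed))
    if (length(bad)) {
      stop("illegal ", alphabet, " character '", ch[bad[1L]],
           "' at position ", bad[1L], " in record '", ids[[i]], "'")
    }
  }
  data.frame(id = ids, description = desc, residues = residues,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records A data.frame with columns `id`, `residues` and optionally
#'   `description` (as returned by [read_fasta()]), or a named character
#'   vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), description = "",
                          residues = unname(records), stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[[i]]
    if (!is.null(records$description) && nzchar(records$description[[i]])) {
      hdr <- paste(hdr, records$description[[i]])
    }
    writeLines(paste0(">", hdr), con)
    s <- records$residues[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Loads `gene`, `mRNA` and `exon` features and reduces each gene to a
#' single representative transcript: the mRNA with the longest summed exon
#' length, ties broken by lexicographic mRNA id. Coordinates are 1-based
#' inclusive throughout, following the GFF3 convention.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with one row per gene: `gene_id`, `chromosome`,
#'   `start`, `end`, `strand`, `protein_id` (the representative mRNA id)
#'   and a list-column `exons` of two-column matrices (start, end), sorted
#'   by start.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(), strand = character(),
                      protein_id = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 9L)) {
    stop("malformed GFF3 line ", which(nf != 9L)[1L], ": expected 9 columns")
  }
  m <- do.call(rbind, f)
  attr_field <- function(attrs, key) {
    hit <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    got <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
    out[got] <- sub(paste0("^;?", key, "="), "", unlist(hit))
    out
  }
  feat <- data.frame(seqid = m[, 1L], type = m[, 3L],
                     start = as.integer(m[, 4L]), end = as.integer(m[, 5L]),
                     strand = m[, 7L], attrs = m[, 9L],
                     stringsAsFactors = FALSE)
  genes <- feat[feat$type == "gene", ]
  mrnas <- feat[feat$type == "mRNA", ]
  exons <- feat[feat$type == "exon", ]
  genes$id <- attr_field(genes$attrs, "ID")
  mrnas$id <- attr_field(mrnas$attrs, "ID")
  mrnas$parent <- attr_field(mrnas$attrs, "Parent")
  exons$parent <- attr_field(exons$attrs, "Parent")
  if (nrow(mrnas) && anyNA(mrnas$parent)) {
    stop("mRNA feature without a Parent attribute in ", path)
  }
  if (nrow(exons) && anyNA(exons$parent)) {
    stop("exon feature without a Parent attribute in ", path)
  }
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gm <- mrnas[mrnas$parent == g$id, , drop = FALSE]
    if (nrow(gm) == 0L) {
      # gene without annotated mRNA: treat the gene span as one exon
      ex <- matrix(c(g$start, g$end), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
      rep_id <- g$id
    } else {
      exlen <- vapply(gm$id, function(mid) {
        e <- exons[exons$parent == mid, , drop = FALSE]
        sum(e$end - e$start + 1L)
      }, integer(1L))
      ord <- order(-exlen, gm$id)
      rep_id <- gm$id[ord[1L]]
      e <- exons[exons$parent == rep_id, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) == 0L) {
        e <- gm[gm$id == rep_id, , drop = FALSE]  # exonless mRNA: its own span
      }
      if (any(e$start < g$start | e$end > g$end)) {
        stop("exon outside parent gene span for gene '", g$id, "'")
      }
      if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)])) {
        stop("overlapping exons under mRNA '", rep_id, "'")
      }
      ex <- cbind(start = e$start, end = e$end)
    }
    out[[i]] <- list(gene_id = g$id, chromosome = g$seqid,
                     start = g$start, end = g$end, strand = g$strand,
                     protein_id = rep_id, exons = ex)
  }
  res <- data.frame(
    gene_id = vapply(out, `[[`, "", "gene_id"),
    chromosome = vapply(out, `[[`, "", "chromosome"),
    start = vapply(out, `[[`, 0L, "start"),
    end = vapply(out, `[[`, 0L, "end"),
    strand = vapply(out, `[[`, "", "strand"),
    protein_id = vapply(out, `[[`, "", "protein_id"),
    stringsAsFactors = FALSE)
  res$exons <- lapply(out, `[[`, "exons")
  res
}

#' Read a per-domain tabular hit file
#'
#' Reads the whitespace-separated per-domain table produced by profile
#' searches (one row per domain hit; `#` lines are comments). Expected
#' column order: target (protein) id, domain id, independent E-value,
#' profile (hmm) from, profile to, alignment from, alignment to, profile
#' length. Profile coverage is computed as
#' `(hmm_to - hmm_from + 1) / hmm_len`.
#'
#' @param path Path to the hit table.
#' @return A data.frame with columns `protein_id`, `domain_id`, `e_value`,
#'   `hmm_from`, `hmm_to`, `ali_from`, `ali_to`, `hmm_len`, `profile_cov`.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("domain table not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  cols <- c("protein_id", "domain_id", "e_value", "hmm_from", "hmm_to",
            "ali_from", "ali_to", "hmm_len")
  if (!length(lines)) {
    out <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    out$profile_cov <- numeric()
    return(out)
  }
  f <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(f) < 8L)) {
    stop("line ", lineno[which(lengths(f) < 8L)[1L]],
         ": expected at least 8 whitespace-separated fields")
  }
  m <- t(vapply(f, function(x) x[1:8], character(8L)))
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      stop("line ", lineno[which(is.na(v))[1L]], ": non-numeric ", what,
           " '", m[which(is.na(v))[1L], j], "'")
    }
    v
  }
  out <- data.frame(protein_id = m[, 1L], domain_id = m[, 2L],
                    e_value = num(3L, "E-value"),
                    hmm_from = as.integer(num(4L, "coordinate")),
                    hmm_to = as.integer(num(5L, "coordinate")),
                    ali_from = as.integer(num(6L, "coordinate")),
                    ali_to = as.integer(num(7L, "coordinate")),
                    hmm_len = as.integer(num(8L, "profile length")),
                    stringsAsFactors = FALSE)
  if (any(out$e_value <= 0)) stop("E-values must be positive")
  if (any(out$hmm_from > out$hmm_to | out$ali_from > out$ali_to)) {
    stop("inverted coordinates in domain table")
  }
  out$profile_cov <- (out$hmm_to - out$hmm_from + 1) / out$hmm_len
  out
}

#' Write a per-domain hit table
#'
#' Inverse of [read_domain_table()]; used by the synthetic-data generator.
#'
#' @param hits Data.frame with the columns of [read_domain_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domain_table <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# target_id domain_id i_evalue hmm_from hmm_to ali_from ali_to hmm_len", con)
  if (nrow(hits)) {
    writeLines(sprintf("%s %s %.3g %d %d %d %d %d",
                       hits$protein_id, hits$domain_id, hits$e_value,
                       hits$hmm_from, hits$hmm_to, hits$ali_from,
                       hits$ali_to, hits$hmm_len), con)
  }
  invisible(path)
}

#' Load the published pepper CaDnaJ catalog
#'
#' Returns the 76-member pepper (Capsicum annuum) DnaJ family catalog
#' bundled with the package: gene name (CaDnaJ01..CaDnaJ76), locus id,
#' chromosome ("1".."12", or "00" for unplaced scaffolds), 1-based
#' coordinates, architecture group (A-E), protein length, molecular weight,
#' theoretical pI, and intron count. The table is typed verbatim from the
#' published survey, including its internal inconsistencies; repeated calls
#' return identical objects.
#'
#' @return A 76-row data.frame.
#' @examples
#' cat76 <- load_catalog()
#' table(cat76$group)
#' @export
load_catalog <- function() {
  path <- system.file("extdata", "cadnaj_catalog.tsv", package = "dnajfam",
                      mustWork = TRUE)
  out <- utils::read.delim(path, comment.char = "#",
                           colClasses = c("character", "character", "integer",
                                          "integer", "character", "character",
                                          "integer", "numeric", "numeric",
                                          "integer"),
                           stringsAsFactors = FALSE)
  stopifnot(nrow(out) == 76L)
  out
}

#' Write interval hits as BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention on output. An empty hit set produces a file holding
#' only the header comment.
#'
#' @param hits Data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED6: chrom start0 end name score strand", con)
  if (nrow(hits)) {
    name <- if (is.null(hits$name)) "." else hits$name
    score <- if (is.null(hits$score)) 0 else hits$score
    strand <- if (is.null(hits$strand)) "." else hits$strand
    writeLines(paste(hits$chrom, hits$start - 1L, hits$end, name, score,
                     strand, sep = "\t"), con)
  }
  invisible(path)
}

#' Write / read a TSV table with a '#'-prefixed header
#'
#' Lossless round-trip for the pipeline's tabular outputs: column names are
#' kept, strings are never mangled, and numeric columns are written at full
#' precision.
#'
#' @param table A data.frame (list-columns are not supported).
#' @param path File path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv` the data.frame.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
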