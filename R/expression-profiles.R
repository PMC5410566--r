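#' Read a genes x tissues expression matrix from TSV
#'
#' First column gene ids, remaining columns tissue RPKM values. Missing
#' cells are imputed as 0 with a message; values must be non-negative.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix with gene rownames and tissue colnames.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  if (anyNA(m)) {
    message("imputing ", sum(is.na(m)), " missing expression cells as 0")
    m[is.na(m)] <- 0
  }
  if (any(m < 0)) stop("negative expression values")
  m
}

#' Log2-transform an abundance matrix
#'
#' `log2(value + pseudocount)` per cell; monotone and rank-preserving
#' within every row for any positive pseudocount.
#'
#' @param m Non-negative numeric matrix.
#' @param pseudocount Positive offset added before the log (default 1, so
#'   zero maps to zero).
#' @return The transformed matrix.
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  log2(m + pseudocount)
}

#' Classify per-gene expression patterns
#'
#' Applied to the raw (untransformed) abundance matrix. A gene is counted
#' as expressed in a tissue when its value is at least `expr_min`.
#' Patterns: `barely_expressed` (no tissue), `constitutive` (every
#' tissue), `tissue_specific` (at most `specific_max` tissues), otherwise
#' `other`. The classes partition the gene set: exactly one call per gene.
#'
#' @param m Genes x tissues matrix of raw abundances.
#' @param expr_min Expression threshold (default 1 RPKM).
#' @param specific_max Maximum number of expressing tissues for a
#'   tissue-specific call (default 2).
#' @return Data.frame: `gene`, `pattern`, `n_expressed`, `expressed_in`
#'   (comma-separated tissue labels).
#' @export
classify_pattern <- function(m, expr_min = 1, specific_max = 2L) {
  expressed <- m >= expr_min
  n <- rowSums(expressed)
  pattern <- ifelse(n == 0L, "barely_expressed",
             ifelse(n == ncol(m), "constitutive",
             ifelse(n <= specific_max, "tissue_specific", "other")))
  data.frame(gene = rownames(m), pattern = pattern,
             n_expressed = as.integer(n),
             expressed_in = vapply(seq_len(nrow(m)), function(i) {
               paste(colnames(m)[expressed[i, ]], collapse = ",")
             }, character(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchically cluster genes for heat-map display
#'
#' Agglomerative clustering of gene rows (average linkage on Euclidean
#' distance by default). Rows are sorted by gene name before clustering so
#' that tie-breaking is deterministic and independent of input order. The
#' dendrogram is also exported in Newick form.
#'
#' @param m_log Log-transformed genes x tissues matrix (>= 1 gene row).
#' @param method Linkage method passed to [stats::hclust()].
#' @param metric Distance metric passed to [stats::dist()].
#' @return A list: `hclust` (NULL for a single gene), `leaf_order`
#'   (gene names in display order), `newick`.
#' @export
cluster_genes <- function(m_log, method = "average", metric = "euclidean") {
  if (nrow(m_log) == 0L) stop("empty matrix")
  m_log <- m_log[order(rownames(m_log)), , drop = FALSE]
  if (nrow(m_log) == 1L) {
    return(list(hclust = NULL, leaf_order = rownames(m_log),
                newick = paste0("(", rownames(m_log), ");")))
  }
  hc <- stats::hclust(stats::dist(m_log, method = metric), method = method)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, leaf_order = hc$labels[hc$order],
       newick = ape::write.tree(phy))
}

#' Render an expression heat map
#'
#' Purely presentational: draws the log-scale matrix with genes in the
#' supplied leaf order (top to bottom), tissues in input order, and a
#' diverging blue-white-red palette. Format follows the file extension
#' (`.svg` or `.png`). Re-rendering with identical inputs produces an
#' identical file.
#'
#' @param m_log Log-transformed matrix.
#' @param leaf_order Gene names in display order (e.g. from
#'   [cluster_genes()]).
#' @param path Output path ending in `.svg` or `.png`.
#' @return Invisibly, `path`.
#' @export
render_heatmap <- function(m_log, leaf_order = rownames(m_log), path) {
  if (nrow(m_log) == 0L || ncol(m_log) == 0L) stop("empty matrix")
  m <- m_log[leaf_order, , drop = FALSE]
  ext <- tolower(tools::file_ext(path))
  h <- max(4, 0.18 * nrow(m) + 1.5)
  if (ext == "svg") {
    grDevices::svg(path, width = 7, height = h)
  } else if (ext == "png") {
    grDevices::png(path, width = 700, height = h * 100, res = 100)
  } else {
    stop("unsupported heat-map format '.", ext, "'")
  }
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  lim <- max(abs(m - mean(m)), 1e-9)
  graphics::par(mar = c(6, 1, 1, 6))
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  zlim = mean(m) + c(-lim, lim), col = pal,
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  graphics::axis(4, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.5, tick = FALSE)
  invisible(path)
}
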