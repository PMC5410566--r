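#' Read a qPCR Ct table from TSV
#'
#' Expected columns: `gene`, `condition` (`control` / `treatment`),
#' `replicate`, `ct`.
#'
#' @param path Path to the TSV.
#' @return Data.frame with validated Ct values (0 < Ct < 45).
#' @export
read_qpcr <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(tab))) {
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$ct <= 0 | tab$ct >= 45)) stop("Ct values must lie in (0, 45)")
  tab
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are aggregated by arithmetic mean per condition
#' (set `per_replicate = TRUE` to average per-replicate ddCt instead);
#' dCt = mean Ct(target) - mean Ct(reference) within each condition,
#' ddCt = dCt(treatment) - dCt(control), fold = 2^(-ddCt). Amplification
#' efficiency is fixed at 2 (no efficiency correction). `replicate_sd` is
#' the replicate Ct standard error of the target propagated across the two
#' conditions, in cycles (i.e. on the log2-fold scale).
#'
#' @param table Ct table (see [read_qpcr()]).
#' @param gene Target gene.
#' @param reference_gene Internal control gene (e.g. `"UBI"`).
#' @param per_replicate Average per-replicate ddCt instead of mean-Ct
#'   aggregation.
#' @return One-row data.frame: `gene`, `fold`, `log2_fold`,
#'   `replicate_sd`.
#' @examples
#' tbl <- data.frame(gene = rep(c("g", "UBI"), each = 4),
#'                   condition = rep(c("control", "treatment"), 4),
#'                   replicate = rep(1:2, 4),
#'                   ct = c(24, 22, 24, 22, 20, 20, 20, 20))
#' ddct_fold(tbl, "g", "UBI")  # ddCt = -2, fold = 4
#' @export
ddct_fold <- function(table, gene, reference_gene = "UBI",
                      per_replicate = FALSE) {
  if (identical(gene, reference_gene)) {
    warning("target equals reference gene; fold is 1 by construction")
    return(data.frame(gene = gene, fold = 1, log2_fold = 0,
                      replicate_sd = 0, stringsAsFactors = FALSE))
  }
  tg <- table[table$gene == gene, , drop = FALSE]
  rf <- table[table$gene == reference_gene, , drop = FALSE]
  for (cond in c("control", "treatment")) {
    if (!any(tg$condition == cond)) {
      stop("gene '", gene, "' has no '", cond, "' measurements")
    }
    if (!any(rf$condition == cond)) {
      stop("reference '", reference_gene, "' has no '", cond,
           "' measurements")
    }
  }
  mean_ct <- function(d, cond) mean(d$ct[d$condition == cond])
  if (per_replicate) {
    ddcts <- c()
    for (r in intersect(tg$replicate, rf$replicate)) {
      dc <- function(cond) {
        tg$ct[tg$condition == cond & tg$replicate == r] -
          rf$ct[rf$condition == cond & rf$replicate == r]
      }
      ddcts <- c(ddcts, dc("treatment") - dc("control"))
    }
    ddct <- mean(ddcts)
  } else {
    dct_c <- mean_ct(tg, "control") - mean_ct(rf, "control")
    dct_t <- mean_ct(tg, "treatment") - mean_ct(rf, "treatment")
    ddct <- dct_t - dct_c
  }
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  rep_sd <- sqrt(sd0(tg$ct[tg$condition == "treatment"])^2 +
                   sd0(tg$ct[tg$condition == "control"])^2)
  data.frame(gene = gene, fold = 2^(-ddct), log2_fold = -ddct,
             replicate_sd = rep_sd, stringsAsFactors = FALSE)
}

#' Fold changes for every gene in a Ct table
#'
#' @param table Ct table (see [read_qpcr()]).
#' @param reference_gene Internal control gene.
#' @return Row-bound [ddct_fold()] results for all non-reference genes.
#' @export
qpcr_foldchanges <- function(table, reference_gene = "UBI") {
  genes <- setdiff(unique(table$gene), reference_gene)
  do.call(rbind, lapply(genes, function(g) {
    ddct_fold(table, g, reference_gene)
  }))
}

#' Call up/down/unchanged responses from fold changes
#'
#' `up` when fold >= `up_threshold`, `down` when fold <= `down_threshold`,
#' otherwise `unchanged`; an additional `strong_up` flag marks folds of at
#' least `strong_threshold` (three-fold induction by default). The up/down
#' cutoffs are reporting conventions, not published rules.
#'
#' @param folds Data.frame with a `fold` column (see
#'   [qpcr_foldchanges()]).
#' @param up_threshold,down_threshold,strong_threshold Fold cutoffs.
#' @return The input with `call` and `strong_up` columns appended.
#' @export
call_response <- function(folds, up_threshold = 2, down_threshold = 0.5,
                          strong_threshold = 3) {
  folds$call <- ifelse(folds$fold >= up_threshold, "up",
                ifelse(folds$fold <= down_threshold, "down", "unchanged"))
  folds$strong_up <- folds$fold >= strong_threshold
  folds
}
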