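#' Survey run configuration
#'
#' Collects input paths and every pipeline threshold in one flat list.
#' Unknown keys are rejected. A YAML file with the same flat keys can be
#' loaded with [read_survey_config()].
#'
#' @param proteins,domains Required inputs: proteome FASTA and per-domain
#'   hit table.
#' @param gff,genome,promoters,expression,qpcr,segmental Optional inputs;
#'   stages missing their input are skipped and marked so in the
#'   MANIFEST.
#' @param prefix Family name prefix used by [assign_names()].
#' @param reference_gene qPCR internal control gene.
#' @param e_threshold,cov_complete,zf_min_repeats,cterm_min See
#'   [arch_config()].
#' @param max_distance_bp,min_coverage,min_identity,max_intervening_genes
#'   See [duplication_criteria()].
#' @param upstream_bp Promoter window length.
#' @param pseudocount,expr_min,specific_max Expression-stage parameters.
#' @param up_threshold,down_threshold qPCR call thresholds.
#' @return A `survey_config` list.
#' @export
survey_config <- function(proteins, domains, gff = NULL, genome = NULL,
                          promoters = NULL, expression = NULL, qpcr = NULL,
                          segmental = NULL, prefix = "DnaJ",
                          reference_gene = "UBI",
                          e_threshold = 1e-5, cov_complete = 0.8,
                          zf_min_repeats = 2L, cterm_min = 40L,
                          max_distance_bp = 100000L, min_coverage = 0.70,
                          min_identity = 0.70, max_intervening_genes = 1L,
                          upstream_bp = 1500L, pseudocount = 1,
                          expr_min = 1, specific_max = 2L,
                          up_threshold = 2, down_threshold = 0.5) {
  cfg <- as.list(environment())
  structure(cfg, class = "survey_config")
}

#' Load a survey configuration from a flat YAML file
#'
#' @param path Path to a YAML document whose keys are the arguments of
#'   [survey_config()].
#' @return A `survey_config` list.
#' @export
read_survey_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(survey_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(survey_config, vals)
}

#' Run the full gene-family survey
#'
#' Orchestrates the pipeline on file inputs: architecture assembly from
#' the domain-hit table, the J-domain completeness filter, five-group
#' classification, chromosome-ordered naming, protein properties and
#' intron counts, chromosome distribution and tandem-duplication calls,
#' promoter cis-element census, expression patterns with a clustered heat
#' map, and qPCR fold changes. Each stage writes a TSV under `out_dir`;
#' optional stages whose inputs are absent are marked `skipped` in the
#' MANIFEST. Reruns with an identical configuration produce identical
#' tables.
#'
#' @param config A [survey_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_survey <- function(config, out_dir) {
  stopifnot(inherits(config, "survey_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  note <- function(stage, status) {
    manifest <<- c(manifest, paste0(stage, "\t", status))
  }
  fail <- function(stage, e) {
    writeLines(c(manifest, paste0(stage, "\tFAILED")),
               file.path(out_dir, "MANIFEST"))
    stop("survey stage '", stage, "' failed: ", conditionMessage(e))
  }
  results <- list()

  # identify + classify + name
  tryCatch({
    proteins <- read_fasta(config$proteins, "protein")
    hits <- read_domain_table(config$domains)
    cfg <- arch_config(config$e_threshold, config$cov_complete,
                       config$zf_min_repeats, config$cterm_min)
    arch <- assemble_architectures(proteins, hits, cfg)
    flt <- filter_complete(arch)
    retained <- classify_architectures(flt$retained)
    results$n_candidates <- nrow(arch)
    results$n_removed <- nrow(flt$removed)
    genes <- if (!is.null(config$gff)) read_gff3(config$gff) else NULL
    members <- data.frame(locus = sub("\\.t[0-9]+$", "", retained$protein_id),
                          protein_id = retained$protein_id,
                          group = retained$group,
                          stringsAsFactors = FALSE)
    if (!is.null(genes)) {
      k <- match(members$protein_id, genes$protein_id)
      members$chromosome <- genes$chromosome[k]
      members$start <- genes$start[k]
      members$end <- genes$end[k]
      members$strand <- genes$strand[k]
      members$introns <- intron_count(genes[k, , drop = FALSE])
      members$chromosome[is.na(members$chromosome)] <- "00"
    } else {
      members$chromosome <- "00"
      members$start <- NA_integer_
      members$end <- NA_integer_
    }
    members <- assign_names(members, prefix = config$prefix)
    seqs <- proteins$residues[match(members$protein_id, proteins$id)]
    members$size_aa <- nchar(seqs)
    members$mw_da <- round(vapply(seqs, molecular_weight, 0), 2)
    members$pi <- round(vapply(seqs, function(s) isoelectric_point(s), 0), 2)
    catalog <- data.frame(
      gene_name = members$gene_name, locus = members$locus,
      location = ifelse(is.na(members$start), "",
                        paste0(members$start, "-", members$end)),
      chromosome = members$chromosome, group = members$group,
      size_aa = members$size_aa, mw_da = members$mw_da, pi = members$pi,
      introns = if (is.null(members$introns)) NA_integer_ else members$introns,
      stringsAsFactors = FALSE)
    write_tsv(catalog, file.path(out_dir, "catalog.tsv"))
    census <- group_census(members$group)
    write_tsv(data.frame(group = names(census), members = census),
              file.path(out_dir, "group_census.tsv"))
    results$members <- members
    results$catalog <- catalog
    results$census <- census
    member_seqs <- stats::setNames(seqs, members$gene_name)
    note("identify_classify_name", "ok")
  }, error = function(e) fail("identify_classify_name", e))

  # chromosome distribution + duplications
  tryCatch({
    dist <- chromosome_distribution(results$members)
    write_tsv(data.frame(chromosome = names(dist), members = dist),
              file.path(out_dir, "chromosome_distribution.tsv"))
    results$chrom_dist <- dist
    crit <- duplication_criteria(config$max_distance_bp, config$min_coverage,
                                 config$min_identity,
                                 config$max_intervening_genes)
    if (!is.null(config$gff)) {
      tandem <- call_tandem(results$members, member_seqs, crit)
      results$tandem <- tandem
      dup <- tandem
      if (!is.null(config$segmental)) {
        segp <- read_segmental_pairs(config$segmental, results$members)
        if (nrow(segp)) {
          segp$chromosome <- NA_character_
          segp$distance_bp <- NA_integer_
          segp$coverage <- NA_real_
          segp$identity <- NA_real_
          dup <- rbind(dup, segp[, names(dup)])
        }
        results$segmental <- segp
      }
      write_tsv(dup, file.path(out_dir, "duplications.tsv"))
      note("map_duplications", "ok")
    } else {
      note("map_duplications", "skipped (no gene models)")
    }
  }, error = function(e) fail("map_duplications", e))

  # promoters
  tryCatch({
    prom <- NULL
    if (!is.null(config$promoters)) {
      prom <- read_fasta(config$promoters, "nucleotide")
    } else if (!is.null(config$genome) && !is.null(config$gff)) {
      genome <- read_fasta(config$genome, "nucleotide")
      genes <- read_gff3(config$gff)
      fam <- genes[genes$gene_id %in% results$members$locus, , drop = FALSE]
      prom <- extract_promoters(genome, fam, config$upstream_bp)
    }
    if (!is.null(prom)) {
      prom <- prom[prom$id %in% results$members$locus, , drop = FALSE]
      hits <- scan_motifs(prom, default_motifs())
      census <- element_census(hits, prom$id, default_motifs())
      write_tsv(hits, file.path(out_dir, "motif_hits.tsv"))
      write_tsv(census$per_motif, file.path(out_dir, "motif_census.tsv"))
      write_tsv(census$per_gene, file.path(out_dir, "motif_per_gene.tsv"))
      results$motif_census <- census
      note("promoters", "ok")
    } else {
      note("promoters", "skipped (no promoter input)")
    }
  }, error = function(e) fail("promoters", e))

  # expression
  tryCatch({
    if (!is.null(config$expression)) {
      m <- read_expression(config$expression)
      pat <- classify_pattern(m, config$expr_min, config$specific_max)
      mlog <- log_transform(m, config$pseudocount)
      cl <- cluster_genes(mlog)
      write_tsv(pat, file.path(out_dir, "expression_patterns.tsv"))
      writeLines(cl$newick, file.path(out_dir, "dendrogram.nwk"))
      render_heatmap(mlog, cl$leaf_order,
                     file.path(out_dir, "heatmap.svg"))
      results$patterns <- pat
      results$clustering <- cl
      note("expression", "ok")
    } else {
      note("expression", "skipped (no expression matrix)")
    }
  }, error = function(e) fail("expression", e))

  # qPCR
  tryCatch({
    if (!is.null(config$qpcr)) {
      ct <- read_qpcr(config$qpcr)
      folds <- call_response(qpcr_foldchanges(ct, config$reference_gene),
                             config$up_threshold, config$down_threshold)
      write_tsv(folds, file.path(out_dir, "qpcr_calls.tsv"))
      results$qpcr <- folds
      note("qpcr", "ok")
    } else {
      note("qpcr", "skipped (no Ct table)")
    }
  }, error = function(e) fail("qpcr", e))

  writeLines(manifest, file.path(out_dir, "MANIFEST"))
  report <- c(
    "# Gene-family survey report", "",
    sprintf("- candidates screened: %d", results$n_candidates),
    sprintf("- removed (incomplete J-domain): %d", results$n_removed),
    sprintf("- family members: %d", nrow(results$members)),
    sprintf("- group census: %s",
            paste(sprintf("%s=%d", names(results$census), results$census),
                  collapse = ", ")),
    if (!is.null(results$tandem)) {
      sprintf("- tandem duplications: %d", nrow(results$tandem))
    },
    if (!is.null(results$patterns)) {
      sprintf("- expression patterns: %s",
              paste(names(table(results$patterns$pattern)),
                    table(results$patterns$pattern),
                    sep = "=", collapse = ", "))
    },
    if (!is.null(results$qpcr)) {
      sprintf("- qPCR calls: %s",
              paste(names(table(results$qpcr$call)),
                    table(results$qpcr$call), sep = "=", collapse = ", "))
    })
  writeLines(report, file.path(out_dir, "report.md"))
  results$manifest <- manifest
  invisible(results)
}

#' Loci removed from the published pepper candidate set
#'
#' The nine pepper loci that passed the initial E-value screen but were
#' removed for lacking a complete J-domain; together with the bundled
#' 76-member catalog they make up the 85 candidates originally screened.
#'
#' @return Character vector of nine locus ids.
#' @export
removed_candidate_loci <- function() {
  c("CA03g32700", "CA06g22620", "CA00g87730", "CA12g09540", "CA02g21540",
    "CA05g10320", "CA11g03100", "CA06g00080", "CA05g07590")
}

#' Check the bundled pepper catalog against its published summaries
#'
#' Recomputes, from the bundled 76-member CaDnaJ catalog, the summary
#' statistics the original survey printed, and compares each against the
#' published value: group census (9/8/53/1/5), intron histogram (25
#' intronless, 11 single-intron, maximum 11), chromosome distribution
#' (eleven members on chromosome 8, nine on 5), the single 100-kb tandem
#' candidate pair CaDnaJ41/CaDnaJ42, and the catalog extrema (minimum
#' length 130 aa, minimum pI 4.56).
#'
#' @param catalog A catalog data.frame; defaults to [load_catalog()].
#'   Passing a perturbed catalog makes the corresponding checks fail,
#'   which is the intended sensitivity control.
#' @return Data.frame with columns `check`, `expected`, `observed`,
#'   `pass`; attribute `all_pass`.
#' @export
verify_against_catalog <- function(catalog = load_catalog()) {
  checks <- list()
  add <- function(name, expected, observed) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, expected = as.character(expected),
      observed = as.character(observed),
      pass = identical(as.character(expected), as.character(observed)),
      stringsAsFactors = FALSE)
  }
  add("family members", 76L, nrow(catalog))
  add("candidates screened (retained + removed)", 85L,
      nrow(catalog) + length(removed_candidate_loci()))
  census <- group_census(catalog$group)
  add("group census A/B/C/D/E", "9/8/53/1/5",
      paste(census, collapse = "/"))
  add("intronless members", 25L, sum(catalog$introns == 0L))
  add("single-intron members", 11L, sum(catalog$introns == 1L))
  add("maximum introns", 11L, max(catalog$introns))
  dist <- chromosome_distribution(catalog)
  add("members on chromosome 8", 11L, unname(dist["8"]))
  add("members on chromosome 5", 9L, unname(dist["5"]))
  cand <- tandem_candidates(catalog)
  add("tandem candidates (100 kb)", "CaDnaJ41/CaDnaJ42",
      paste(paste(cand$gene_a, cand$gene_b, sep = "/"), collapse = ","))
  stats_ <- catalog_stats(catalog)
  add("minimum length (aa)", "130 (CaDnaJ23)",
      sprintf("%d (%s)", stats_$size$min, stats_$size$min_gene))
  add("minimum pI", "4.56 (CaDnaJ74)",
      sprintf("%.2f (%s)", stats_$pi$min, stats_$pi$min_gene))
  out <- do.call(rbind, checks)
  attr(out, "all_pass") <- all(out$pass)
  out
}
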