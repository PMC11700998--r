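# Orchestration: run every analysis stage over one genome or a cohort,
# optionally writing a report bundle (TSV/JSON + MANIFEST) to a directory.
# Defaults mirror the study parameters: score cutoff 95, 1 kb merge
# distance, >= 3 genes per cluster, 50/300/50 flank windows, >= 4 T
# terminator runs.

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (c in names(df)) if (is.list(df[[c]]))
    df[[c]] <- vapply(df[[c]], function(x)
      paste(unlist(x), collapse = ","), character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Profile one genome end-to-end
#'
#' Runs the full single-genome pipeline: high-confidence filter, isotype /
#' isoacceptor tallies, sequence uniqueness, cluster calling, flank
#' extraction and regulatory-element scans, and intron extraction.
#'
#' @param genome a [tdna_genome] with sequence.
#' @param records a [tdna_records] table on that genome.
#' @param outdir optional output directory for the report bundle.
#' @param score_cutoff high-confidence score cutoff (default 95).
#' @param drop_pseudo drop pseudogene-flagged records (default TRUE).
#' @param gap_bp cluster merge distance (default 1000).
#' @param min_cluster_size minimum cluster membership (default 3).
#' @param upstream,downstream flank window sizes (defaults `c(50, 300)`
#'   and 50).
#' @param min_t_run minimum poly(T) run (default 4).
#' @param motifs TATA motif set (default `"TATA"`).
#' @return list of class `tdna_profile` with elements `records` (filtered,
#'   sequences attached), `counts`, `unique`, `clusters`,
#'   `cluster_summary`, `flanks`, `flank_report`, `flank_aggregate`,
#'   `introns` and `summary`.
#' @export
run_genome_profile <- function(genome, records, outdir = NULL,
                               score_cutoff = 95, drop_pseudo = TRUE,
                               gap_bp = 1000L, min_cluster_size = 3L,
                               upstream = c(50L, 300L), downstream = 50L,
                               min_t_run = 4L, motifs = "TATA") {
  rec <- filter_high_confidence(records, score_cutoff, drop_pseudo)
  rec <- attach_gene_sequences(rec, genome)
  counts <- tally_counts(stats::setNames(list(rec), genome$genome_id))
  uniq <- unique_fraction(rec)
  clusters <- call_clusters(rec, gap_bp = gap_bp,
                            min_size = min_cluster_size)
  csum <- cluster_summary(clusters, nrow(rec))
  flanks <- extract_flanks(rec, genome, upstream = upstream,
                           downstream = downstream)
  freport <- flank_report(flanks, motifs = motifs, min_run = min_t_run)
  fagg <- if (nrow(freport)) aggregate_flank_reports(freport) else NULL
  introns <- extract_introns(rec, genome)
  res <- list(
    genome_id = genome$genome_id, lineage = genome$lineage,
    records = rec, counts = counts, unique = uniq,
    clusters = clusters, cluster_summary = csum,
    flanks = flanks, flank_report = freport, flank_aggregate = fagg,
    introns = introns,
    summary = list(
      genome_id = genome$genome_id, lineage = genome$lineage,
      size_bp = genome$size_bp,
      n_input = nrow(records), n_high_confidence = nrow(rec),
      n_isotypes = ncol(counts$isotype),
      unique_pct = uniq$pct,
      n_clusters = csum$n_clusters, pct_clustered = csum$pct_clustered,
      n_introns = nrow(introns)),
    params = list(score_cutoff = score_cutoff, drop_pseudo = drop_pseudo,
                  gap_bp = gap_bp, min_cluster_size = min_cluster_size,
                  upstream = upstream, downstream = downstream,
                  min_t_run = min_t_run, motifs = motifs))
  class(res) <- "tdna_profile"
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(as.data.frame(rec), file.path(outdir, "records.tsv"))
    write_tsv(as.data.frame(counts$isoacceptor),
              file.path(outdir, "isoacceptor_counts.tsv"))
    write_tsv(clusters, file.path(outdir, "clusters.tsv"))
    write_tsv(freport[, setdiff(names(freport), "t_runs")],
              file.path(outdir, "flank_report.tsv"))
    write_tsv(introns, file.path(outdir, "introns.tsv"))
    jsonlite::write_json(
      list(summary = res$summary, params = res$params,
           flank_aggregate = fagg, cluster_summary = csum,
           missing_isoacceptors = counts$missing),
      file.path(outdir, "MANIFEST.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.tdna_profile <- function(x, ...) {
  s <- x$summary
  cat("<tdna_profile> ", s$genome_id, " (", s$lineage, ")\n",
      "  genes: ", s$n_high_confidence, " high-confidence of ", s$n_input,
      " input\n",
      "  unique sequences: ", round(s$unique_pct, 1), "%\n",
      "  clusters: ", s$n_clusters, " (", round(s$pct_clustered, 1),
      "% of genes clustered)\n",
      "  introns: ", s$n_introns, "\n", sep = "")
  invisible(x)
}

#' Cross-genome cohort comparison
#'
#' Per-lineage and overall count-vs-size regressions, uniqueness means,
#' the shared-identical-sequence table and (when genome sequence is
#' available) pooled regulatory-element aggregates.
#'
#' @param genomes named list of [tdna_genome] objects (sequence optional).
#' @param records_by_genome parallel named list of [tdna_records] tables
#'   with `gene_seq` populated.
#' @param outdir optional output directory.
#' @param score_cutoff,drop_pseudo high-confidence filter parameters.
#' @param shared_k minimum genome count for the shared-sequence table.
#' @param ... further parameters passed to [run_genome_profile()] when
#'   sequences are available.
#' @return list of class `tdna_cohort`: `regression`, `unique`,
#'   `lineage_unique_means`, `shared`, `counts`, `sizes_mb`, `lineages`,
#'   and `flank_aggregate` (NULL when no genome carries sequence).
#' @export
run_cohort_comparison <- function(genomes, records_by_genome, outdir = NULL,
                                  score_cutoff = 95, drop_pseudo = TRUE,
                                  shared_k = 2L, ...) {
  if (length(genomes) < 2L) stop("need >= 2 genomes")
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  names(genomes) <- names(records_by_genome) <- ids
  lineages <- stats::setNames(vapply(genomes, `[[`, character(1),
                                     "lineage"), ids)
  filt <- lapply(records_by_genome, filter_high_confidence,
                 score_cutoff = score_cutoff, drop_pseudo = drop_pseudo)
  sizes_mb <- vapply(genomes, `[[`, numeric(1), "size_bp") / 1e6
  counts <- vapply(filt, nrow, integer(1))
  reg <- if (length(genomes) >= 3L)
    regress_counts_vs_size(sizes_mb, counts, groups = lineages)
  else {
    warning("fewer than 3 genomes; regression skipped")
    NULL
  }
  uniq <- unique_fraction(filt, lineages = lineages)
  shared <- shared_identical_sequences(filt, k = shared_k)
  with_seq <- !vapply(genomes, function(g) is.null(g$contigs), logical(1))
  fagg <- NULL
  if (any(with_seq)) {
    reports <- lapply(ids[with_seq], function(g) {
      fl <- extract_flanks(filt[[g]], genomes[[g]])
      flank_report(fl)
    })
    fagg <- aggregate_flank_reports(do.call(rbind, reports))
  }
  res <- list(regression = reg, unique = uniq,
              lineage_unique_means = attr(uniq, "lineage_means"),
              shared = shared, counts = counts, sizes_mb = sizes_mb,
              lineages = lineages, flank_aggregate = fagg)
  class(res) <- "tdna_cohort"
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(reg)) write_tsv(reg, file.path(outdir, "regression.tsv"))
    write_tsv(uniq, file.path(outdir, "uniqueness.tsv"))
    write_tsv(shared, file.path(outdir, "shared_sequences.tsv"))
    jsonlite::write_json(
      list(n_genomes = length(genomes),
           lineage_unique_means = as.list(res$lineage_unique_means),
           flank_aggregate = fagg),
      file.path(outdir, "MANIFEST.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.tdna_cohort <- function(x, ...) {
  cat("<tdna_cohort> ", length(x$counts), " genomes\n", sep = "")
  if (!is.null(x$regression)) print(x$regression)
  if (!is.null(x$lineage_unique_means)) {
    cat("mean unique-sequence %% by lineage:\n")
    print(round(x$lineage_unique_means, 1))
  }
  cat(nrow(x$shared), " sequence(s) shared across >= 2 genomes\n", sep = "")
  invisible(x)
}
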