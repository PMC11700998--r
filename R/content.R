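# Per-genome tDNA content: high-confidence filtering, isotype/isoacceptor
# tallies, sequence uniqueness, cross-genome identity and the gene-count
# versus genome-size regression.

#' Filter annotations to the high-confidence set
#'
#' Keeps records whose bit score meets the cutoff (inclusive) and,
#' optionally, drops pseudogene-flagged records. The default cutoff of 95
#' matches the isotype-score threshold applied by tRNAscan-SE's eukaryotic
#' high-confidence post-filter.
#'
#' @param records a [tdna_records] table.
#' @param score_cutoff minimum score retained (default 95).
#' @param drop_pseudo drop records whose note contains "pseudo".
#' @return the filtered records; attributes `n_kept`/`n_dropped` report the
#'   outcome.
#' @export
filter_high_confidence <- function(records, score_cutoff = 95,
                                   drop_pseudo = TRUE) {
  keep <- records$score >= score_cutoff
  if (drop_pseudo) keep <- keep & !grepl("pseudo", records$note,
                                         ignore.case = TRUE)
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no records pass the high-confidence filter")
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Tally isotype and isoacceptor counts per genome
#'
#' @param records_by_genome named list of [tdna_records] tables (one per
#'   genome), or a single table (treated as one genome).
#' @return list with `isotype` and `isoacceptor` count matrices (rows =
#'   genomes) and `missing`, a data.frame listing the isotype-anticodon
#'   combinations (and isotypes) absent from each genome relative to the
#'   union observed in the input.
#' @export
tally_counts <- function(records_by_genome) {
  if (is.data.frame(records_by_genome))
    records_by_genome <- list(genome = records_by_genome)
  if (is.null(names(records_by_genome)))
    names(records_by_genome) <- paste0("genome", seq_along(records_by_genome))
  acc_of <- function(r) {
    if (nrow(r) == 0L) return(character(0))
    paste0(r$isotype, "-", ifelse(is.na(r$anticodon), "NNN", r$anticodon))
  }
  all_acc <- sort(unique(unlist(lapply(records_by_genome, acc_of))))
  all_iso <- sort(unique(unlist(lapply(records_by_genome,
                                       function(r) r$isotype))))
  acc_mat <- t(vapply(records_by_genome, function(r) {
    tab <- table(factor(acc_of(r), levels = all_acc))
    as.integer(tab)
  }, integer(length(all_acc))))
  colnames(acc_mat) <- all_acc
  iso_mat <- t(vapply(records_by_genome, function(r) {
    tab <- table(factor(r$isotype, levels = all_iso))
    as.integer(tab)
  }, integer(length(all_iso))))
  colnames(iso_mat) <- all_iso
  miss <- do.call(rbind, lapply(rownames(acc_mat), function(g) {
    zero_acc <- all_acc[acc_mat[g, ] == 0L]
    if (length(zero_acc) == 0L) return(NULL)
    data.frame(genome_id = g, isoacceptor = zero_acc,
               isotype_absent = sub("-.*$", "", zero_acc) %in%
                 all_iso[iso_mat[g, ] == 0L],
               stringsAsFactors = FALSE)
  }))
  list(isotype = iso_mat, isoacceptor = acc_mat,
       missing = miss %||% data.frame(genome_id = character(),
                                      isoacceptor = character(),
                                      isotype_absent = logical()))
}

#' Percentage of unique tDNA sequences
#'
#' Uniqueness compares full sense-strand genomic gene sequences, introns
#' included, uppercase — the strictest reproducible reading. A genome with
#' no genes yields `NA`.
#'
#' @param records a [tdna_records] table (single genome) or a named list of
#'   them.
#' @param lineages optional named lineage vector (names = genome ids) used
#'   to add per-lineage mean percentages.
#' @return for a single table: list with `pct`, `distinct`, `total`. For a
#'   list: data.frame per genome plus (when `lineages` given) an attribute
#'   `lineage_means`.
#' @export
unique_fraction <- function(records, lineages = NULL) {
  one <- function(r) {
    if (nrow(r) == 0L)
      return(list(pct = NA_real_, distinct = 0L, total = 0L))
    if (anyNA(r$gene_seq)) stop("gene_seq must be populated")
    d <- length(unique(toupper(r$gene_seq)))
    list(pct = 100 * d / nrow(r), distinct = d, total = nrow(r))
  }
  if (is.data.frame(records)) return(one(records))
  per <- lapply(records, one)
  df <- data.frame(genome_id = names(records),
                   pct = vapply(per, `[[`, numeric(1), "pct"),
                   distinct = vapply(per, `[[`, numeric(1), "distinct"),
                   total = vapply(per, `[[`, numeric(1), "total"),
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(lineages)) {
    df$lineage <- lineages[df$genome_id]
    means <- tapply(df$pct, df$lineage, mean, na.rm = TRUE)
    attr(df, "lineage_means") <- means
  }
  df
}

#' Sequences shared identically across genomes
#'
#' Exact string identity on sense-strand gene sequences across a cohort
#' (so a copy carried on the minus strand of one genome still matches).
#'
#' @param records_by_genome named list of [tdna_records] tables.
#' @param k minimum number of genomes a sequence must appear in (default 2).
#' @return data.frame with `sequence`, `isoacceptor`, `n_genomes` and a
#'   comma-separated `genomes` column, ordered by decreasing `n_genomes`.
#' @export
shared_identical_sequences <- function(records_by_genome, k = 2L) {
  if (length(records_by_genome) < 2L) stop("need >= 2 genomes")
  if (is.null(names(records_by_genome)))
    names(records_by_genome) <- paste0("genome", seq_along(records_by_genome))
  long <- do.call(rbind, lapply(names(records_by_genome), function(g) {
    r <- records_by_genome[[g]]
    if (nrow(r) == 0L) return(NULL)
    data.frame(genome_id = g, sequence = toupper(r$gene_seq),
               isoacceptor = paste0(r$isotype, "-",
                                    ifelse(is.na(r$anticodon), "NNN",
                                           r$anticodon)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(long)) return(data.frame(sequence = character(),
                                       isoacceptor = character(),
                                       n_genomes = integer(),
                                       genomes = character()))
  per_seq <- split(long, long$sequence)
  rows <- lapply(per_seq, function(d) {
    gs <- sort(unique(d$genome_id))
    data.frame(sequence = d$sequence[1],
               isoacceptor = paste(sort(unique(d$isoacceptor)),
                                   collapse = ";"),
               n_genomes = length(gs),
               genomes = paste(gs, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_genomes >= k, , drop = FALSE]
  out <- out[order(-out$n_genomes, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Regress tDNA counts on genome size
#'
#' Ordinary least squares of gene count on genome size (Mb), overall and
#' per group. The p-value is the two-sided t-test on the slope (n - 2 df),
#' matching `summary.lm`.
#'
#' @param sizes_mb numeric genome sizes in Mb.
#' @param counts integer gene counts (same length).
#' @param groups optional grouping labels (e.g. lineage); groups with fewer
#'   than 3 genomes are skipped with a warning.
#' @return data.frame of class `tdna_regression` with one row per fit
#'   (`overall` first): slope, intercept, r_squared, p_value, n.
#' @export
regress_counts_vs_size <- function(sizes_mb, counts, groups = NULL) {
  stopifnot(length(sizes_mb) == length(counts))
  fit_one <- function(x, y, label) {
    if (length(x) < 3L) {
      warning("group '", label, "' has fewer than 3 genomes; skipped")
      return(NULL)
    }
    if (stats::var(x) == 0) stop("zero variance in genome size for '",
                                 label, "': regression undefined")
    if (stats::var(y) == 0)   # flat response: R^2 is 0 by convention
      return(data.frame(group = label, slope = 0, intercept = y[1],
                        r_squared = 0, p_value = 1, n = length(x),
                        stringsAsFactors = FALSE))
    m <- stats::lm(y ~ x)
    sm <- suppressWarnings(summary(m))  # perfect fits warn; p is moot there
    data.frame(group = label,
               slope = unname(stats::coef(m)[2]),
               intercept = unname(stats::coef(m)[1]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4],
               n = length(x), stringsAsFactors = FALSE)
  }
  out <- fit_one(sizes_mb, counts, "overall")
  if (!is.null(groups)) {
    for (g in unique(groups)) {
      sel <- groups == g
      out <- rbind(out, fit_one(sizes_mb[sel], counts[sel], g))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("tdna_regression", "data.frame")
  out
}

#' @export
print.tdna_regression <- function(x, ...) {
  cat("tDNA count ~ genome size (Mb), OLS:\n")
  df <- as.data.frame(x)
  df$slope <- signif(df$slope, 4)
  df$intercept <- signif(df$intercept, 4)
  df$r_squared <- signif(df$r_squared, 3)
  df$p_value <- format.pval(df$p_value, digits = 3)
  print(df, row.names = FALSE)
  invisible(x)
}
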