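# tDNA cluster calling by interval-density merging: genes are merged
# single-linkage when the gap between neighbours (end-to-start, half-open
# intervals, strand-blind) is at most the merge distance, and merged runs of
# at least `min_size` genes are reported — the ">= 3 tDNAs within 1 kb"
# density criterion, with BEDTools-merge gap semantics.

# pattern label for an ordered vector of member isotypes
classify_pattern <- function(iso) {
  u <- unique(iso)
  if (length(u) == 1L) return(paste0("homogeneous:", u))
  if (length(u) == 2L && all(iso[-1] != iso[-length(iso)]))
    return(paste0("alternating:", u[1], "/", u[2]))
  "mixed"
}

#' Call tDNA clusters
#'
#' @param records a [tdna_records] table.
#' @param gap_bp merge distance in bp (default 1000). Genes `i` and `i+1`
#'   (sorted by start, per contig) join one cluster iff
#'   `start(i+1) - end(i) <= gap_bp`; overlapping/bookended genes always
#'   merge. Strand is ignored.
#' @param min_size minimum member count reported (default 3).
#' @param start_to_start measure the distance start-to-start instead of
#'   gap-wise (alternative reading of "within 1 kb of each other").
#' @return data.frame of class `tdna_clusters`: contig, start/end envelope
#'   (0-based half-open), size, pattern, and a `members` list-column of
#'   gene ids in start order.
#' @export
call_clusters <- function(records, gap_bp = 1000L, min_size = 3L,
                          start_to_start = FALSE) {
  stopifnot(gap_bp >= 0)
  out <- list()
  for (ctg in unique(records$contig)) {
    r <- records[records$contig == ctg, , drop = FALSE]
    r <- r[order(r$start, r$end), , drop = FALSE]
    if (nrow(r) == 0L) next
    d <- if (start_to_start) diff(r$start)
         else r$start[-1] - cummax(r$end)[-nrow(r)]  # running max end:
                                                     # contained intervals
                                                     # must not break a run
    grp <- cumsum(c(0L, as.integer(d > gap_bp)))
    for (g in split(seq_len(nrow(r)), grp)) {
      if (length(g) < min_size) next
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = min(r$start[g]), end = max(r$end[g]),
        size = length(g),
        pattern = classify_pattern(r$isotype[g]),
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- list(r$gene_id[g])
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(contig = character(), start = integer(),
                         end = integer(), size = integer(),
                         pattern = character(),
                         members = I(list()))
  res <- res[order(res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("tdna_clusters", "data.frame")
  res
}

#' Classify the composition pattern of a cluster
#'
#' `homogeneous:<iso>` if all member isotypes are equal;
#' `alternating:<isoA>/<isoB>` if exactly two isotypes occur and no two
#' adjacent members (by start order) share one; otherwise `mixed`.
#'
#' @param isotypes character vector of member isotypes in start order (or a
#'   one-row slice of a `tdna_clusters` table).
#' @return the pattern label.
#' @export
classify_cluster <- function(isotypes) {
  if (is.data.frame(isotypes)) {
    if (!"isotype" %in% names(isotypes))
      stop("pass member isotypes in start order")
    isotypes <- isotypes$isotype
  }
  if (length(isotypes) < 3L) stop("cluster size must be >= 3")
  classify_pattern(as.character(isotypes))
}

#' Per-genome cluster statistics
#'
#' @param clusters a `tdna_clusters` table.
#' @param total_genes total gene count of the genome.
#' @return list: `n_clusters`, `clustered_genes`, `pct_clustered`
#'   (100 * clustered / total), `largest_size`, `largest_pattern`.
#' @export
cluster_summary <- function(clusters, total_genes) {
  stopifnot(total_genes >= 0)
  if (total_genes == 0L && nrow(clusters) > 0L)
    stop("clusters reported for a genome with zero genes")
  cg <- sum(clusters$size)
  list(n_clusters = nrow(clusters),
       clustered_genes = cg,
       pct_clustered = if (total_genes > 0L) 100 * cg / total_genes else 0,
       largest_size = if (nrow(clusters)) max(clusters$size) else 0L,
       largest_pattern = if (nrow(clusters))
         clusters$pattern[which.max(clusters$size)] else NA_character_)
}

#' @export
print.tdna_clusters <- function(x, ...) {
  cat("<tdna_clusters> ", nrow(x), " cluster(s)\n", sep = "")
  if (nrow(x)) {
    df <- as.data.frame(x)[, c("contig", "start", "end", "size", "pattern")]
    print(utils::head(df, 20), row.names = FALSE)
    if (nrow(x) > 20) cat("...\n")
  }
  invisible(x)
}
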