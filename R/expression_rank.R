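#' Load an FPKM matrix from TSV
#'
#' Expects a header row of timepoint labels and a first column of gene ids.
#' Values must be numeric and non-negative; the loader reports the exact
#' cell (gene, column) of the first offending entry.
#'
#' @param path TSV file, genes in rows, timepoints in columns.
#' @return An `ExpressionMatrix`: list with `genes`, `timepoints` and a
#'   numeric `values` matrix (genes x timepoints).
#' @export
load_fpkm <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("FPKM table needs a gene_id column and >= 1 timepoint")
  genes <- raw[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    stop("duplicated gene_id in FPKM table: ", paste(unique(dup), collapse = ", "))
  }
  timepoints <- colnames(raw)[-1]
  values <- matrix(NA_real_, nrow = length(genes), ncol = length(timepoints),
                   dimnames = list(genes, timepoints))
  for (j in seq_along(timepoints)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    if (any(is.na(v))) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric FPKM value at gene '%s', column '%s'",
                   genes[i], timepoints[j]))
    }
    values[, j] <- v
  }
  if (any(values < 0)) {
    i <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative FPKM value at gene '%s', column '%s'",
                 genes[i[1]], timepoints[i[2]]))
  }
  structure(list(genes = genes, timepoints = timepoints, values = values),
            class = "ExpressionMatrix")
}

#' Write an `ExpressionMatrix` back to TSV (round-trips with [load_fpkm()])
#' @param m An `ExpressionMatrix`.
#' @param path Output TSV path.
#' @export
write_fpkm <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene_id = m$genes, m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", m$timepoints)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank genes by mean expression over the diurnal cycle
#'
#' The mean is the unweighted arithmetic mean over all supplied timepoint
#' columns (replicate columns, if present, enter individually). Rank 1 is
#' the highest mean; tied means all receive the minimum rank of their block.
#'
#' @param m An `ExpressionMatrix` (or a plain numeric matrix with gene
#'   rownames).
#' @return A `RankTable` data frame: `gene_id`, `mean_fpkm`, `sd_fpkm`,
#'   `rank`, ordered by rank. For a single timepoint `sd_fpkm` is `NA`.
#' @export
rank_expression <- function(m) {
  if (inherits(m, "ExpressionMatrix")) {
    values <- m$values
    genes <- m$genes
  } else {
    values <- as.matrix(m)
    genes <- rownames(values)
    if (is.null(genes)) stop("matrix input needs gene rownames")
  }
  if (ncol(values) < 1) stop("need at least one timepoint")
  mu <- rowMeans(values)
  sd_ <- if (ncol(values) > 1) apply(values, 1, stats::sd) else rep(NA_real_, nrow(values))
  rk <- rank(-mu, ties.method = "min")
  out <- data.frame(gene_id = genes, mean_fpkm = mu, sd_fpkm = sd_,
                    rank = as.integer(rk), stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("RankTable", "data.frame")
  out
}

#' Filter genes by expression rank, with explicit exceptions
#'
#' Keeps genes whose rank is at most `max_rank` ("above rank 350" in the
#' screen's sense of being among the 350 most expressed), plus any
#' explicitly excepted genes regardless of rank (the screen's nitrate
#' reductase terminator is the motivating case: rank 15537, kept because
#' the gene is strongly induced under nitrogen depletion).
#'
#' @param rt A `RankTable`.
#' @param max_rank Largest admissible rank (>= 0).
#' @param exceptions Character vector of gene ids to keep unconditionally.
#' @return Character vector of gene ids passing the filter.
#' @export
rank_filter <- function(rt, max_rank, exceptions = character()) {
  stopifnot(is.data.frame(rt), max_rank >= 0)
  keep <- rt$gene_id[rt$rank <= max_rank]
  union(keep, intersect(exceptions, rt$gene_id))
}

#' Count long 3' UTRs among the top-ranked genes
#'
#' Takes the `top_n` best-ranked genes (optionally restricted to a subset,
#' e.g. nuclear genes), looks up their 3' UTR lengths and counts how many
#' exceed `threshold`. Top-ranked genes missing from the length table are
#' reported in `n_missing`, never silently dropped.
#'
#' @param rt A `RankTable`.
#' @param lengths Data frame `gene_id`, `length` as from [feature_lengths()].
#' @param top_n Number of top-ranked genes to inspect.
#' @param threshold Length threshold in bp (default 1000).
#' @param subset Optional character vector restricting the ranking universe
#'   before the top-n cut (ranks are recomputed within the subset).
#' @return List `count`, `top_n`, `threshold`, `n_missing`.
#' @export
utr_length_by_rank <- function(rt, lengths, top_n, threshold = 1000,
                               subset = NULL) {
  stopifnot(is.data.frame(rt), is.data.frame(lengths))
  if (!is.null(subset)) {
    rt <- rt[rt$gene_id %in% subset, ]
    rt$rank <- rank(-rt$mean_fpkm, ties.method = "min")
  }
  rt <- rt[order(rt$rank, rt$gene_id), ]
  if (top_n > nrow(rt)) {
    stop(sprintf("top_n (%d) exceeds the %d ranked genes available",
                 top_n, nrow(rt)))
  }
  top <- utils::head(rt$gene_id, top_n)
  len <- lengths$length[match(top, lengths$gene_id)]
  list(count = sum(len > threshold, na.rm = TRUE),
       top_n = top_n, threshold = threshold,
       n_missing = sum(is.na(len)))
}
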