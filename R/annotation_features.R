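#' Parse GFF3 gene models into a GeneModelSet
#'
#' Reads a GFF3 annotation (gene / mRNA / CDS / five_prime_UTR /
#' three_prime_UTR records linked by `Parent` attributes, as in Phytozome
#' filtered gene models) and builds one gene model per gene, keeping a single
#' representative transcript. All coordinates are 1-based inclusive, matching
#' the GFF3 convention; a feature's length is `end - start + 1` summed over
#' its intervals.
#'
#' @param path Path to a GFF3 file. An optional trailing `##FASTA` section is
#'   ignored.
#' @param transcript_policy How to pick the representative transcript when a
#'   gene has several mRNAs: `"longest"` (largest exonic length, ties broken
#'   by the lexicographically smallest transcript id) or `"primary"`
#'   (lexicographically smallest transcript id, which selects the `.1` model
#'   in Phytozome-style annotations).
#' @return A `GeneModelSet`: a list with `genes` (one row per gene: span
#'   coordinates, strand, per-kind feature lengths, `has_utr3`), `features`
#'   (one row per CDS/UTR interval of the representative transcript) and
#'   bookkeeping counts. Genes lacking an annotated 3' UTR are retained with
#'   `utr3_length = 0` and `has_utr3 = FALSE`.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c(
#'   "##gff-version 3",
#'   "chr1\tx\tgene\t100\t1200\t.\t+\t.\tID=g1",
#'   "chr1\tx\tmRNA\t100\t1200\t.\t+\t.\tID=g1.t1;Parent=g1",
#'   "chr1\tx\tCDS\t100\t1000\t.\t+\t0\tID=g1.t1.c;Parent=g1.t1",
#'   "chr1\tx\tthree_prime_UTR\t1001\t1200\t.\t+\t.\tID=g1.t1.u;Parent=g1.t1"
#' ), gff)
#' gm <- parse_gff3(gff)
#' gm$genes$utr3_length  # 200
#' @export
parse_gff3 <- function(path, transcript_policy = c("longest", "primary")) {
  transcript_policy <- match.arg(transcript_policy)
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  validate_gff3_syntax(path)

  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(empty_gene_model_set(transcript_policy))
  }
  type <- as.character(gr$type)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parents <- first_parent(gr$Parent)

  gene_idx <- which(type == "gene")
  mrna_idx <- which(type == "mRNA")
  if (length(gene_idx) == 0) {
    return(empty_gene_model_set(transcript_policy))
  }

  gene_ids <- ids[gene_idx]
  mrna_ids <- ids[mrna_idx]

  orphan_mrna <- mrna_ids[!(parents[mrna_idx] %in% gene_ids)]
  child_kinds <- c("CDS", "five_prime_UTR", "three_prime_UTR", "exon")
  child_idx <- which(type %in% child_kinds)
  orphan_children <- unique(parents[child_idx][!(parents[child_idx] %in% mrna_ids)])
  orphan_children <- orphan_children[!is.na(orphan_children)]
  orphans <- c(orphan_mrna, orphan_children)
  if (length(orphans) > 0) {
    stop("GFF3 features reference unknown Parent id(s): ",
         paste(unique(orphans), collapse = ", "))
  }

  feat <- data.frame(
    idx = child_idx,
    kind = c(CDS = "cds", five_prime_UTR = "utr5",
             three_prime_UTR = "utr3", exon = "exon")[type[child_idx]],
    transcript_id = parents[child_idx],
    chrom = as.character(GenomicRanges::seqnames(gr))[child_idx],
    start = GenomicRanges::start(gr)[child_idx],
    end = GenomicRanges::end(gr)[child_idx],
    strand = as.character(GenomicRanges::strand(gr))[child_idx],
    stringsAsFactors = FALSE
  )
  feat$width <- feat$end - feat$start + 1

  # representative transcript per gene
  mrna_parent <- parents[mrna_idx]
  exonic_len <- vapply(mrna_ids, function(tid) {
    f <- feat[feat$transcript_id == tid, ]
    if (any(f$kind == "exon")) sum(f$width[f$kind == "exon"])
    else sum(f$width[f$kind != "exon"])
  }, numeric(1))

  chosen <- vapply(gene_ids, function(gid) {
    tids <- mrna_ids[mrna_parent == gid]
    if (length(tids) == 0) return(NA_character_)
    if (transcript_policy == "primary") return(sort(tids)[1])
    len <- exonic_len[match(tids, mrna_ids)]
    best <- tids[len == max(len)]
    sort(best)[1]
  }, character(1))

  keep_gene <- !is.na(chosen)
  n_no_mrna <- sum(!keep_gene)
  gene_ids <- gene_ids[keep_gene]
  gene_idx <- gene_idx[keep_gene]
  chosen <- chosen[keep_gene]

  feat <- feat[feat$transcript_id %in% chosen & feat$kind != "exon", ]
  feat$gene_id <- gene_ids[match(feat$transcript_id, chosen)]
  feat <- feat[order(feat$gene_id, feat$start), c("gene_id", "transcript_id",
                                                  "kind", "chrom", "start",
                                                  "end", "strand", "width")]
  rownames(feat) <- NULL

  len_of <- function(gid, kind) {
    sum(feat$width[feat$gene_id == gid & feat$kind == kind])
  }
  genes <- data.frame(
    gene_id = gene_ids,
    transcript_id = chosen,
    chrom = as.character(GenomicRanges::seqnames(gr))[gene_idx],
    start = GenomicRanges::start(gr)[gene_idx],
    end = GenomicRanges::end(gr)[gene_idx],
    strand = as.character(GenomicRanges::strand(gr))[gene_idx],
    stringsAsFactors = FALSE
  )
  genes$cds_length <- vapply(genes$gene_id, len_of, numeric(1), kind = "cds")
  genes$utr5_length <- vapply(genes$gene_id, len_of, numeric(1), kind = "utr5")
  genes$utr3_length <- vapply(genes$gene_id, len_of, numeric(1), kind = "utr3")
  genes$has_utr3 <- genes$utr3_length > 0
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  rownames(genes) <- NULL

  structure(
    list(genes = genes, features = feat,
         transcript_policy = transcript_policy,
         n_genes_without_mrna = n_no_mrna),
    class = "GeneModelSet"
  )
}

empty_gene_model_set <- function(transcript_policy) {
  structure(
    list(
      genes = data.frame(gene_id = character(), transcript_id = character(),
                         chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         cds_length = numeric(), utr5_length = numeric(),
                         utr3_length = numeric(), has_utr3 = logical(),
                         stringsAsFactors = FALSE),
      features = data.frame(gene_id = character(), transcript_id = character(),
                            kind = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), width = integer(),
                            stringsAsFactors = FALSE),
      transcript_policy = transcript_policy,
      n_genes_without_mrna = 0L
    ),
    class = "GeneModelSet"
  )
}

# GFF3 body lines must have 9 tab-separated fields; report the first offender
# with its line number. A trailing ##FASTA section is legal and skipped.
validate_gff3_syntax <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (identical(ln, "##FASTA")) break
    if (ln == "" || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf != 9) {
      stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, found %d",
                   i, nf))
    }
  }
  invisible(TRUE)
}

first_parent <- function(p) {
  if (is.null(p)) return(NA_character_)
  vapply(as.list(p), function(x) {
    if (length(x) == 0) NA_character_ else as.character(x)[1]
  }, character(1))
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat(sprintf("GeneModelSet: %d genes on %d sequence(s); %d with annotated 3' UTR\n",
              nrow(x$genes), length(unique(x$genes$chrom)), sum(x$genes$has_utr3)))
  cat(sprintf("  representative transcript policy: %s\n", x$transcript_policy))
  invisible(x)
}

#' Per-gene feature lengths
#'
#' Extracts the total annotated length of one feature kind per gene from a
#' [parse_gff3()] result. Genes without that feature are excluded from the
#' table and counted in the `n_excluded` attribute (they are never reported
#' as length 0).
#'
#' @param models A `GeneModelSet`.
#' @param kind One of `"utr3"`, `"utr5"`, `"cds"`.
#' @return A data frame with columns `gene_id` and `length` (bp), with
#'   attribute `n_excluded` giving the number of genes lacking the feature.
#' @export
feature_lengths <- function(models, kind = c("utr3", "utr5", "cds")) {
  stopifnot(inherits(models, "GeneModelSet"))
  kind <- match.arg(kind)
  if (nrow(models$genes) == 0) stop("no gene models supplied")
  col <- paste0(kind, "_length")
  len <- models$genes[[col]]
  keep <- len > 0
  out <- data.frame(gene_id = models$genes$gene_id[keep],
                    length = len[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Histogram of feature lengths with half-open bins
#'
#' Bin `i` (0-based) covers `[i * binsize, (i + 1) * binsize)`, so with the
#' default 100-bp bins a 100-bp feature falls in the second bin.
#'
#' @param lengths Numeric vector of non-negative lengths (bp).
#' @param binsize Positive bin width in bp (default 100).
#' @return A `LengthHistogram`: data frame `bin_lo`, `bin_hi`, `count` with
#'   attribute `n_total`. Empty bins below the maximum are retained so that
#'   `sum(count) == n_total`.
#' @export
length_histogram <- function(lengths, binsize = 100) {
  if (binsize <= 0) stop("binsize must be > 0")
  if (length(lengths) > 0 && any(lengths < 0)) {
    stop("negative lengths are not allowed")
  }
  if (length(lengths) == 0) {
    out <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0))
  } else {
    bin <- floor(lengths / binsize)
    tab <- tabulate(bin + 1, nbins = max(bin) + 1)
    out <- data.frame(bin_lo = (seq_along(tab) - 1) * binsize,
                      bin_hi = seq_along(tab) * binsize,
                      count = tab)
  }
  attr(out, "n_total") <- length(lengths)
  class(out) <- c("LengthHistogram", "data.frame")
  out
}

#' Classify terminator lengths into the three screen size classes
#'
#' Short is strictly below 100 bp, medium is 100-600 bp inclusive at both
#' ends, long is strictly above 600 bp; the classes partition the positive
#' integers.
#'
#' @param length Vector of positive lengths (bp).
#' @return Factor with levels `short`, `medium`, `long`.
#' @examples
#' classify_length(c(34, 100, 600, 601, 786))
#' @export
classify_length <- function(length) {
  if (any(length <= 0)) stop("length must be positive")
  cut(length, breaks = c(0, 99.5, 600.5, Inf),
      labels = c("short", "medium", "long"))
}

#' Distances between genomically adjacent genes
#'
#' Genes are ordered by span start within each chromosome (strand is
#' ignored for adjacency) and one distance is emitted per adjacent pair:
#' `downstream_start - upstream_end - 1`, i.e. the number of bases strictly
#' between the two measured boundaries. Overlapping annotations therefore
#' give negative distances, which are retained.
#'
#' `mode = "utr_to_utr"` measures from the genomic end of the upstream
#' gene's last annotated UTR interval to the genomic start of the downstream
#' gene's first annotated UTR interval; genes with no annotated UTR fall
#' back to their span boundary. `mode = "span_to_span"` always uses gene
#' span boundaries.
#'
#' @param models A `GeneModelSet`.
#' @param mode `"utr_to_utr"` (default) or `"span_to_span"`.
#' @return Data frame `upstream_gene`, `downstream_gene`, `chrom`,
#'   `distance` (bp). Chromosomes carrying a single gene contribute no rows.
#' @export
intergenic_distances <- function(models, mode = c("utr_to_utr", "span_to_span")) {
  stopifnot(inherits(models, "GeneModelSet"))
  mode <- match.arg(mode)
  g <- models$genes
  if (nrow(g) < 2) {
    return(data.frame(upstream_gene = character(), downstream_gene = character(),
                      chrom = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (mode == "utr_to_utr") {
    f <- models$features
    utr <- f[f$kind %in% c("utr5", "utr3"), ]
    lo <- tapply(utr$start, utr$gene_id, min)
    hi <- tapply(utr$end, utr$gene_id, max)
    g$bound_lo <- ifelse(g$gene_id %in% names(lo), lo[g$gene_id], g$start)
    g$bound_hi <- ifelse(g$gene_id %in% names(hi), hi[g$gene_id], g$end)
  } else {
    g$bound_lo <- g$start
    g$bound_hi <- g$end
  }
  g <- g[order(g$chrom, g$start, g$gene_id), ]
  out <- lapply(split(g, g$chrom), function(gc) {
    n <- nrow(gc)
    if (n < 2) return(NULL)
    data.frame(upstream_gene = gc$gene_id[-n],
               downstream_gene = gc$gene_id[-1],
               chrom = gc$chrom[-n],
               distance = gc$bound_lo[-1] - gc$bound_hi[-n] - 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(upstream_gene = character(), downstream_gene = character(),
                      chrom = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Summary statistics for a vector of feature lengths
#'
#' The median uses the lower-middle convention for even n (the n/2-th sorted
#' element), so it is always an observed, integer-valued length;
#' interpolation is available via `median_convention = "interpolate"`.
#'
#' @param lengths Non-empty numeric vector (bp).
#' @param threshold Report the fraction of lengths strictly greater than
#'   this value (default 1000 bp).
#' @param median_convention `"lower"` (default) or `"interpolate"`.
#' @return List with `n`, `median`, `mean`, `threshold`, `fraction_above`.
#' @export
summarize_lengths <- function(lengths, threshold = 1000,
                              median_convention = c("lower", "interpolate")) {
  median_convention <- match.arg(median_convention)
  if (length(lengths) == 0) stop("cannot summarize an empty length vector")
  s <- sort(lengths)
  med <- if (median_convention == "lower") {
    s[floor((length(s) + 1) / 2)]
  } else {
    stats::median(s)
  }
  list(n = length(lengths), median = med, mean = mean(lengths),
       threshold = threshold,
       fraction_above = sum(lengths > threshold) / length(lengths))
}
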