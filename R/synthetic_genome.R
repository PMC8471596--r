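#' Configuration for the synthetic genome generator
#'
#' The generator emulates the statistical surface of the *C. reinhardtii*
#' annotation that the downstream analysis consumes: a three-component
#' 3' UTR length mixture (short < 100 bp, medium 100-600 bp, long > 600 bp,
#' with weights defaulting to the approximate class abundances of the real
#' genome, ~686 / ~7,407 / ~11,000 genes), GC-rich intergenic spacing, and a
#' poly(A) motif planted so that it ends a configurable 10-20 nt upstream of
#' the annotated cleavage point in a configurable fraction of UTRs.
#'
#' @param n_genes Number of genes to plant.
#' @param n_chroms Number of chromosomes (genes split evenly).
#' @param class_weights Mixture weights for short/medium/long 3' UTRs; must
#'   sum to 1.
#' @param class_ranges List of length-2 vectors giving the uniform length
#'   range sampled within each class.
#' @param utr5_range,cds_range Uniform length ranges for 5' UTRs and CDS.
#' @param gap_range Uniform range for intergenic gaps (bp between gene spans).
#' @param motif_prob Probability a 3' UTR carries a planted TGTAA motif.
#' @param motif_offset_range Distance (nt) from the motif end to the UTR's
#'   3' (cleavage) end.
#' @param gc Genome GC content (the real nuclear genome averages 0.64).
#' @param chrom_size Optional fixed chromosome length (bp). `NA` (default)
#'   sizes each chromosome to fit its genes; a fixed size that cannot
#'   accommodate the planted genes raises a packing error.
#' @return A `GenomeGenConfig` list.
#' @export
genome_config <- function(n_genes = 60, n_chroms = 2,
                          class_weights = c(short = 0.036, medium = 0.388,
                                            long = 0.576),
                          class_ranges = list(short = c(20, 99),
                                              medium = c(100, 600),
                                              long = c(601, 1500)),
                          utr5_range = c(50, 300), cds_range = c(300, 1500),
                          gap_range = c(200, 3000),
                          motif_prob = 0.9, motif_offset_range = c(10, 20),
                          gc = 0.64, chrom_size = NA) {
  if (abs(sum(class_weights) - 1) > 1e-8) stop("class_weights must sum to 1")
  stopifnot(n_genes >= 0, n_chroms >= 1, motif_prob >= 0, motif_prob <= 1,
            gc > 0, gc < 1)
  structure(list(n_genes = n_genes, n_chroms = n_chroms,
                 class_weights = class_weights, class_ranges = class_ranges,
                 utr5_range = utr5_range, cds_range = cds_range,
                 gap_range = gap_range, motif_prob = motif_prob,
                 motif_offset_range = motif_offset_range, gc = gc,
                 chrom_size = chrom_size),
            class = "GenomeGenConfig")
}

sample_utr3_lengths <- function(cfg, n = cfg$n_genes) {
  classes <- sample(names(cfg$class_weights), n, replace = TRUE,
                    prob = cfg$class_weights)
  vapply(classes, function(cl) {
    r <- cfg$class_ranges[[cl]]
    sample(seq(r[1], r[2]), 1)
  }, numeric(1))
}

runif_len <- function(n, range) {
  sample(seq(range[1], range[2]), n, replace = TRUE)
}

random_dna <- function(n, gc = 0.64) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic genome (FASTA + GFF3) with planted truth
#'
#' Lays genes with a five_prime_UTR / CDS / three_prime_UTR structure along
#' each chromosome (random strand, uniform intergenic gaps), fills the
#' sequence with GC-biased random DNA, and plants a sense-strand TGTAA
#' motif near the 3' end of a configurable fraction of UTRs (on the genomic
#' minus strand for minus-strand genes, so the extracted sense sequence
#' carries it). Every planted quantity is echoed in a truth table, enabling
#' exact round-trip tests of the annotation and part-selection machinery.
#'
#' Output is deterministic for a fixed seed and config (byte-identical
#' files on rerun).
#'
#' @param cfg A `GenomeGenConfig` from [genome_config()].
#' @param seed Integer RNG seed.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"synth"`).
#' @return List `fasta`, `gff3` (file paths) and `truth`: data frame
#'   `gene_id`, `chrom`, `strand`, `utr5_length`, `cds_length`,
#'   `utr3_length`, `size_class`, `has_motif`, `motif_pos_sense` (1-based
#'   position in the sense-oriented 3' UTR, `NA` if none planted).
#' @export
gen_genome <- function(cfg = genome_config(), seed = 1,
                       dir = tempfile("synthgenome"), prefix = "synth") {
  stopifnot(inherits(cfg, "GenomeGenConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  n <- cfg$n_genes
  per_chrom <- if (n > 0) split(seq_len(n), rep(seq_len(cfg$n_chroms),
                                                length.out = n)) else list()
  truth <- list()
  chrom_seqs <- character(cfg$n_chroms)
  gff <- c("##gff-version 3")

  gene_counter <- 0
  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- sprintf("chr%02d", ci)
    idx <- if (ci <= length(per_chrom)) per_chrom[[ci]] else integer(0)
    pieces <- character(0)
    pos <- 0L
    for (g in idx) {
      gene_counter <- gene_counter + 1
      gid <- sprintf("SYNG%04d", gene_counter)
      tid <- paste0(gid, ".t1")
      gap <- runif_len(1, cfg$gap_range)
      u5 <- runif_len(1, cfg$utr5_range)
      cds <- runif_len(1, cfg$cds_range)
      u3 <- sample_utr3_lengths(cfg, 1)
      strand <- sample(c("+", "-"), 1)
      has_motif <- stats::runif(1) < cfg$motif_prob

      utr3_seq <- random_dna(u3, cfg$gc)
      motif_pos <- NA_integer_
      if (has_motif && u3 >= 5 + cfg$motif_offset_range[1]) {
        offset <- runif_len(1, cfg$motif_offset_range)  # motif end -> UTR 3' end
        motif_end <- u3 - offset
        if (motif_end >= 5) {
          motif_pos <- motif_end - 4L
          substr(utr3_seq, motif_pos, motif_end) <- "TGTAA"
          # the random fill may contain further TGTAAs; that is fine, the
          # truth table records the planted one
        } else {
          has_motif <- FALSE
        }
      } else {
        has_motif <- FALSE
      }

      gene_len <- u5 + cds + u3
      gstart <- pos + gap + 1L
      gend <- gstart + gene_len - 1L
      # genomic layout: + strand reads utr5|cds|utr3 left to right,
      # - strand reads it right to left
      if (strand == "+") {
        u5_iv <- c(gstart, gstart + u5 - 1L)
        cds_iv <- c(gstart + u5, gstart + u5 + cds - 1L)
        u3_iv <- c(gend - u3 + 1L, gend)
        gene_seq <- paste0(random_dna(u5, cfg$gc), random_dna(cds, cfg$gc),
                           utr3_seq)
      } else {
        u3_iv <- c(gstart, gstart + u3 - 1L)
        cds_iv <- c(gstart + u3, gstart + u3 + cds - 1L)
        u5_iv <- c(gend - u5 + 1L, gend)
        gene_seq <- paste0(revcomp(utr3_seq), random_dna(cds, cfg$gc),
                           random_dna(u5, cfg$gc))
      }
      pieces <- c(pieces, random_dna(gap, cfg$gc), gene_seq)
      pos <- gend

      gff <- c(gff,
        gff_line(chrom, "gene", gstart, gend, strand, sprintf("ID=%s", gid)),
        gff_line(chrom, "mRNA", gstart, gend, strand,
                 sprintf("ID=%s;Parent=%s", tid, gid)),
        gff_line(chrom, "five_prime_UTR", u5_iv[1], u5_iv[2], strand,
                 sprintf("ID=%s.u5;Parent=%s", tid, tid)),
        gff_line(chrom, "CDS", cds_iv[1], cds_iv[2], strand,
                 sprintf("ID=%s.cds;Parent=%s", tid, tid)),
        gff_line(chrom, "three_prime_UTR", u3_iv[1], u3_iv[2], strand,
                 sprintf("ID=%s.u3;Parent=%s", tid, tid)))

      truth[[gid]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        utr5_length = u5, cds_length = cds, utr3_length = u3,
        size_class = as.character(classify_length(u3)),
        has_motif = has_motif, motif_pos_sense = motif_pos,
        stringsAsFactors = FALSE)
    }
    # trailing spacer so the last gene is not flush with the chromosome end
    pieces <- c(pieces, random_dna(runif_len(1, cfg$gap_range), cfg$gc))
    chrom_seqs[ci] <- paste(pieces, collapse = "")
    if (!is.na(cfg$chrom_size)) {
      used <- nchar(chrom_seqs[ci])
      if (used > cfg$chrom_size) {
        stop(sprintf("cannot pack %d gene(s) into a %d-bp chromosome (%d bp needed); increase chrom_size or reduce n_genes",
                     length(idx), cfg$chrom_size, used))
      }
      chrom_seqs[ci] <- paste0(chrom_seqs[ci],
                               random_dna(cfg$chrom_size - used, cfg$gc))
    }
  }

  fasta_path <- file.path(dir, paste0(prefix, ".fasta"))
  gff_path <- file.path(dir, paste0(prefix, ".gff3"))
  seqs <- Biostrings::DNAStringSet(chrom_seqs)
  names(seqs) <- sprintf("chr%02d", seq_len(cfg$n_chroms))
  Biostrings::writeXStringSet(seqs, fasta_path)
  writeLines(gff, gff_path)

  truth_df <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(gene_id = character(), chrom = character(), strand = character(),
               utr5_length = numeric(), cds_length = numeric(),
               utr3_length = numeric(), size_class = character(),
               has_motif = logical(), motif_pos_sense = integer(),
               stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL
  list(fasta = fasta_path, gff3 = gff_path, truth = truth_df)
}

gff_line <- function(chrom, type, start, end, strand, attrs) {
  paste(chrom, "termpart", type, start, end, ".", strand, ".", attrs,
        sep = "\t")
}
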