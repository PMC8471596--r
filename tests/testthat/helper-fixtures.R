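# Fixture builders shared across test files. Everything is generated in
# code at test time; nothing is read from disk except what the tests write.

# minimal GFF3 with one + strand and one - strand gene; utr3 intervals
# 1001..1200 (200 bp) and 5001..5057 (57 bp)
write_two_gene_gff3 <- function(path = tempfile(fileext = ".gff3"),
                                reversed = FALSE) {
  g1 <- c(
    "chr1\tt\tgene\t100\t1200\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t100\t1200\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tt\tfive_prime_UTR\t100\t199\t.\t+\t.\tID=g1.t1.u5;Parent=g1.t1",
    "chr1\tt\tCDS\t200\t1000\t.\t+\t0\tID=g1.t1.c;Parent=g1.t1",
    "chr1\tt\tthree_prime_UTR\t1001\t1200\t.\t+\t.\tID=g1.t1.u3;Parent=g1.t1"
  )
  g2 <- c(
    "chr1\tt\tgene\t5001\t6000\t.\t-\t.\tID=g2",
    "chr1\tt\tmRNA\t5001\t6000\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr1\tt\tthree_prime_UTR\t5001\t5057\t.\t-\t.\tID=g2.t1.u3;Parent=g2.t1",
    "chr1\tt\tCDS\t5058\t5900\t.\t-\t0\tID=g2.t1.c;Parent=g2.t1",
    "chr1\tt\tfive_prime_UTR\t5901\t6000\t.\t-\t.\tID=g2.t1.u5;Parent=g2.t1"
  )
  body <- if (reversed) c(g2, g1) else c(g1, g2)
  writeLines(c("##gff-version 3", body), path)
  path
}

# a genome + annotation with fully controlled 3' UTR sequences, for
# select_candidates tests: utr3_seqs is a named list gene_id -> sense
# sequence; genes are laid head-to-tail on one chromosome, all + strand
write_planted_genome <- function(utr3_seqs,
                                 dir = tempfile("planted")) {
  dir.create(dir, showWarnings = FALSE)
  cds_len <- 60
  gap <- 100
  fasta <- character(0)
  gff <- "##gff-version 3"
  pos <- 0
  filler <- function(n) paste(rep("C", n), collapse = "")
  chrom_seq <- ""
  for (gid in names(utr3_seqs)) {
    u3 <- utr3_seqs[[gid]]
    gstart <- pos + gap + 1
    cds_iv <- c(gstart, gstart + cds_len - 1)
    u3_iv <- c(gstart + cds_len, gstart + cds_len + nchar(u3) - 1)
    chrom_seq <- paste0(chrom_seq, filler(gap), filler(cds_len), u3)
    gff <- c(gff,
      sprintf("chrA\tt\tgene\t%d\t%d\t.\t+\t.\tID=%s", gstart, u3_iv[2], gid),
      sprintf("chrA\tt\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
              gstart, u3_iv[2], gid, gid),
      sprintf("chrA\tt\tCDS\t%d\t%d\t.\t+\t0\tID=%s.t1.c;Parent=%s.t1",
              cds_iv[1], cds_iv[2], gid, gid),
      sprintf("chrA\tt\tthree_prime_UTR\t%d\t%d\t.\t+\t.\tID=%s.t1.u3;Parent=%s.t1",
              u3_iv[1], u3_iv[2], gid, gid))
    pos <- u3_iv[2]
  }
  fasta_path <- file.path(dir, "genome.fasta")
  gff_path <- file.path(dir, "genes.gff3")
  writeLines(c(">chrA", chrom_seq), fasta_path)
  writeLines(gff, gff_path)
  list(fasta = fasta_path, gff3 = gff_path)
}

# random DNA without any BsaI/BpiI site (either strand) or TGTAA motif
clean_random_dna <- function(n) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    if (nrow(find_sites(s, moclo_enzymes())) == 0 &&
        length(scan_motif(s)) == 0) return(s)
  }
}

# independent brute-force Mann-Whitney oracle: U by pairwise comparison for
# every labeling of the pooled sample
mwu_oracle <- function(x, y) {
  pair_u <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  nx <- length(x)
  N <- length(pooled)
  idx <- utils::combn(N, nx)
  us <- apply(idx, 2, function(ii) pair_u(pooled[ii], pooled[-ii]))
  mu <- nx * (N - nx) / 2
  u_obs <- pair_u(x, y)
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# plate-record table built directly (bypassing the generator)
make_plates <- function(n, viable_rounds, gfp_positive = NULL,
                        construct = "X", strain = "cw15",
                        experiment_id = 1) {
  stopifnot(is.matrix(viable_rounds), nrow(viable_rounds) == n)
  df <- data.frame(line_id = sprintf("%s_L%03d", construct, seq_len(n)),
                   construct = construct, strain = strain,
                   selection = "zeocin", experiment_id = experiment_id,
                   stringsAsFactors = FALSE)
  for (r in seq_len(ncol(viable_rounds))) {
    df[[paste0("viable_r", r)]] <- viable_rounds[, r]
  }
  final <- viable_rounds[, ncol(viable_rounds)]
  gfp <- rep(NA, n)
  if (!is.null(gfp_positive)) gfp[final] <- gfp_positive[final]
  df$gfp <- gfp
  df
}
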