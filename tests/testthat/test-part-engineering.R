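test_that("scan_motif finds overlapping occurrences on the sense strand", {
  expect_equal(scan_motif("TGTAA"), 1)
  expect_equal(scan_motif("TGTAATGTAA"), c(1, 6))
  expect_equal(scan_motif("TGTAAGTAA"), 1)      # overlap, second broken
  expect_length(scan_motif("AAAAA"), 0)
  expect_equal(scan_motif("ugUAAtgtaa"), c(1, 6))  # RNA input mapped to DNA
  expect_error(scan_motif("TGTNA"), "non-ACGT")
})

test_that("trim_to_motif keeps the motif plus the requested tail", {
  # motif occupies 8..12 (1-based end 12); tail 33 -> 45-bp prefix of 50
  s <- paste0(strrep("C", 7), "TGTAA", strrep("A", 38))
  expect_equal(nchar(s), 50)
  expect_equal(nchar(trim_to_motif(s, tail = 33)), 45)

  # tail 0 with the motif at the very end: unchanged
  s2 <- paste0(strrep("G", 10), "TGTAA")
  expect_equal(trim_to_motif(s2, tail = 0), s2)

  # several occurrences: the last one compatible with the tail is used
  s3 <- paste0("TGTAA", strrep("C", 20), "TGTAA", strrep("G", 10))
  expect_equal(nchar(trim_to_motif(s3, tail = 5)), 35)
  expect_equal(nchar(trim_to_motif(s3, tail = 11)), 16)  # falls back to motif 1
  expect_warning(out <- trim_to_motif(s3, tail = 36), "tail")
  expect_equal(out, s3)

  expect_error(trim_to_motif("ACGTACGT"), "not found")
})

test_that("find_sites reports both strands at plus-strand coordinates", {
  hits <- find_sites("AAGGTCTCAA")
  expect_equal(hits$enzyme, "BsaI")
  expect_equal(hits$position, 3)
  expect_equal(hits$strand, "+")

  rc <- find_sites("TTGAGACCTT")  # GAGACC = revcomp(GGTCTC)
  expect_equal(rc$enzyme, "BsaI")
  expect_equal(rc$strand, "-")

  expect_equal(nrow(find_sites("ATATATATAT")), 0)

  # strand symmetry: reverse-complementing never changes the hit count
  set.seed(21)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    rcs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(nrow(find_sites(rcs)), nrow(find_sites(s)))
  }
})

test_that("domesticate removes all type-IIS sites with single substitutions", {
  s <- paste0("AATGTAA", "GGTCTC", "TTTTTT", "GAAGAC", "CCTGTAACCAA")
  p <- domesticate(terminator_part("p1", s))
  expect_true(p$domesticated)
  expect_equal(nrow(find_sites(p$sequence)), 0)
  expect_equal(nrow(p$mutations), 2)
  expect_equal(nchar(p$sequence), nchar(s))
  # motifs untouched
  expect_equal(p$motif_hits, scan_motif(s))

  # idempotence
  p2 <- domesticate(p)
  expect_identical(p2$sequence, p$sequence)
  expect_equal(nrow(p2$mutations), nrow(p$mutations))

  # no sites -> unchanged, empty mutation log
  clean <- terminator_part("p0", "AATGTAACCGGAATT")
  expect_equal(nrow(domesticate(clean)$mutations), 0)
  expect_identical(domesticate(clean)$sequence, clean$sequence)
})

test_that("domesticate errors when a site is fully protected", {
  s <- paste0("AA", "GGTCTC", "TGTAA", "CC")
  p <- terminator_part("p", s)
  expect_error(domesticate(p, protected = data.frame(start = 1, end = nchar(s))),
               "BsaI")
})

test_that("randomized planted sites are always removed and stay removed", {
  set.seed(31)
  recs <- c("GGTCTC", "GAAGAC", "GAGACC", "GTCTTC")
  for (i in 1:20) {
    backbone <- clean_random_dna(80)
    n_sites <- sample(1:3, 1)
    pos <- sort(sample(seq(5, 60, by = 12), n_sites))
    s <- backbone
    for (p0 in pos) substr(s, p0, p0 + 5) <- sample(recs, 1)
    part <- domesticate(terminator_part(sprintf("r%d", i), s))
    expect_equal(nrow(find_sites(part$sequence)), 0)
    expect_identical(domesticate(part)$sequence, part$sequence)
  }
})

test_that("Golden Gate assembly closes the circle and digestion recovers parts", {
  set.seed(9)
  mk <- function(up, dn, n, role) {
    assembly_part(paste0(up, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                   collapse = ""), dn), role)
  }
  p1 <- mk("AATG", "GCTT", 12, "promoter")
  p2 <- mk("GCTT", "CGAA", 12, "terminator")
  bb <- mk("CGAA", "AATG", 30, "backbone")
  asm <- simulate_assembly(list(p1, p2), bb)
  # 20 + 20 + 38 bp with three 4-nt junctions each counted once
  expect_equal(nchar(asm$sequence), 20 + 20 + 38 - 3 * 4)
  expect_identical(digest_assembly(asm),
                   c(p1$sequence, p2$sequence, bb$sequence))

  # minimal case: one part closing directly onto the backbone
  q <- mk("AATG", "GCTT", 10, "cds")
  bb2 <- mk("GCTT", "AATG", 16, "backbone")
  asm2 <- simulate_assembly(list(q), bb2)
  expect_equal(nchar(asm2$sequence), 18 + 24 - 8)
  expect_identical(digest_assembly(asm2), c(q$sequence, bb2$sequence))

  # mismatched junction is named
  p3 <- mk("TTAC", "CGAA", 12, "terminator")
  expect_error(simulate_assembly(list(p1, p3), bb), "promoter->terminator")

  # an overhang reused at two junctions is an ambiguity error
  pa <- mk("AATG", "AATG", 12, "promoter")
  bb3 <- mk("AATG", "AATG", 16, "backbone")
  expect_error(simulate_assembly(list(pa), bb3), "ambiguous")
})

test_that("larger randomized assemblies round-trip through digestion", {
  set.seed(51)
  overhangs <- c("AATG", "GCTT", "CGAA", "TTAC", "GGAC", "CCAT")
  roles <- c("promoter", "utr5", "cds", "terminator", "intron")
  for (i in 1:10) {
    k <- sample(2:5, 1)
    ov <- sample(overhangs, k + 1)
    parts <- lapply(seq_len(k), function(j) {
      assembly_part(paste0(ov[j],
                           paste(sample(c("A", "C", "G", "T"),
                                        sample(8:40, 1), TRUE), collapse = ""),
                           ov[j + 1]), roles[(j - 1) %% 5 + 1])
    })
    bb <- assembly_part(paste0(ov[k + 1],
                               paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                                     collapse = ""), ov[1]), "backbone")
    asm <- simulate_assembly(parts, bb)
    expect_identical(digest_assembly(asm),
                     vapply(c(parts, list(bb)), `[[`, character(1), "sequence"))
  }
})

test_that("linearization_flank measures the shorter arc to the cassette", {
  set.seed(61)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  while (length(scan_motif(s, "AGTACT")) > 0) {
    p <- scan_motif(s, "AGTACT")[1]
    substr(s, p, p) <- "C"
  }
  # ScaI cuts AGT^ACT: site planted at 4197 puts the cut at 4200
  substr(s, 4197, 4202) <- "AGTACT"
  lf <- linearization_flank(s, "ScaI", c(1000, 3000))
  expect_true(lf$is_unique)
  expect_false(lf$in_cassette)
  expect_equal(lf$cut_position, 4200)
  expect_equal(lf$flank_bp, 1199)

  # two sites: not unique
  s2 <- s
  substr(s2, 3500, 3505) <- "AGTACT"
  expect_false(linearization_flank(s2, "ScaI", c(1000, 3000))$is_unique)

  # no site: error
  s3 <- s
  substr(s3, 4197, 4202) <- "AAAAAA"
  expect_error(linearization_flank(s3, "ScaI", c(1000, 3000)), "no site")

  # a cut inside the cassette is flagged, not an exception
  s4 <- s
  substr(s4, 4197, 4202) <- "AAAAAA"
  substr(s4, 1997, 2002) <- "AGTACT"
  lf4 <- linearization_flank(s4, "ScaI", c(1000, 3000))
  expect_true(lf4$in_cassette)
  expect_true(is.na(lf4$flank_bp))
})

test_that("select_candidates applies motif, length and rank rules", {
  tail20 <- strrep("A", 20)
  utr <- function(core, len) {
    paste0(strrep("G", len - nchar(core) - 20), core, tail20)
  }
  seqs <- list(
    gm01 = utr("TGTAA", 300),             # passes
    gm02 = utr("TGTAA", 500),             # passes
    gm03 = utr("TGACA", 300),             # no motif -> dropped
    gm04 = utr("TGGAA", 400),             # no motif -> dropped
    gm05 = utr("TGTAA", 1200),            # > 1000 bp -> dropped
    gm06 = utr("TGTAA", 90)               # passes (short class)
  )
  gx <- write_planted_genome(seqs)
  gm <- parse_gff3(gx$gff3)
  parts <- select_candidates(gm, gx$fasta, ranks = NULL)
  expect_equal(vapply(parts, `[[`, character(1), "source_gene"),
               c("gm01", "gm02", "gm06"))
  expect_equal(vapply(parts, `[[`, character(1), "size_class"),
               c("medium", "medium", "short"))
  expect_true(all(vapply(parts, function(p) length(p$motif_hits) > 0,
                         logical(1))))

  # empty model set
  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_length(select_candidates(parse_gff3(empty), gx$fasta), 0)

  # rank filter: keep only gm02 by rank, gm06 as an exception
  rt <- data.frame(gene_id = names(seqs),
                   mean_fpkm = c(1, 100, 5, 5, 5, 0.1),
                   sd_fpkm = 0, rank = c(6L, 1L, 3L, 3L, 3L, 5L))
  parts <- select_candidates(gm, gx$fasta, rt, max_rank = 1,
                             exceptions = "gm06")
  expect_setequal(vapply(parts, `[[`, character(1), "source_gene"),
                  c("gm02", "gm06"))

  # missing chromosome in the FASTA is an error
  other <- tempfile(fileext = ".fasta")
  writeLines(c(">chrZ", "ACGT"), other)
  expect_error(select_candidates(gm, other, ranks = NULL), "chrA")
})

test_that("minus-strand parts read in the sense direction", {
  g <- gen_genome(genome_config(n_genes = 30, motif_prob = 1), seed = 13)
  gm <- parse_gff3(g$gff3)
  genome <- Biostrings::readDNAStringSet(g$fasta)
  minus <- g$truth[g$truth$strand == "-" & g$truth$has_motif, ]
  expect_gt(nrow(minus), 0)
  for (i in seq_len(nrow(minus))) {
    s <- termpart:::extract_utr3_sequence(gm, genome, minus$gene_id[i])
    expect_equal(nchar(s), minus$utr3_length[i])
    expect_true(minus$motif_pos_sense[i] %in% scan_motif(s))
  }
})

test_that("candidate selection is invariant to annotation record order", {
  g <- gen_genome(genome_config(n_genes = 16), seed = 17)
  gm <- parse_gff3(g$gff3)
  lines <- readLines(g$gff3)
  # reverse whole gene blocks (5 records each) after the header
  body <- lines[-1]
  blocks <- split(body, rep(seq_len(length(body) / 5), each = 5))
  shuffled <- tempfile(fileext = ".gff3")
  writeLines(c(lines[1], unlist(rev(blocks))), shuffled)
  p1 <- select_candidates(gm, g$fasta, ranks = NULL)
  p2 <- select_candidates(parse_gff3(shuffled), g$fasta, ranks = NULL)
  expect_identical(parts_table(p1), parts_table(p2))
})
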