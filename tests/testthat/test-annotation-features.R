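test_that("parse_gff3 builds gene models with correct UTR lengths and strands", {
  gm <- parse_gff3(write_two_gene_gff3())
  expect_s3_class(gm, "GeneModelSet")
  expect_equal(nrow(gm$genes), 2)
  expect_equal(gm$genes$utr3_length[gm$genes$gene_id == "g1"], 200)
  expect_equal(gm$genes$utr3_length[gm$genes$gene_id == "g2"], 57)
  expect_true(all(gm$genes$has_utr3))
  expect_equal(gm$genes$strand, c("+", "-"))
})

test_that("parse_gff3 handles empty input and flags genes without 3' UTRs", {
  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  gm <- parse_gff3(empty)
  expect_equal(nrow(gm$genes), 0)

  no_utr <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t300\t.\t+\t.\tID=gA",
    "chr1\tt\tmRNA\t1\t300\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tt\tCDS\t1\t300\t.\t+\t0\tID=gA.t1.c;Parent=gA.t1"
  ), no_utr)
  gm <- parse_gff3(no_utr)
  expect_equal(gm$genes$utr3_length, 0)
  expect_false(gm$genes$has_utr3)
})

test_that("parse_gff3 reports malformed lines and orphan parents", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tt\tgene\t1\t100"), bad)
  expect_error(parse_gff3(bad), "line 3")

  orphan <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t1\t500\t.\t+\t.\tID=g1",
               "chr1\tt\tmRNA\t1\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr1\tt\tCDS\t1\t400\t.\t+\t0\tID=zz.c;Parent=ghost.t9"),
             orphan)
  expect_error(parse_gff3(orphan), "ghost\\.t9")
})

test_that("representative transcript policy picks longest or primary mRNA", {
  two_t <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t1000\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t1\t1000\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tt\tCDS\t1\t300\t.\t+\t0\tID=g1.t1.c;Parent=g1.t1",
    "chr1\tt\tmRNA\t1\t1000\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\tt\tCDS\t1\t600\t.\t+\t0\tID=g1.t2.c;Parent=g1.t2",
    "chr1\tt\tthree_prime_UTR\t601\t700\t.\t+\t.\tID=g1.t2.u;Parent=g1.t2"
  ), two_t)
  expect_equal(parse_gff3(two_t, "longest")$genes$transcript_id, "g1.t2")
  expect_equal(parse_gff3(two_t, "primary")$genes$transcript_id, "g1.t1")
})

test_that("feature_lengths sums split intervals and counts exclusions", {
  split_utr <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t1000\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t1\t1000\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tt\tCDS\t1\t500\t.\t+\t0\tID=g1.t1.c;Parent=g1.t1",
    "chr1\tt\tthree_prime_UTR\t501\t600\t.\t+\t.\tID=g1.t1.u3a;Parent=g1.t1",
    "chr1\tt\tthree_prime_UTR\t701\t779\t.\t+\t.\tID=g1.t1.u3b;Parent=g1.t1",
    "chr1\tt\tgene\t2001\t2500\t.\t+\t.\tID=g2",
    "chr1\tt\tmRNA\t2001\t2500\t.\t+\t.\tID=g2.t1;Parent=g2",
    "chr1\tt\tCDS\t2001\t2500\t.\t+\t0\tID=g2.t1.c;Parent=g2.t1"
  ), split_utr)
  gm <- parse_gff3(split_utr)
  fl <- feature_lengths(gm, "utr3")
  expect_equal(fl$gene_id, "g1")
  expect_equal(fl$length, 100 + 79)
  expect_equal(attr(fl, "n_excluded"), 1)
  expect_error(feature_lengths(gm, "promoter"))
})

test_that("length_histogram bins half-open intervals and conserves totals", {
  h <- length_histogram(c(50, 150, 150, 650), binsize = 100)
  expect_equal(h$count[h$bin_lo == 0], 1)
  expect_equal(h$count[h$bin_lo == 100], 2)
  expect_equal(h$count[h$bin_lo == 600], 1)
  expect_equal(sum(h$count), attr(h, "n_total"))

  h0 <- length_histogram(numeric(0))
  expect_equal(attr(h0, "n_total"), 0)
  expect_equal(sum(h0$count), 0)

  expect_error(length_histogram(c(10, -5)), "negative")
  expect_error(length_histogram(1:3, binsize = 0))

  set.seed(42)
  for (bs in c(1, 7, 100, 250)) {
    lens <- sample.int(2000, 500, replace = TRUE)
    expect_equal(sum(length_histogram(lens, bs)$count), 500)
  }
})

test_that("size classes partition lengths and agree with 100-bp histogram bins", {
  expect_equal(as.character(classify_length(c(34, 99))), c("short", "short"))
  expect_equal(as.character(classify_length(c(100, 600))), c("medium", "medium"))
  expect_equal(as.character(classify_length(c(601, 786))), c("long", "long"))
  expect_error(classify_length(0))

  set.seed(7)
  lens <- c(99, 100, 600, 601, sample.int(1500, 400, replace = TRUE))
  cls <- classify_length(lens)
  expect_equal(sum(table(cls)), length(lens))
  h <- length_histogram(lens, 100)
  expect_equal(sum(h$count[h$bin_hi <= 100]), sum(cls == "short"))
  expect_equal(sum(h$count[h$bin_lo >= 600]) - sum(lens == 600),
               sum(cls == "long"))
})

test_that("intergenic distances use the stated convention and are order independent", {
  gm <- parse_gff3(write_two_gene_gff3())
  d_span <- intergenic_distances(gm, "span_to_span")
  expect_equal(d_span$distance, 5001 - 1200 - 1)
  d_utr <- intergenic_distances(gm, "utr_to_utr")
  # upstream gene's last UTR ends at 1200; downstream gene's first UTR starts 5001
  expect_equal(d_utr$distance, 5001 - 1200 - 1)

  gm_rev <- parse_gff3(write_two_gene_gff3(reversed = TRUE))
  expect_equal(intergenic_distances(gm_rev, "utr_to_utr"),
               intergenic_distances(gm, "utr_to_utr"))

  # explicit boundary fixture: upstream feature ends 1000, downstream starts 1501
  fx <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t1000\t.\t+\t.\tID=a",
    "chr1\tt\tmRNA\t1\t1000\t.\t+\t.\tID=a.t;Parent=a",
    "chr1\tt\tCDS\t1\t1000\t.\t+\t0\tID=a.c;Parent=a.t",
    "chr1\tt\tgene\t1501\t2000\t.\t+\t.\tID=b",
    "chr1\tt\tmRNA\t1501\t2000\t.\t+\t.\tID=b.t;Parent=b",
    "chr1\tt\tCDS\t1501\t2000\t.\t+\t0\tID=b.c;Parent=b.t"
  ), fx)
  expect_equal(intergenic_distances(parse_gff3(fx), "span_to_span")$distance, 500)

  # a single gene on a scaffold yields no pairs
  single <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr9\tt\tgene\t1\t100\t.\t+\t.\tID=s1",
               "chr9\tt\tmRNA\t1\t100\t.\t+\t.\tID=s1.t;Parent=s1",
               "chr9\tt\tCDS\t1\t100\t.\t+\t0\tID=s1.c;Parent=s1.t"), single)
  expect_equal(nrow(intergenic_distances(parse_gff3(single))), 0)
})

test_that("summarize_lengths uses the lower-middle median convention", {
  expect_equal(summarize_lengths(681)$median, 681)
  expect_equal(summarize_lengths(c(1, 2, 3, 4))$median, 2)
  expect_equal(summarize_lengths(c(1, 2, 3, 4),
                                 median_convention = "interpolate")$median, 2.5)
  s <- summarize_lengths(c(500, 1500, 2500), threshold = 1000)
  expect_equal(s$fraction_above, 2 / 3)
  expect_error(summarize_lengths(numeric(0)))
})
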