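# GFF3 parsing, element derivation, BED round-trip.

write_gff <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  f <- file.path(dir, "test.gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("GFF3 hierarchy is read into gene models", {
  f <- write_gff(c(
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t1001\t1400\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\texon\t1601\t2000\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\tCDS\t1101\t1400\t.\t+\t.\tParent=g1.t1"))
  gm <- parse_gff(f)
  expect_length(gm, 1)
  g <- gm$g1
  expect_equal(g$start, 1000L)
  expect_equal(g$end, 2000L)
  expect_length(g$transcripts, 1)
  expect_equal(nrow(g$transcripts$g1.t1$exons), 2)
  expect_equal(nrow(g$transcripts$g1.t1$cds), 1)
})

test_that("orphan features are skipped and counted; multiple mRNAs attach", {
  f <- write_gff(c(
    "chr1\tsrc\tgene\t101\t500\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\tsrc\texon\t101\t500\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\texon\t101\t400\t.\t+\t.\tParent=g1.t2",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=missing.tx"))
  expect_message(gm <- parse_gff(f), "1 feature")
  expect_equal(attr(gm, "skipped"), 1L)
  expect_length(gm$g1$transcripts, 2)
})

test_that("malformed lines fail with line number; transcript-less gene warns", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tsrc\tgene\t1\t100"), f)
  expect_error(parse_gff(f), "line 3")
  f2 <- write_gff("chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=lonely", dir)
  expect_warning(gm <- parse_gff(f2), "no transcripts")
  expect_length(gm$lonely$transcripts, 0)
})

simple_gene <- function(strand = "+") {
  # 1-based [1001..2000]; exon = whole gene; CDS 1-based [1101..1900]
  f <- write_gff(c(
    sprintf("chr1\tsrc\tgene\t1001\t2000\t.\t%s\t.\tID=g1", strand),
    sprintf("chr1\tsrc\tmRNA\t1001\t2000\t.\t%s\t.\tID=g1.t1;Parent=g1", strand),
    sprintf("chr1\tsrc\texon\t1001\t2000\t.\t%s\t.\tParent=g1.t1", strand),
    sprintf("chr1\tsrc\tCDS\t1101\t1900\t.\t%s\t.\tParent=g1.t1", strand)),
    dir = withr::local_tempdir(.local_envir = parent.frame()))
  parse_gff(f)$g1
}

test_that("UTRs are derived from exon minus CDS and flanks tile 10 x 100 bp", {
  g <- simple_gene("+")
  el <- derive_elements(g, upstream_bins = 10, bin_width = 100,
                        chrom_length = 5000)
  u5 <- el[el$type == "UTR5", ]
  u3 <- el[el$type == "UTR3", ]
  expect_equal(c(u5$start, u5$end), c(1000L, 1100L))
  expect_equal(c(u3$start, u3$end), c(1900L, 2000L))
  up <- el[el$type == "upstream", ]
  expect_equal(nrow(up), 10)
  expect_equal(sort(up$start), seq(0L, 900L, by = 100L))
  expect_equal(up$start[up$rank == 1], 900L)  # nearest bin first
  dn <- el[el$type == "downstream", ]
  expect_equal(sort(dn$start), seq(2000L, 2900L, by = 100L))
  expect_true(all(el$start >= 0 & el$end <= 5000))
})

test_that("flipping the strand mirrors the element roles", {
  # this gene's layout is symmetric about its midpoint within [0, 3000), so
  # the minus-strand version must carry the same intervals with 5'/3' and
  # up/downstream roles swapped, and exon ranks reversed
  ep <- derive_elements(simple_gene("+"), 10, 100, 3000)
  em <- derive_elements(simple_gene("-"), 10, 100, 3000)
  swap <- c(UTR5 = "UTR3", UTR3 = "UTR5", upstream = "downstream",
            downstream = "upstream", gene = "gene", exon = "exon", CDS = "CDS")
  expect_setequal(paste(ep$start, ep$end, swap[ep$type]),
                  paste(em$start, em$end, em$type))
})

test_that("identical exon intervals from different transcripts consolidate", {
  f <- write_gff(c(
    "chr1\tsrc\tgene\t101\t700\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t700\t.\t+\t.\tID=tA;Parent=g1",
    "chr1\tsrc\tmRNA\t101\t500\t.\t+\t.\tID=tB;Parent=g1",
    "chr1\tsrc\texon\t101\t300\t.\t+\t.\tParent=tA",
    "chr1\tsrc\texon\t101\t300\t.\t+\t.\tParent=tB",
    "chr1\tsrc\texon\t401\t700\t.\t+\t.\tParent=tA"))
  g <- parse_gff(f)$g1
  el <- derive_elements(g, upstream_bins = 0, chrom_length = 1000)
  shared <- el[el$type == "exon" & el$start == 100, ]
  expect_equal(nrow(shared), 1)
  expect_equal(shared$transcripts, "tA,tB")
  expect_false(any(duplicated(el[, c("start", "end", "type")])))
})

test_that("flank bins truncate at chromosome edges, never negative", {
  f <- write_gff(c(
    "chr1\tsrc\tgene\t51\t250\t.\t-\t.\tID=g1",
    "chr1\tsrc\tmRNA\t51\t250\t.\t-\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t51\t250\t.\t-\t.\tParent=g1.t1"))
  g <- parse_gff(f)$g1
  el <- derive_elements(g, upstream_bins = 3, bin_width = 100,
                        chrom_length = 1000)
  # downstream of a minus-strand gene lies at lower coordinates: only the
  # 50 bp before the gene start exist
  dn <- el[el$type == "downstream", ]
  expect_equal(nrow(dn), 1)
  expect_equal(c(dn$start, dn$end), c(0L, 50L))
  expect_true(all(el$start >= 0))
  up <- el[el$type == "upstream", ]
  expect_equal(nrow(up), 3)
})

test_that("derivation is idempotent under re-consolidation and in bounds", {
  g <- simple_gene("+")
  for (bins in c(0, 5, 10)) {
    el <- derive_elements(g, bins, 100, 3000)
    expect_false(any(duplicated(el[, c("start", "end", "type", "parent")])))
    expect_true(all(el$end > el$start))
    flank <- el[el$type %in% c("upstream", "downstream"), ]
    expect_lte(sum(flank$end - flank$start), 2 * bins * 100)
  }
})

test_that("BED grouping, rejection, and as_gene typing work", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "t.bed")
  writeLines(c("chr1\t100\t200\tR1", "chr1\t300\t380\tR1",
               "chr1\t500\t520\tR1", "chr2\t10\t90\tR2",
               "chr2\t50\t40\tbadrow"), bed)
  expect_message(el <- read_bed(bed), "1 BED row")
  r1 <- el[el$parent == "R1" & el$type == "custom", ]
  expect_equal(r1$rank, 1:3)
  expect_equal(nrow(el[el$parent == "R1" & el$type == "region", ]), 1)
  expect_false("badrow" %in% el$parent)

  suppressMessages(elg <- read_bed(bed, as_gene = TRUE))
  expect_true(all(elg$type[elg$parent == "R1"] %in% c("gene", "exon")))
  expect_equal(sum(elg$type == "exon" & elg$parent == "R1"), 3)
})

test_that("BED write/read round-trips the element multiset", {
  g <- simple_gene("+")
  el <- derive_elements(g, 10, 100, 3000)
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "rt.bed")
  write_bed(el, bed)
  expect_equal(length(readLines(bed)), nrow(el))
  back <- read_bed(bed)
  expect_setequal(paste(back$chrom, back$start, back$end, back$type, back$parent),
                  paste(el$chrom, el$start, el$end, el$type, el$parent))

  # empty input writes an empty file
  empty <- el[0, ]
  f2 <- file.path(dir, "empty.bed")
  write_bed(empty, f2)
  expect_equal(length(readLines(f2)), 0)
})
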