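# Depth computation, coverage fractions, representative transcripts,
# neighbor merging, profile construction.

test_that("region depth counts spanning reads and empty regions", {
  reads <- data.frame(start = rep(100L, 3), end = rep(150L, 3))
  bam <- make_bam(reads)
  expect_equal(region_depth(bam, "chr1", 100, 150), rep(3L, 50))
  expect_equal(region_depth(bam, "chr1", 500, 550), rep(0L, 50))
  expect_warning(d <- region_depth(bam, "chrX", 0, 10), "absent")
  expect_equal(d, rep(0L, 10))
})

test_that("depth matches the brute-force pileup oracle (BAM and table)", {
  set.seed(7)
  for (i in 1:5) {
    n <- 40
    starts <- sample(0:900, n, replace = TRUE)
    reads <- data.frame(start = starts, end = starts + sample(20:80, n, TRUE))
    expected <- oracle_depth(reads, 0, 1000)
    bam <- make_bam(reads, chrom_len = 2000L)
    expect_equal(region_depth(bam, "chr1", 0, 1000), expected)
    tab <- make_depth_table(expected)
    expect_equal(region_depth(tab, "chr1", 0, 1000), expected)
  }
})

test_that("coverage_fraction counts covered bases at min_depth", {
  expect_equal(coverage_fraction(rep(5L, 10)), 1.0)
  d <- c(rep(2L, 37), rep(0L, 63))
  expect_equal(coverage_fraction(d), 0.37)
  expect_equal(coverage_fraction(rep(3L, 20), min_depth = 5), 0.0)
  expect_error(coverage_fraction(integer(0)), "zero-length")
  # monotone non-increasing in min_depth
  d2 <- sample(0:10, 200, replace = TRUE)
  fr <- vapply(1:10, function(m) coverage_fraction(d2, m), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

fake_gene <- function(cds_lens = c(300, 600)) {
  txs <- lapply(seq_along(cds_lens), function(i) {
    len <- cds_lens[i]
    list(transcript_id = c("tA", "tB", "tC")[i],
         exons = cbind(start = 0L, end = len + 100L),
         cds = cbind(start = 50L, end = 50L + len),
         utr5 = cbind(start = integer(0), end = integer(0)),
         utr3 = cbind(start = integer(0), end = integer(0)))
  })
  names(txs) <- vapply(txs, `[[`, "", "transcript_id")
  structure(list(gene_id = "g", chrom = "chr1", start = 0L,
                 end = max(cds_lens) + 100L, strand = "+",
                 transcripts = txs), class = "gene_model")
}

test_that("representative transcript selection is deterministic", {
  g <- fake_gene(c(300, 600))
  expect_equal(select_representative(g, "longest_cds"), "tB")
  g2 <- fake_gene(c(400, 400))
  expect_equal(select_representative(g2, "longest_cds"), "tA")  # tie -> lexicographic
  expect_setequal(select_representative(fake_gene(c(1, 2, 3)), "all"),
                  c("tA", "tB", "tC"))
  expect_length(select_representative(g, "gene_body"), 0)
  expect_error(select_representative(g, "highest_coverage"), "coverage")
  expect_equal(select_representative(g, "highest_coverage",
                                     coverages = c(tA = 0.9, tB = 0.3)), "tA")
})

test_that("equal-coverage neighbors merge and merging is idempotent", {
  vals <- rbind(c(0.5, 1.0), c(0.5, 1.0), c(0.2, 1.0))
  info <- data.frame(element_id = paste0("g:exon:", 1:3), chrom = "chr1",
                     start = c(0L, 100L, 200L), end = c(100L, 200L, 300L),
                     type = "exon", parent = "g", transcripts = "",
                     rank = 1:3, strand = "+", stringsAsFactors = FALSE)
  colnames(vals) <- c("s1", "s2")
  prof <- pavkit:::new_profile(info, vals, list(min_depth = 1))
  m <- merge_equal_neighbors(prof)
  expect_equal(nrow(m$values), 2)
  expect_equal(m$info$rank[1], "1-2")
  expect_equal(m$info$start[1], 0L)
  expect_equal(m$info$end[1], 200L)

  # differing in one sample only -> no merge
  vals2 <- rbind(c(0.5, 1.0), c(0.5, 0.9))
  prof2 <- pavkit:::new_profile(info[1:2, ], vals2, list())
  expect_equal(nrow(merge_equal_neighbors(prof2)$values), 2)

  # idempotence on random fixtures
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    v <- matrix(round(sample(c(0, 0.5, 1), n * 3, TRUE), 4), n, 3,
                dimnames = list(NULL, paste0("s", 1:3)))
    inf <- data.frame(element_id = paste0("g:exon:", 1:n), chrom = "chr1",
                      start = (0:(n - 1)) * 100L, end = (1:n) * 100L,
                      type = "exon", parent = "g", transcripts = "",
                      rank = 1:n, strand = "+", stringsAsFactors = FALSE)
    p1 <- merge_equal_neighbors(pavkit:::new_profile(inf, v, list()))
    p2 <- merge_equal_neighbors(p1)
    expect_equal(p1$info$element_id, p2$info$element_id)
    expect_equal(unname(p1$values), unname(p2$values))
  }
})

test_that("profiles have matched shapes and planted deletions read as zero", {
  sim <- shared_cohort()
  prof <- build_profile(sim$elements, sim$samples)
  expect_equal(ncol(prof$region$values), length(sim$samples))
  expect_equal(ncol(prof$element$values), length(sim$samples))
  expect_equal(nrow(prof$region$values), sum(sim$elements$type == "gene"))
  expect_true(all(prof$element$values >= 0 & prof$element$values <= 1))

  # whole-gene deletions give coverage 0 on the gene row
  del_cells <- which(sim$truth == 0 &
                     grepl(":gene:1$", rownames(sim$truth)), arr.ind = TRUE)
  expect_gt(nrow(del_cells), 0)
  for (k in seq_len(min(5, nrow(del_cells)))) {
    rid <- rownames(sim$truth)[del_cells[k, 1]]
    sid <- colnames(sim$truth)[del_cells[k, 2]]
    expect_equal(unname(prof$region$values[rid, sid]), 0)
  }
  # untouched genes read as exactly 1 under deterministic tiling
  expect_true(any(prof$region$values == 1))
})

test_that("gene-region coverage is bracketed by element coverages when tiled", {
  # elements that tile the parent exactly: 2 custom intervals under a region
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "r.bed")
  writeLines(c("chr1\t0\t100\tR1", "chr1\t100\t200\tR1"), bed)
  el <- read_bed(bed)
  depth <- c(rep(1L, 60), rep(0L, 140))
  tab <- make_depth_table(depth, dir = dir)
  prof <- build_profile(el, c(s1 = tab))
  reg <- prof$region$values["R1:region:1", "s1"]
  elv <- prof$element$values[, "s1"]
  expect_gte(reg, min(elv))
  expect_lte(reg, max(elv))
  expect_equal(unname(reg), 0.3)  # union-based aggregate: 60 of 200 bases
})

test_that("profile TSVs are deterministic and round-trip", {
  sim <- shared_cohort()
  prof <- build_profile(sim$elements, sim$samples)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "p1.tsv"); f2 <- file.path(dir, "p2.tsv")
  write_profile(prof$element, f1)
  prof_again <- build_profile(sim$elements, sim$samples)
  write_profile(prof_again$element, f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- read_profile(f1)
  expect_equal(unname(back$values), unname(prof$element$values))
  expect_equal(back$info$element_id, prof$element$info$element_id)
  expect_equal(back$meta$min_depth, 1)
})

test_that("unreadable sample input aborts with the offending file named", {
  sim <- shared_cohort()
  bad <- c(sim$samples, ghost = "/nonexistent/ghost.bam")
  expect_error(build_profile(sim$elements, bad), "ghost.bam")
})
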