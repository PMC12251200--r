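# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use different algorithms (per-base
# stabbing counts, factorial-formula enumeration, combn permutation) from
# the code under test.

# Per-base depth by interval stabbing: reads is a data.frame of aligned
# blocks (start, end), 0-based half-open.
oracle_depth <- function(reads, start, end) {
  depth <- integer(end - start)
  for (i in seq_len(nrow(reads))) {
    s <- max(reads$start[i], start)
    e <- min(reads$end[i], end)
    if (e > s) {
      idx <- (s - start + 1L):(e - start)
      depth[idx] <- depth[idx] + 1L
    }
  }
  depth
}

# Exact two-sided Fisher p by enumerating every table with the observed
# margins; table probability from the factorial formula
# P = (prod r_i!)(prod c_j!) / (N! prod x_ij!).
oracle_fisher <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) return(1)
  lp <- function(x1) {
    x2 <- cs - x1
    if (any(x2 < 0)) return(-Inf)
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
      sum(lfactorial(c(x1, x2)))
  }
  # enumerate first-row vectors summing to rs[1], bounded by column margins
  k <- length(cs)
  rows <- list(integer(0))
  for (j in seq_len(k - 1L)) {
    rows <- unlist(lapply(rows, function(r) {
      lapply(0:min(cs[j], rs[1] - sum(r)), function(v) c(r, v))
    }), recursive = FALSE)
  }
  rows <- lapply(rows, function(r) c(r, rs[1] - sum(r)))
  rows <- Filter(function(r) r[k] >= 0 && r[k] <= cs[k], rows)
  lps <- vapply(rows, lp, numeric(1))
  lp_obs <- lp(tab[1, ])
  sum(exp(lps[lps <= lp_obs + log1p(1e-7)]))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of the C(N, n1)
# assignments of the pooled midranks to group 1; p = 2 * min(tails).
oracle_wilcoxon <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(r), n1)
  ws <- apply(sets, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Exhaustive mean pan/core over all subsets of size n of the PAV columns.
oracle_growth <- function(vals, n) {
  vals <- vals[rowSums(vals) > 0, , drop = FALSE]
  sets <- utils::combn(ncol(vals), n)
  pan <- apply(sets, 2, function(idx)
    sum(rowSums(vals[, idx, drop = FALSE]) > 0))
  core <- apply(sets, 2, function(idx)
    sum(rowSums(vals[, idx, drop = FALSE]) == length(idx)))
  c(pan = mean(pan), core = mean(core))
}

# Minimal profile/PAV constructors for fixtures built in code.
make_info <- function(n, type = "gene", chrom = "chr1", width = 100L) {
  data.frame(
    element_id = paste0("r", seq_len(n), ":", type, ":1"),
    chrom = chrom, start = (seq_len(n) - 1L) * width * 2L,
    end = (seq_len(n) - 1L) * width * 2L + width,
    type = type, parent = paste0("r", seq_len(n)), transcripts = "",
    rank = 1L, strand = "+", stringsAsFactors = FALSE)
}

make_profile <- function(values, type = "gene") {
  info <- make_info(nrow(values), type)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  pavkit:::new_profile(info, values, list(min_depth = 1))
}

make_pav <- function(values, type = "gene") {
  info <- make_info(nrow(values), type)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  pavkit:::new_pav(info, values, list(method = "fixed", threshold = 0.5))
}

# Write a tiny SAM and convert to a sorted+indexed BAM; reads is a
# data.frame (start, end) of 0-based half-open full-match alignments.
make_bam <- function(reads, chrom = "chr1", chrom_len = 10000L,
                     dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "reads.sam")
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  for (i in seq_len(nrow(reads))) {
    len <- reads$end[i] - reads$start[i]
    lines <- c(lines, sprintf("r%04d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                              i, chrom, reads$start[i] + 1L, len,
                              strrep("A", len)))
  }
  writeLines(lines, sam)
  bam0 <- Rsamtools::asBam(sam, file.path(dir, "unsorted"),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, file.path(dir, "reads"))
  Rsamtools::indexBam(bam)
  bam
}

# Write a depth table (chrom, 1-based pos, depth) from a depth vector
# starting at 0-based position `offset`.
make_depth_table <- function(depth, chrom = "chr1", offset = 0L,
                             dir = withr::local_tempdir(.local_envir = parent.frame())) {
  f <- file.path(dir, "depth.tsv")
  pos <- which(depth > 0)
  utils::write.table(
    data.frame(chrom, offset + pos, depth[pos]), f,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  f
}

# A single synthetic cohort shared across test files (generated once per
# test run; deterministic tiling, depth-table mode).
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "pavkit-shared-cohort")
      spec <- cohort_spec(n_samples = 8, n_genes = 10, seed = 101)
      cache <<- sim_cohort(spec, dir)
    }
    cache
  }
})
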