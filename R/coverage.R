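# Coverage computation from BAM files or per-base depth tables.
#
# "Coverage" of a region is the fraction of its bases supported by at least
# `min_depth` aligned bases. Aligned support comes from CIGAR M/=/X blocks
# only: bases under read deletions (D) and splice gaps (N) do not count.

.default_bam_flag <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE,
                         isDuplicate = FALSE,
                         isNotPassingQualityControls = FALSE)
}

# Per-chromosome depth as an RleList from one sample's alignments or depth
# table. Depth tables are 3-column TSV (chrom, 1-based position, depth);
# positions absent from the table have depth 0.
.sample_coverage <- function(path, mapq_min = 0L) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    param <- Rsamtools::ScanBamParam(flag = .default_bam_flag(),
                                     mapqFilter = mapq_min)
    gal <- GenomicAlignments::readGAlignments(path, param = param)
    grl <- GenomicAlignments::grglist(gal, drop.D.ranges = TRUE)
    cov <- GenomicRanges::coverage(unlist(grl, use.names = FALSE))
    return(cov)
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos", "depth"))
  res <- lapply(split(dt, by = "chrom", keep.by = TRUE), function(d) {
    v <- integer(max(d$pos))
    v[d$pos] <- as.integer(d$depth)
    S4Vectors::Rle(v)
  })
  IRanges::RleList(res, compress = FALSE)
}

.pad_rle <- function(r, len) {
  if (length(r) >= len) return(r)
  c(r, S4Vectors::Rle(0L, len - length(r)))
}

#' Per-base depth over one region
#'
#' Computes the per-base sequencing depth across a region from a
#' coordinate-sorted, indexed BAM file (counting mapped, primary,
#' non-duplicate, non-QC-fail reads with MAPQ >= `mapq_min`; aligned blocks
#' only, so deletions and splice gaps contribute nothing) or from a 3-column
#' depth table (chrom, 1-based position, depth).
#'
#' @param path BAM or depth-table path.
#' @param chrom Chromosome name.
#' @param start,end Region coordinates, 0-based half-open.
#' @param mapq_min Minimum mapping quality (BAM only).
#' @return Integer vector of length `end - start`. If the chromosome is
#'   absent from the input, an all-zero vector with a warning.
#' @export
region_depth <- function(path, chrom, start, end, mapq_min = 0L) {
  stopifnot(end > start)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
    if (!chrom %in% names(hdr)) {
      warning("chromosome ", chrom, " absent from BAM header; returning zeros")
      return(integer(end - start))
    }
    which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
    param <- Rsamtools::ScanBamParam(flag = .default_bam_flag(),
                                     mapqFilter = mapq_min, which = which)
    gal <- GenomicAlignments::readGAlignments(path, param = param)
    grl <- GenomicAlignments::grglist(gal, drop.D.ranges = TRUE)
    cov <- GenomicRanges::coverage(unlist(grl, use.names = FALSE))
    r <- if (chrom %in% names(cov)) .pad_rle(cov[[chrom]], end) else S4Vectors::Rle(0L, end)
    return(as.integer(S4Vectors::window(r, start + 1L, end)))
  }
  cov <- .sample_coverage(path)
  if (!chrom %in% names(cov)) {
    warning("chromosome ", chrom, " absent from depth table; returning zeros")
    return(integer(end - start))
  }
  as.integer(S4Vectors::window(.pad_rle(cov[[chrom]], end), start + 1L, end))
}

#' Coverage fraction of a depth vector
#'
#' @param depth Non-negative integer vector of per-base depths.
#' @param min_depth A base counts as covered when its depth is at least this.
#' @return Fraction of covered bases in `[0, 1]`.
#' @export
coverage_fraction <- function(depth, min_depth = 1L) {
  if (!length(depth)) stop("zero-length region")
  if (min_depth < 1) stop("min_depth must be >= 1")
  mean(depth >= min_depth)
}

#' Select representative transcripts for a gene
#'
#' @param gene A gene model.
#' @param mode One of `longest_cds`, `longest_exon`, `longest_transcript`,
#'   `highest_coverage`, `all`, `gene_body`. The four single-transcript modes
#'   break ties by lexicographically smallest transcript id; `all` keeps
#'   every transcript and `gene_body` keeps none (gene-body-only analysis).
#' @param coverages Named numeric vector of per-transcript coverage scores,
#'   required for `highest_coverage`.
#' @return Character vector of selected transcript ids (possibly empty).
#' @export
select_representative <- function(gene,
                                  mode = c("longest_cds", "longest_exon",
                                           "longest_transcript",
                                           "highest_coverage", "all", "gene_body"),
                                  coverages = NULL) {
  mode <- match.arg(mode)
  txs <- gene$transcripts
  ids <- names(txs)
  if (mode == "all") return(ids)
  if (mode == "gene_body") return(character(0))
  if (!length(ids)) return(character(0))
  metric <- switch(mode,
    longest_cds = vapply(txs, function(t) sum(t$cds[, 2] - t$cds[, 1]), numeric(1)),
    longest_exon = vapply(txs, function(t) sum(t$exons[, 2] - t$exons[, 1]), numeric(1)),
    longest_transcript = vapply(txs, function(t) {
      if (nrow(t$exons)) max(t$exons[, 2]) - min(t$exons[, 1]) else 0
    }, numeric(1)),
    highest_coverage = {
      if (is.null(coverages)) {
        stop("highest_coverage requires per-transcript coverages; compute coverage first")
      }
      cv <- coverages[ids]
      cv[is.na(cv)] <- -Inf
      cv
    })
  best <- which(metric == max(metric))
  ids[best][order(ids[best])][1]
}

#' Coverage profile constructor
#' @param info Element table rows describing the profile rows.
#' @param values Numeric matrix, rows matching `info`, columns = samples.
#' @param meta List of provenance fields.
#' @param depth Optional matrix of per-element mean depths, same shape.
#' @return A `CoverageProfile` object.
#' @keywords internal
new_profile <- function(info, values, meta = list(), depth = NULL) {
  stopifnot(nrow(info) == nrow(values))
  rownames(values) <- info$element_id
  if (!is.null(depth)) rownames(depth) <- info$element_id
  structure(list(info = info, values = values, depth = depth, meta = meta),
            class = "CoverageProfile")
}

#' @export
print.CoverageProfile <- function(x, ...) {
  cat(sprintf("CoverageProfile: %d regions x %d samples (min_depth=%s)\n",
              nrow(x$values), ncol(x$values),
              x$meta$min_depth %||% 1))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build region- and element-level coverage profiles
#'
#' For every element row and sample, computes the fraction of bases covered
#' at depth >= `min_depth` and the mean per-base depth. Parent rows of type
#' `gene` are evaluated over the gene span; parent rows of type `region`
#' (general BED targets) are aggregated over their member intervals, so gaps
#' between discontinuous intervals do not dilute the coverage.
#'
#' @param elements Element table from [gff_elements()] or [read_bed()].
#' @param samples Named character vector: sample id -> BAM path or 3-column
#'   depth-table path.
#' @param min_depth Minimum depth for a base to count as covered.
#' @param mapq_min Minimum mapping quality (BAM inputs).
#' @param precision Coverage fractions are rounded to this many decimals.
#' @return List with `region` and `element` [CoverageProfile][new_profile]
#'   objects sharing the same sample columns.
#' @export
build_profile <- function(elements, samples, min_depth = 1L, mapq_min = 0L,
                          precision = 4L) {
  stopifnot(nrow(elements) > 0, length(samples) >= 1)
  if (is.null(names(samples))) {
    names(samples) <- sub("\\.(bam|tsv|txt|depth)$", "", basename(samples))
  }
  missing <- !file.exists(samples)
  if (any(missing)) {
    stop("unreadable sample input(s): ", paste(samples[missing], collapse = ", "))
  }

  n <- nrow(elements)
  covered <- matrix(0, n, length(samples),
                    dimnames = list(elements$element_id, names(samples)))
  depthsum <- covered
  width <- elements$end - elements$start

  for (s in seq_along(samples)) {
    cov <- .sample_coverage(samples[[s]], mapq_min)
    for (ch in unique(elements$chrom)) {
      sel <- which(elements$chrom == ch)
      maxend <- max(elements$end[sel])
      r <- if (ch %in% names(cov)) .pad_rle(cov[[ch]], maxend) else S4Vectors::Rle(0L, maxend)
      ir <- IRanges::IRanges(elements$start[sel] + 1L, elements$end[sel])
      covered[sel, s] <- IRanges::viewSums(IRanges::Views(r >= min_depth, ir))
      depthsum[sel, s] <- IRanges::viewSums(IRanges::Views(r, ir))
    }
  }

  # aggregate "region" parents over their member intervals
  region_rows <- which(elements$type == "region")
  for (i in region_rows) {
    pid <- elements$parent[i]
    mem <- which(elements$parent == pid & !.is_parent_type(elements$type))
    if (length(mem)) {
      covered[i, ] <- colSums(covered[mem, , drop = FALSE])
      depthsum[i, ] <- colSums(depthsum[mem, , drop = FALSE])
      width[i] <- sum(width[mem])
    }
  }

  frac <- round(sweep(covered, 1, width, "/"), precision)
  mdep <- round(sweep(depthsum, 1, width, "/"), precision)
  meta <- list(min_depth = min_depth, mapq_min = mapq_min,
               precision = precision)

  is_parent <- .is_parent_type(elements$type)
  list(
    region = new_profile(elements[is_parent, , drop = FALSE],
                         frac[is_parent, , drop = FALSE], meta,
                         mdep[is_parent, , drop = FALSE]),
    element = new_profile(elements[!is_parent, , drop = FALSE],
                          frac[!is_parent, , drop = FALSE], meta,
                          mdep[!is_parent, , drop = FALSE])
  )
}

#' Merge rank-adjacent elements with equal coverage
#'
#' Within each (parent, type) run of rank-ordered elements, maximal runs
#' whose coverage vectors are equal in every sample (after rounding to
#' `precision` decimals) collapse into one element spanning min(start) to
#' max(end), with a concatenated rank label such as `"2-4"`. Idempotent.
#'
#' @param profile An element-level `CoverageProfile`.
#' @param precision Decimals at which coverage vectors are compared.
#' @return A merged `CoverageProfile` (ranks become character labels).
#' @export
merge_equal_neighbors <- function(profile, precision = 4L) {
  info <- profile$info
  vals <- round(profile$values, precision)
  keep <- logical(0)
  out_info <- list(); out_vals <- list(); out_depth <- list()
  grp <- paste(info$parent, info$type, sep = "\r")
  for (g in unique(grp)) {
    sel <- which(grp == g)
    sel <- sel[order(suppressWarnings(as.numeric(sub("-.*", "", info$rank[sel]))))]
    run_start <- 1L
    runs <- list()
    if (length(sel) > 1) {
      for (k in 2:length(sel)) {
        if (!isTRUE(all(vals[sel[k], ] == vals[sel[k - 1L], ]))) {
          runs[[length(runs) + 1L]] <- sel[run_start:(k - 1L)]
          run_start <- k
        }
      }
    }
    runs[[length(runs) + 1L]] <- sel[run_start:length(sel)]
    for (r in runs) {
      first <- r[1]
      row <- info[first, , drop = FALSE]
      row$start <- min(info$start[r])
      row$end <- max(info$end[r])
      rk <- as.character(info$rank[r])
      row$rank <- if (length(r) > 1) {
        paste0(sub("-.*", "", rk[1]), "-", sub(".*-", "", rk[length(rk)]))
      } else rk
      tx <- sort(unique(unlist(strsplit(info$transcripts[r], ","))))
      row$transcripts <- paste(tx[nzchar(tx)], collapse = ",")
      out_info[[length(out_info) + 1L]] <- row
      out_vals[[length(out_vals) + 1L]] <- profile$values[first, , drop = FALSE]
      if (!is.null(profile$depth)) {
        out_depth[[length(out_depth) + 1L]] <- profile$depth[first, , drop = FALSE]
      }
    }
  }
  info2 <- do.call(rbind, out_info)
  info2$element_id <- paste(info2$parent, info2$type, info2$rank, sep = ":")
  vals2 <- do.call(rbind, out_vals)
  depth2 <- if (length(out_depth)) do.call(rbind, out_depth) else NULL
  meta <- profile$meta
  meta$merged <- TRUE
  new_profile(info2, vals2, meta, depth2)
}

#' Write a coverage profile as TSV
#'
#' The format is: `#` comment lines holding provenance metadata, then a
#' header row, row metadata columns and one column per sample.
#'
#' @param profile A `CoverageProfile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(profile$meta)) {
    writeLines(sprintf("#%s=%s", k, profile$meta[[k]]), con)
  }
  df <- cbind(profile$info, as.data.frame(profile$values, check.names = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coverage profile written by [write_profile()]
#' @param path TSV path.
#' @return A `CoverageProfile`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- strsplit(sub("^#", "", m), "=", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(kv[2]))
    meta[[kv[1]]] <- if (is.na(v)) kv[2] else v
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("element_id", "chrom", "start", "end", "type",
                           "parent", "transcripts", "rank", "strand", "split"),
                         names(df))
  info <- df[, meta_cols, drop = FALSE]
  info$transcripts[is.na(info$transcripts)] <- ""
  vals <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  new_profile(info, vals, meta)
}
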