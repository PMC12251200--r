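# Annotation handling: GFF3 -> gene models -> element tables -> BED.
#
# Coordinate convention: GFF3 is read 1-based inclusive and converted once,
# at the parsing boundary, to 0-based half-open. Everything downstream
# (element tables, BED I/O, coverage) uses 0-based half-open coordinates.

#' Parse a GFF3 annotation into gene models
#'
#' Reads a GFF3 file with the standard gene / mRNA (or transcript) /
#' exon-CDS-UTR hierarchy linked through `ID`/`Parent` attributes and returns
#' one gene model per `gene` feature. Child features whose `Parent` cannot be
#' resolved are counted and skipped with a message; genes without any
#' transcript produce a gene-body-only model with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of gene models (one per gene). Each model is a list
#'   with `gene_id`, `chrom`, `start`, `end` (0-based half-open), `strand`
#'   and `transcripts`, itself a named list of transcripts carrying `exons`,
#'   `cds`, `utr5`, `utr3` as two-column (start, end) integer matrices.
#'   The number of skipped orphan features is attached as attribute
#'   `"skipped"`.
#' @export
parse_gff <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1] - 1L)]
  body <- which(!grepl("^\\s*(#|$)", lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(nf != 9L)
  if (length(bad)) {
    stop(sprintf("malformed GFF3 at line %d: expected 9 tab-separated fields, found %d",
                 body[bad[1]], nf[bad[1]]))
  }

  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parents <- if (!is.null(gr$Parent)) as.list(gr$Parent) else
    replicate(length(gr), character(0), simplify = FALSE)

  feat <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    id = ids,
    stringsAsFactors = FALSE
  )
  # expand multi-parent children (e.g. exons shared between transcripts)
  np <- pmax(lengths(parents), 1L)
  flat <- feat[rep(seq_len(nrow(feat)), np), , drop = FALSE]
  flat$parent <- unlist(lapply(parents, function(p) if (length(p)) p else NA_character_),
                        use.names = FALSE)

  gene_rows <- flat[flat$type == "gene", , drop = FALSE]
  gene_rows <- gene_rows[!duplicated(gene_rows$id), , drop = FALSE]
  if (!nrow(gene_rows)) stop("no gene features found in ", path)
  gene_rows$strand[!gene_rows$strand %in% c("+", "-")] <- "+"

  skipped <- 0L
  tx_rows <- flat[flat$type %in% c("mRNA", "transcript"), , drop = FALSE]
  orphan_tx <- !(tx_rows$parent %in% gene_rows$id)
  skipped <- skipped + sum(orphan_tx)
  tx_rows <- tx_rows[!orphan_tx, , drop = FALSE]

  child_types <- c(exon = "exon", CDS = "CDS",
                   five_prime_UTR = "UTR5", three_prime_UTR = "UTR3")
  ch_rows <- flat[flat$type %in% names(child_types), , drop = FALSE]
  orphan_ch <- !(ch_rows$parent %in% tx_rows$id)
  skipped <- skipped + sum(orphan_ch)
  ch_rows <- ch_rows[!orphan_ch, , drop = FALSE]
  ch_rows$slot <- unname(child_types[ch_rows$type])
  if (skipped > 0) {
    message(skipped, " feature(s) with unresolvable Parent skipped")
  }

  iv_mat <- function(df) {
    if (!nrow(df)) {
      return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
    }
    ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
    cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }

  models <- vector("list", nrow(gene_rows))
  names(models) <- gene_rows$id
  for (i in seq_len(nrow(gene_rows))) {
    g <- gene_rows[i, ]
    txs <- tx_rows[tx_rows$parent == g$id, , drop = FALSE]
    tlist <- list()
    for (j in seq_len(nrow(txs))) {
      tid <- txs$id[j]
      ch <- ch_rows[ch_rows$parent == tid, , drop = FALSE]
      tlist[[tid]] <- list(
        transcript_id = tid,
        exons = iv_mat(ch[ch$slot == "exon", , drop = FALSE]),
        cds = iv_mat(ch[ch$slot == "CDS", , drop = FALSE]),
        utr5 = iv_mat(ch[ch$slot == "UTR5", , drop = FALSE]),
        utr3 = iv_mat(ch[ch$slot == "UTR3", , drop = FALSE])
      )
    }
    if (!length(tlist)) {
      warning("gene ", g$id, " has no transcripts; gene-body-only model",
              call. = FALSE)
    }
    models[[g$id]] <- structure(
      list(gene_id = g$id, chrom = g$chrom, start = g$start, end = g$end,
           strand = g$strand, transcripts = tlist),
      class = "gene_model")
  }
  attr(models, "skipped") <- skipped
  models
}

#' Derive genic elements for one gene model
#'
#' Emits the gene body, per-transcript exons, CDS and UTR records, and
#' strand-aware upstream/downstream flanking bins. When a transcript carries
#' CDS but no explicit UTR features, UTRs are derived as exon minus CDS and
#' assigned 5'/3' relative to the strand. Records from different transcripts
#' with identical (start, end, type) are consolidated into one element whose
#' `transcripts` field lists every contributor. Ranks run 5' to 3' in gene
#' orientation for body elements (exon 1 of a minus-strand gene is the
#' rightmost); flanking bins are numbered nearest-to-gene = 1. Flanks are
#' clipped to `[0, chrom_length)` and dropped when clipping empties them.
#'
#' @param gene A gene model from [parse_gff()].
#' @param upstream_bins Number of flanking bins on each side.
#' @param bin_width Width of each flanking bin in bp.
#' @param chrom_length Chromosome length in bp (used to clip flanks);
#'   `Inf` disables right-side clipping.
#' @param transcripts Optional character vector of transcript ids to restrict
#'   element derivation to (e.g. a representative transcript).
#' @return An element table (data.frame, class `pav_elements`) with columns
#'   `element_id`, `chrom`, `start`, `end`, `type`, `parent`, `transcripts`,
#'   `rank`, `strand`; coordinates 0-based half-open.
#' @export
derive_elements <- function(gene, upstream_bins = 10L, bin_width = 100L,
                            chrom_length = Inf, transcripts = NULL) {
  stopifnot(inherits(gene, "gene_model"), gene$start < gene$end,
            gene$strand %in% c("+", "-"))
  if (chrom_length < gene$end) stop("chrom_length smaller than gene end")

  pb <- function(s, e, type, tx = NA_character_) {
    if (!length(s)) return(NULL)
    data.frame(start = as.numeric(s), end = as.numeric(e), type = type,
               tx = tx, dist_rank = NA_real_, stringsAsFactors = FALSE)
  }
  out <- list(pb(gene$start, gene$end, "gene"))

  txs <- gene$transcripts
  if (!is.null(transcripts)) txs <- txs[intersect(names(txs), transcripts)]
  for (t in txs) {
    if (nrow(t$exons)) out <- c(out, list(pb(t$exons[, 1], t$exons[, 2], "exon", t$transcript_id)))
    if (nrow(t$cds)) out <- c(out, list(pb(t$cds[, 1], t$cds[, 2], "CDS", t$transcript_id)))
    u5 <- t$utr5; u3 <- t$utr3
    if (!nrow(u5) && !nrow(u3) && nrow(t$cds) && nrow(t$exons)) {
      exr <- IRanges::IRanges(t$exons[, 1] + 1L, t$exons[, 2])
      cdr <- IRanges::IRanges(t$cds[, 1] + 1L, t$cds[, 2])
      dif <- IRanges::setdiff(exr, cdr)
      if (length(dif)) {
        before <- dif[IRanges::end(dif) < min(IRanges::start(cdr))]
        after <- dif[IRanges::start(dif) > max(IRanges::end(cdr))]
        if (gene$strand == "+") { u5r <- before; u3r <- after } else { u5r <- after; u3r <- before }
        u5 <- cbind(start = IRanges::start(u5r) - 1L, end = IRanges::end(u5r))
        u3 <- cbind(start = IRanges::start(u3r) - 1L, end = IRanges::end(u3r))
      }
    }
    if (nrow(u5)) out <- c(out, list(pb(u5[, 1], u5[, 2], "UTR5", t$transcript_id)))
    if (nrow(u3)) out <- c(out, list(pb(u3[, 1], u3[, 2], "UTR3", t$transcript_id)))
  }

  # flanking bins; bin i is the i-th bin counted away from the gene
  if (upstream_bins > 0 && bin_width > 0) {
    i <- seq_len(upstream_bins)
    left <- data.frame(start = gene$start - i * bin_width,
                       end = gene$start - (i - 1L) * bin_width, dist_rank = i)
    right <- data.frame(start = gene$end + (i - 1L) * bin_width,
                        end = gene$end + i * bin_width, dist_rank = i)
    left$type <- if (gene$strand == "+") "upstream" else "downstream"
    right$type <- if (gene$strand == "+") "downstream" else "upstream"
    for (fl in list(left, right)) {
      fl$start <- pmax(fl$start, 0)
      fl$end <- pmin(fl$end, chrom_length)
      fl <- fl[fl$end > fl$start, , drop = FALSE]
      if (nrow(fl)) {
        p <- pb(fl$start, fl$end, fl$type)
        p$dist_rank <- fl$dist_rank
        out <- c(out, list(p))
      }
    }
  }

  df <- do.call(rbind, out)

  # consolidate duplicates by (start, end, type), pooling transcript ids
  key <- paste(df$start, df$end, df$type, sep = "\r")
  txof <- vapply(split(df$tx, key), function(v) {
    v <- sort(unique(v[!is.na(v)]))
    paste(v, collapse = ",")
  }, character(1))
  cons <- df[!duplicated(key), , drop = FALSE]
  cons$transcripts <- unname(txof[paste(cons$start, cons$end, cons$type, sep = "\r")])

  # ranks: flanks by distance (nearest first), body elements 5'->3'
  cons$rank <- NA_integer_
  for (tp in unique(cons$type)) {
    sel <- which(cons$type == tp)
    if (tp %in% c("upstream", "downstream")) {
      ord <- order(cons$dist_rank[sel])
    } else {
      ord <- order(cons$start[sel], decreasing = (gene$strand == "-"))
    }
    cons$rank[sel[ord]] <- seq_along(sel)
  }
  cons$dist_rank <- NULL

  res <- data.frame(
    chrom = gene$chrom,
    start = as.integer(cons$start), end = as.integer(cons$end),
    type = cons$type, parent = gene$gene_id,
    transcripts = cons$transcripts, rank = cons$rank,
    strand = gene$strand, stringsAsFactors = FALSE)
  res <- res[order(match(res$type, .ELEMENT_TYPES), res$rank), , drop = FALSE]
  as_pav_elements(res)
}

#' Assemble an element table and assign element ids
#' @param df Data frame with element columns.
#' @return The data frame with class `pav_elements` and an `element_id` column.
#' @keywords internal
as_pav_elements <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "type", "parent", "rank", "strand") %in% names(df)))
  if (is.null(df$transcripts)) df$transcripts <- ""
  df$element_id <- paste(df$parent, df$type, df$rank, sep = ":")
  if (anyDuplicated(df$element_id)) stop("duplicate element ids")
  rownames(df) <- NULL
  df <- df[, c("element_id", "chrom", "start", "end", "type", "parent",
               "transcripts", "rank", "strand")]
  class(df) <- c("pav_elements", "data.frame")
  df
}

#' Derive elements for every gene in an annotation
#'
#' Convenience wrapper over [derive_elements()]: the gene-mode analogue of a
#' `gff2bed` step. Accepts a GFF3 path or a parsed gene-model list.
#'
#' @param genes GFF3 path or result of [parse_gff()].
#' @param upstream_bins,bin_width Flank layout (default 10 bins of 100 bp).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   flank clipping.
#' @param transcripts Optional named list: gene id -> transcript ids to keep
#'   (see [select_representative()]).
#' @return Combined element table for all genes.
#' @export
gff_elements <- function(genes, upstream_bins = 10L, bin_width = 100L,
                         chrom_lengths = NULL, transcripts = NULL) {
  if (is.character(genes)) genes <- parse_gff(genes)
  tabs <- lapply(genes, function(g) {
    cl <- if (!is.null(chrom_lengths) && g$chrom %in% names(chrom_lengths))
      chrom_lengths[[g$chrom]] else Inf
    tx <- if (!is.null(transcripts)) transcripts[[g$gene_id]] else NULL
    derive_elements(g, upstream_bins, bin_width, cl, tx)
  })
  res <- do.call(rbind, tabs)
  class(res) <- c("pav_elements", "data.frame")
  rownames(res) <- NULL
  res
}

#' Read target regions from a BED file
#'
#' Rows are grouped by the name column; discontinuous intervals sharing a
#' name become distinct elements of one parent, ranked in genomic order.
#' Names written by [write_bed()] (`parent:type:rank`) are split back into
#' their components so a write/read cycle preserves parent and type.
#' With `as_gene = TRUE` each name group is treated as a gene whose
#' intervals are exons (a parent row of type `gene` spanning the group is
#' added); otherwise intervals are typed `custom` under a parent row of type
#' `region`. Rows with `start >= end` are rejected with a message and the
#' remaining rows are kept.
#'
#' @param path BED file with at least 4 columns (chrom, start, end, name).
#' @param as_gene Treat each name group as a gene with exon intervals.
#' @return An element table (`pav_elements`).
#' @export
read_bed <- function(path, as_gene = FALSE) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 4) stop("BED file must have at least 4 columns")
  names(raw)[1:4] <- c("chrom", "start", "end", "name")
  raw$strand <- if (ncol(raw) >= 6) ifelse(raw[[6]] %in% c("+", "-"), raw[[6]], "+") else "+"
  bad <- raw$start >= raw$end
  if (any(bad)) {
    message(sum(bad), " BED row(s) with start >= end rejected")
    raw <- raw[!bad, , drop = FALSE]
  }
  if (!nrow(raw)) stop("no valid BED rows in ", path)

  # recover parent/type from names of the form parent:type:rank
  parts <- strsplit(raw$name, ":", fixed = TRUE)
  from_self <- vapply(parts, function(p)
    length(p) == 3 && p[2] %in% .ELEMENT_TYPES, logical(1))
  raw$parent <- ifelse(from_self, vapply(parts, `[`, "", 1L), raw$name)
  raw$etype <- ifelse(from_self, vapply(parts, `[`, "", 2L),
                      if (as_gene) "exon" else "custom")
  if (as_gene) raw$etype[raw$etype == "custom"] <- "exon"

  out <- list()
  for (pid in unique(raw$parent)) {
    g <- raw[raw$parent == pid, , drop = FALSE]
    g <- g[order(g$chrom, g$start), , drop = FALSE]
    parent_type <- if (as_gene) "gene" else "region"
    has_parent_row <- g$etype %in% .PARENT_TYPES
    body <- g[!has_parent_row, , drop = FALSE]
    recs <- list()
    if (any(has_parent_row)) {
      pr <- g[has_parent_row, , drop = FALSE][1, ]
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = pr$chrom, start = pr$start, end = pr$end, type = pr$etype,
        parent = pid, transcripts = "", rank = 1L, strand = pr$strand,
        stringsAsFactors = FALSE)
    } else if (nrow(body)) {
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = body$chrom[1], start = min(body$start), end = max(body$end),
        type = parent_type, parent = pid, transcripts = "", rank = 1L,
        strand = body$strand[1], stringsAsFactors = FALSE)
    }
    if (nrow(body)) {
      for (tp in unique(body$etype)) {
        b <- body[body$etype == tp, , drop = FALSE]
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = b$chrom, start = b$start, end = b$end, type = tp,
          parent = pid, transcripts = "", rank = seq_len(nrow(b)),
          strand = b$strand, stringsAsFactors = FALSE)
      }
    }
    out[[pid]] <- do.call(rbind, recs)
  }
  as_pav_elements(do.call(rbind, out))
}

#' Write an element table as BED6
#'
#' Emits 0-based half-open BED6 with `name = parent:type:rank`, score 0,
#' sorted by chromosome then start. The file round-trips through
#' [read_bed()], preserving the (chrom, start, end, type, parent) multiset.
#'
#' @param elements An element table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(elements, path) {
  if (!nrow(elements)) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = elements$chrom, start = elements$start, end = elements$end,
    name = paste(elements$parent, elements$type, elements$rank, sep = ":"),
    score = 0L, strand = elements$strand, stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start, bed$end, bed$name), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
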