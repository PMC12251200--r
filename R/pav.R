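# PAV calling: coverage fractions -> binary presence/absence.

#' PAV matrix constructor
#' @param info Row metadata (element table columns).
#' @param values 0/1 integer matrix, rows = regions, columns = samples.
#' @param meta Provenance list (method, threshold/min_gap, min_depth, ...).
#' @return A `PAVMatrix` object.
#' @keywords internal
new_pav <- function(info, values, meta = list()) {
  stopifnot(nrow(info) == nrow(values), all(values %in% c(0L, 1L)))
  mode(values) <- "integer"
  rownames(values) <- info$element_id
  structure(list(info = info, values = values, meta = meta),
            class = "PAVMatrix")
}

#' @export
print.PAVMatrix <- function(x, ...) {
  cat(sprintf("PAVMatrix: %d regions x %d samples (method=%s)\n",
              nrow(x$values), ncol(x$values), x$meta$method %||% "?"))
  invisible(x)
}

#' Call PAV with a fixed coverage threshold
#'
#' A region is present in a sample when its coverage fraction is at least
#' the threshold; equality counts as present.
#'
#' @param profile A `CoverageProfile`.
#' @param threshold Coverage threshold in (0, 1].
#' @return A `PAVMatrix`.
#' @export
call_fixed <- function(profile, threshold = 0.5) {
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  vals <- (profile$values >= threshold) + 0L
  meta <- c(profile$meta[c("min_depth", "mapq_min")],
            list(method = "fixed", threshold = threshold))
  new_pav(profile$info, vals, meta)
}

# Exact 1-D two-cluster split of a numeric vector: exhaustive breakpoint
# scan over the sorted values minimising within-cluster sum of squares.
# Returns the index (in sorted order) of the last low-cluster member, or 0
# when no split is taken.
.best_split <- function(v) {
  n <- length(v)
  s <- sort(v)
  css <- cumsum(s); css2 <- cumsum(s^2)
  wss <- function(a, b) { # sum of squares of s[a..b] around its mean
    m <- b - a + 1L
    tot <- css2[b] - if (a > 1) css2[a - 1L] else 0
    su <- css[b] - if (a > 1) css[a - 1L] else 0
    tot - su^2 / m
  }
  best_k <- 1L
  best <- Inf
  for (k in seq_len(n - 1L)) {
    w <- wss(1L, k) + wss(k + 1L, n)
    if (w < best - 1e-12) { best <- w; best_k <- k }
  }
  best_k
}

#' Call PAV with per-region adaptive thresholds
#'
#' For each region, coverage values across samples are split into two
#' clusters by an exact 1-D 2-means (exhaustive breakpoint search over the
#' sorted values, minimising within-cluster sum of squares; deterministic,
#' no random initialisation). The higher cluster is called present. When
#' all values are equal, or the gap between the two cluster means is below
#' `min_gap`, the region is called all-present (no credible absence signal).
#' The per-region split point (midpoint between the clusters, `NA` when
#' unsplit) is recorded in the result's row metadata.
#'
#' @param profile A `CoverageProfile` with at least two samples.
#' @param min_gap Minimum distance between cluster means to accept a split.
#' @return A `PAVMatrix` with a `split` column in its `info`.
#' @export
call_adaptive <- function(profile, min_gap = 0.1) {
  vals <- profile$values
  if (ncol(vals) < 2) {
    stop("adaptive calling requires >= 2 samples; use call_fixed() instead")
  }
  out <- matrix(1L, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  split_at <- rep(NA_real_, nrow(vals))
  for (i in seq_len(nrow(vals))) {
    v <- vals[i, ]
    if (max(v) - min(v) < 1e-12) next
    k <- .best_split(v)
    s <- sort(v)
    gap <- mean(s[(k + 1):length(s)]) - mean(s[1:k])
    if (gap < min_gap) next
    cut <- (s[k] + s[k + 1]) / 2
    split_at[i] <- cut
    out[i, ] <- (v > cut) + 0L
  }
  info <- profile$info
  info$split <- split_at
  meta <- c(profile$meta[c("min_depth", "mapq_min")],
            list(method = "adaptive", min_gap = min_gap))
  new_pav(info, out, meta)
}

#' Roll gene PAV up to gene families
#'
#' A family is present in a sample when at least one member gene is present.
#'
#' @param gene_pav A gene-level `PAVMatrix` (rows of type `gene` are used;
#'   if none, all rows are treated as genes keyed by their parent id).
#' @param families Either a data.frame with columns `family` and `gene`, or
#'   a named list family -> character vector of gene ids. Members missing
#'   from the PAV matrix are warned about and ignored; families with no
#'   resolvable member are dropped with a warning.
#' @return A family-level `PAVMatrix`.
#' @export
gene_family_pav <- function(gene_pav, families) {
  if (is.data.frame(families)) {
    families <- split(families$gene, families$family)
  }
  info <- gene_pav$info
  gene_rows <- which(info$type %in% .PARENT_TYPES)
  if (!length(gene_rows)) gene_rows <- seq_len(nrow(info))
  vals <- gene_pav$values[gene_rows, , drop = FALSE]
  gene_ids <- info$parent[gene_rows]

  fam_rows <- list()
  fam_vals <- list()
  n_unknown <- 0L
  dropped <- character(0)
  for (fam in names(families)) {
    members <- match(families[[fam]], gene_ids)
    n_unknown <- n_unknown + sum(is.na(members))
    members <- members[!is.na(members)]
    if (!length(members)) {
      dropped <- c(dropped, fam)
      next
    }
    fam_vals[[fam]] <- (colSums(vals[members, , drop = FALSE]) > 0) + 0L
    fam_rows[[fam]] <- data.frame(
      chrom = info$chrom[gene_rows][members[1]], start = NA_integer_,
      end = NA_integer_, type = "family", parent = fam, transcripts = "",
      rank = 1L, strand = "+", stringsAsFactors = FALSE)
  }
  if (n_unknown > 0) warning(n_unknown, " family member(s) not in PAV matrix; ignored")
  if (length(dropped)) {
    warning("famil(ies) with no resolvable member dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(fam_vals)) stop("no family with resolvable members")
  info2 <- do.call(rbind, fam_rows)
  info2$element_id <- paste0(info2$parent, ":family:1")
  info2 <- info2[, c("element_id", "chrom", "start", "end", "type", "parent",
                     "transcripts", "rank", "strand")]
  meta <- gene_pav$meta
  meta$rollup <- "gene_family_or"
  new_pav(info2, do.call(rbind, fam_vals), meta)
}

#' Write a PAV matrix as TSV
#' @param pav A `PAVMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pav <- function(pav, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(pav$meta)) {
    writeLines(sprintf("#%s=%s", k, pav$meta[[k]]), con)
  }
  df <- cbind(pav$info, as.data.frame(pav$values, check.names = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PAV matrix written by [write_pav()]
#' @param path TSV path.
#' @return A `PAVMatrix`.
#' @export
read_pav <- function(path) {
  prof <- read_profile(path)
  mode(prof$values) <- "integer"
  new_pav(prof$info, prof$values, prof$meta)
}
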