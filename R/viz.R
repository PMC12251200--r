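# Static visualization. Every plotting function writes an image AND the
# exact data table it rendered as a sidecar TSV; the TSV is the testable
# surface, the image is checked for existence only.

.write_sidecar <- function(df, file) {
  data_file <- sub("\\.(png|svg|pdf)$", ".tsv", file)
  if (identical(data_file, file)) data_file <- paste0(file, ".tsv")
  utils::write.table(df, data_file, sep = "\t", quote = FALSE, row.names = FALSE)
  data_file
}

.save_plot <- function(p, file, width = 7, height = 5) {
  grDevices::png(file, width = width * 100, height = height * 100, res = 100)
  print(p)
  grDevices::dev.off()
  file
}

# long-format table from a profile/PAV matrix, capped deterministically at
# `max_rows` rows (kept in decreasing presence/coverage order)
.matrix_long <- function(info, values, max_rows = 2000L) {
  if (nrow(values) > max_rows) {
    keep <- order(rowSums(values), decreasing = TRUE)[seq_len(max_rows)]
    info <- info[keep, , drop = FALSE]
    values <- values[keep, , drop = FALSE]
  }
  data.frame(
    region = rep(info$element_id, ncol(values)),
    sample = rep(colnames(values), each = nrow(values)),
    value = as.vector(values), stringsAsFactors = FALSE)
}

#' Overview plots of a PAV or coverage profile
#'
#' @param x A `PAVMatrix` (kinds `stat`, `hist`, `bar`, `pav_heat`) or
#'   `CoverageProfile` (kind `cov_heat`).
#' @param kind One of `stat` (per-sample presence counts), `hist`
#'   (histogram of presence counts with category colours), `bar`
#'   (per-sample category proportions), `pav_heat` / `cov_heat`
#'   (region x sample heatmap annotated with per-region presence totals).
#' @param file Output PNG path.
#' @param groups Optional named vector sample -> group for a heatmap strip.
#' @param softcore_fraction Category definition for `hist`/`bar`.
#' @param max_rows Heatmap row cap (deterministic downsampling above it).
#' @return Invisibly, list with `file` and `data_file` (sidecar TSV).
#' @export
plot_overview <- function(x, kind = c("stat", "hist", "bar", "pav_heat", "cov_heat"),
                          file, groups = NULL, softcore_fraction = 0.99,
                          max_rows = 2000L) {
  kind <- match.arg(kind)
  if (!nrow(x$values)) stop("empty matrix")
  if (kind == "stat") {
    cnt <- colSums(x$values >= if (inherits(x, "PAVMatrix")) 1 else 0.5)
    df <- data.frame(sample = names(cnt), present = as.integer(cnt))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = sample, y = present)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(y = "regions present") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  } else if (kind == "hist") {
    cl <- classify(x, softcore_fraction)
    df <- as.data.frame(table(presence = cl$presence, category = cl$category),
                        stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, , drop = FALSE]
    df$presence <- as.integer(df$presence)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = presence, y = Freq, fill = category)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "samples with region present", y = "regions") +
      ggplot2::theme_bw()
  } else if (kind == "bar") {
    cl <- classify(x, softcore_fraction)
    cat_of <- setNames(cl$category, cl$element_id)
    long <- .matrix_long(x$info, x$values, Inf)
    long <- long[long$value == 1, , drop = FALSE]
    long$category <- cat_of[long$region]
    tab <- as.data.frame(table(sample = long$sample, category = long$category),
                         stringsAsFactors = FALSE)
    tot <- tapply(tab$Freq, tab$sample, sum)
    tab$proportion <- tab$Freq / as.vector(tot[tab$sample])
    df <- tab
    p <- ggplot2::ggplot(df, ggplot2::aes(x = sample, y = proportion, fill = category)) +
      ggplot2::geom_col() +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  } else {
    df <- .matrix_long(x$info, x$values, max_rows)
    totals <- tapply(df$value, df$region, sum)
    df$region_total <- as.vector(totals[df$region])
    if (!is.null(groups)) df$group <- groups[df$sample]
    df$region <- factor(df$region, levels = names(sort(totals, decreasing = TRUE)))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = region, y = sample, fill = value)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient(low = "grey90", high = "firebrick") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_blank())
  }
  data_file <- .write_sidecar(df, file)
  .save_plot(p, file)
  invisible(list(file = file, data_file = data_file))
}

#' Growth-curve plots for pan/core size estimates
#'
#' @param growth Result of [estimate_sizes()].
#' @param style `line_err` (mean with sd error bars), `jitter`, or `ribbon`
#'   (mean with a +/- sd ribbon).
#' @param file Output PNG path.
#' @return Invisibly, `file` plus the per-n summary table path (`data_file`).
#' @export
plot_growth <- function(growth, style = c("line_err", "jitter", "ribbon"), file) {
  style <- match.arg(style)
  if (!nrow(growth)) stop("empty growth table")
  long <- rbind(
    data.frame(growth[c("group", "n", "rep")], series = "pan", count = growth$pan),
    data.frame(growth[c("group", "n", "rep")], series = "core", count = growth$core))
  summ <- aggregate(count ~ group + n + series, long,
                    function(v) c(mean = mean(v), sd = stats::sd(v)))
  summ <- data.frame(summ[c("group", "n", "series")],
                     mean = summ$count[, "mean"],
                     sd = ifelse(is.na(summ$count[, "sd"]), 0, summ$count[, "sd"]))
  summ <- summ[order(summ$group, summ$series, summ$n), ]
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = n, y = mean, colour = series,
                                          linetype = group, group = interaction(group, series)))
  p <- switch(style,
    line_err = p + ggplot2::geom_line() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd, ymax = mean + sd), width = 0.2),
    jitter = ggplot2::ggplot(long, ggplot2::aes(x = n, y = count, colour = series)) +
      ggplot2::geom_jitter(width = 0.15, height = 0, size = 0.6) +
      ggplot2::facet_wrap(~group),
    ribbon = p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = mean - sd, ymax = mean + sd, fill = series),
      alpha = 0.3, colour = NA) + ggplot2::geom_line())
  p <- p + ggplot2::labs(x = "genomes sampled", y = "regions") + ggplot2::theme_bw()
  data_file <- .write_sidecar(summ, file)
  .save_plot(p, file)
  invisible(list(file = file, data_file = data_file, summary = summ))
}

#' Sample ordination and clustering on a PAV matrix
#'
#' `pca` runs principal component analysis on the centred (unscaled) binary
#' matrix, samples as observations, and emits PC1/PC2 coordinates; `cluster`
#' computes Jaccard distances between samples and average-linkage
#' hierarchical clustering, emitting the dendrogram leaf order and merge
#' heights.
#'
#' @param pav A `PAVMatrix`.
#' @param mode `"pca"` (>= 3 samples) or `"cluster"` (>= 2 samples).
#' @param file Output PNG path.
#' @param groups Optional named vector sample -> group for colouring.
#' @return Invisibly, `file`, `data_file`, and the coordinates/order table.
#' @export
plot_samples <- function(pav, mode = c("pca", "cluster"), file, groups = NULL) {
  mode <- match.arg(mode)
  m <- t(pav$values)
  if (mode == "pca") {
    if (nrow(m) < 3) stop("pca requires >= 3 samples")
    if (all(apply(m, 2, stats::var) == 0)) stop("constant PAV matrix: zero variance")
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(pc$x))
    df <- data.frame(sample = rownames(pc$x), pc$x[, seq_len(k), drop = FALSE])
    if (!is.null(groups)) df$group <- groups[df$sample]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = PC1,
                                          y = if (k > 1) PC2 else 0)) +
      ggplot2::geom_point(ggplot2::aes(colour = if (!is.null(groups)) group else NULL)) +
      ggplot2::labs(y = "PC2", colour = "group") + ggplot2::theme_bw()
    data_file <- .write_sidecar(df, file)
    .save_plot(p, file)
    return(invisible(list(file = file, data_file = data_file, coords = df)))
  }
  if (nrow(m) < 2) stop("cluster requires >= 2 samples")
  d <- stats::dist(m, method = "binary")  # Jaccard distance on 0/1 rows
  hc <- stats::hclust(d, method = "average")
  df <- data.frame(order = seq_along(hc$order),
                   sample = hc$labels[hc$order], stringsAsFactors = FALSE)
  data_file <- .write_sidecar(df, file)
  grDevices::png(file, width = 700, height = 500, res = 100)
  plot(hc, main = "Sample clustering (Jaccard, average linkage)",
       xlab = "", sub = "")
  grDevices::dev.off()
  invisible(list(file = file, data_file = data_file, order = df, hclust = hc))
}

#' Association-result plots
#'
#' @param results Data frame from [associate_all()].
#' @param kind `pheno_heat` (regions x traits, -log10 adjusted p),
#'   `manhattan` (-log10 p along the genome for one trait, top 5 regions
#'   flagged), `pheno_block` (per trait level, presence/absence proportions
#'   for one region), `pheno_bar` (counts), `pheno_vio` (continuous trait by
#'   PAV group).
#' @param file Output PNG path.
#' @param trait,region Selectors (required by the single-trait/region kinds).
#' @param pav Required for `pheno_block`/`pheno_bar`/`pheno_vio` (and for
#'   `manhattan` region coordinates).
#' @param phenotypes Required for `pheno_block`/`pheno_bar`/`pheno_vio`.
#' @return Invisibly, `file` and `data_file`.
#' @export
plot_association <- function(results,
                             kind = c("pheno_heat", "manhattan", "pheno_block",
                                      "pheno_bar", "pheno_vio"),
                             file, trait = NULL, region = NULL, pav = NULL,
                             phenotypes = NULL) {
  kind <- match.arg(kind)
  if (!nrow(results)) stop("empty association results")
  pick <- function(df, col, val) {
    if (is.null(val)) stop("selector required for kind ", kind)
    out <- df[df[[col]] == val, , drop = FALSE]
    if (!nrow(out)) stop("selector matches nothing: ", val)
    out
  }
  if (kind == "pheno_heat") {
    df <- results[!is.na(results$p_adjusted), , drop = FALSE]
    if (!nrow(df)) stop("no testable results")
    df <- data.frame(region = df$region, trait = df$trait,
                     neglog10_padj = -log10(pmax(df$p_adjusted, 1e-300)))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = trait, y = region, fill = neglog10_padj)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient(low = "grey95", high = "firebrick") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
  } else if (kind == "manhattan") {
    df <- pick(results, "trait", trait)
    df <- df[!is.na(df$p_value), , drop = FALSE]
    if (is.null(pav)) stop("manhattan requires the PAV matrix for coordinates")
    idx <- match(df$region, pav$info$element_id)
    df$chrom <- pav$info$chrom[idx]
    df$pos <- (pav$info$start[idx] + pav$info$end[idx]) / 2
    df$neglog10_p <- -log10(pmax(df$p_value, 1e-300))
    top <- order(df$p_value)[seq_len(min(5L, nrow(df)))]
    df$top5 <- FALSE; df$top5[top] <- TRUE
    df <- df[, c("region", "trait", "chrom", "pos", "p_value", "neglog10_p", "top5")]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = pos, y = neglog10_p, colour = top5)) +
      ggplot2::geom_point() +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
      ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
      ggplot2::labs(y = "-log10(p)") + ggplot2::theme_bw()
  } else {
    if (is.null(pav) || is.null(phenotypes)) {
      stop(kind, " requires pav and phenotypes")
    }
    pick(results, "region", region)
    samples <- intersect(colnames(pav$values), rownames(phenotypes))
    pres <- pav$values[region, samples]
    tv <- phenotypes[samples, trait]
    ok <- !is.na(tv)
    if (kind == "pheno_vio") {
      df <- data.frame(sample = samples[ok], trait_value = tv[ok],
                       pav = ifelse(pres[ok] == 1, "present", "absent"))
      p <- ggplot2::ggplot(df, ggplot2::aes(x = pav, y = trait_value, fill = pav)) +
        ggplot2::geom_violin() + ggplot2::geom_jitter(width = 0.1, size = 0.8) +
        ggplot2::labs(title = region, y = trait) + ggplot2::theme_bw()
    } else {
      tab <- table(level = tv[ok], pav = ifelse(pres[ok] == 1, "present", "absent"))
      df <- as.data.frame(tab, stringsAsFactors = FALSE)
      tot <- tapply(df$Freq, df$level, sum)
      df$proportion <- df$Freq / as.vector(tot[df$level])
      p <- ggplot2::ggplot(df, ggplot2::aes(x = level,
                                            y = if (kind == "pheno_block") proportion else Freq,
                                            fill = pav)) +
        ggplot2::geom_col() +
        ggplot2::labs(title = region, y = if (kind == "pheno_block") "proportion" else "samples") +
        ggplot2::theme_bw()
    }
  }
  data_file <- .write_sidecar(df, file)
  .save_plot(p, file)
  invisible(list(file = file, data_file = data_file, data = df))
}

#' Composite element heatmap for one parent region
#'
#' Heatmap rows are samples and columns are the parent's elements ordered
#' by rank; cell values are coverage, PAV, or mean depth. A top track
#' sketches the element coordinates (the gene model) and optional phenotype
#' strips annotate the samples.
#'
#' @param parent Parent (gene/region) id.
#' @param profile Element-level `CoverageProfile` (kinds `cov` and `depth`)
#'   or `PAVMatrix` (kind `pav`).
#' @param kind `"cov"`, `"pav"` or `"depth"` (`depth` requires the profile
#'   to carry a mean-depth matrix).
#' @param file Output PNG path.
#' @param phenotypes Optional phenotype data frame for sample strips.
#' @param traits Traits to annotate with (default: all).
#' @return Invisibly, `file`, `data_file` and the plotted long table.
#' @export
plot_elements <- function(parent, profile, kind = c("cov", "pav", "depth"),
                          file, phenotypes = NULL, traits = NULL) {
  kind <- match.arg(kind)
  sel <- which(profile$info$parent == parent & !.is_parent_type(profile$info$type))
  if (!length(sel)) stop("unknown parent or no elements: ", parent)
  vals <- switch(kind,
    cov = profile$values, pav = profile$values,
    depth = {
      if (is.null(profile$depth)) stop("depth mode requires a mean-depth table")
      profile$depth
    })
  info <- profile$info[sel, , drop = FALSE]
  ord <- order(match(info$type, .ELEMENT_TYPES),
               suppressWarnings(as.numeric(sub("-.*", "", info$rank))))
  info <- info[ord, , drop = FALSE]
  vals <- vals[sel[ord], , drop = FALSE]

  long <- data.frame(
    element = rep(info$element_id, ncol(vals)),
    type = rep(info$type, ncol(vals)),
    start = rep(info$start, ncol(vals)),
    end = rep(info$end, ncol(vals)),
    sample = rep(colnames(vals), each = nrow(vals)),
    value = as.vector(vals), stringsAsFactors = FALSE)
  if (!is.null(phenotypes)) {
    samples <- colnames(vals)
    if (is.null(traits)) traits <- colnames(phenotypes)
    for (tr in traits) long[[paste0("pheno_", tr)]] <-
      rep(phenotypes[samples, tr], each = nrow(vals))
  }
  long$element <- factor(long$element, levels = info$element_id)
  long$sample <- factor(long$sample, levels = colnames(vals))

  model <- data.frame(element = info$element_id, type = info$type,
                      start = info$start, end = info$end,
                      x = seq_len(nrow(info)))
  p_heat <- ggplot2::ggplot(long, ggplot2::aes(x = element, y = sample, fill = value)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.1) +
    ggplot2::scale_fill_gradient(low = "grey92", high = "firebrick",
                                 limits = if (kind == "pav") c(0, 1) else NULL) +
    ggplot2::labs(title = sprintf("%s (%s)", parent, kind)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
  p_track <- ggplot2::ggplot(model) +
    ggplot2::geom_segment(ggplot2::aes(x = start, xend = end, y = type, yend = type,
                                       colour = type), linewidth = 3) +
    ggplot2::labs(x = "position (bp)") + ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
  combined <- patchwork::wrap_plots(p_track, p_heat, ncol = 1, heights = c(1, 4))
  grDevices::png(file, width = 900, height = 700, res = 100)
  print(combined)
  grDevices::dev.off()
  data_file <- .write_sidecar(long, file)
  invisible(list(file = file, data_file = data_file, data = long))
}
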