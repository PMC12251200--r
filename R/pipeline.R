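# One-step batch drivers chaining annotation -> coverage -> PAV calling ->
# classification -> growth estimation -> (optional) phenotype association
# -> preview figures, with a YAML run manifest and a stage log.

#' Build a batch run configuration
#'
#' @param mode `"gene"` (requires `gff`) or `"general"` (requires `bed`).
#' @param gff,bed Annotation input for the respective mode.
#' @param samples Named character vector: sample id -> BAM or depth-table
#'   path.
#' @param out_dir Output directory.
#' @param method,threshold,min_gap PAV calling method and parameters.
#' @param rep_mode Representative-transcript mode (gene mode).
#' @param upstream_bins,bin_width Flank layout (gene mode).
#' @param as_gene Treat BED name groups as genes (general mode).
#' @param min_depth,mapq_min Coverage parameters.
#' @param merge Merge rank-adjacent equal-coverage elements.
#' @param softcore_fraction,repetitions,seed Downstream parameters.
#' @param phenotypes Optional phenotype TSV path.
#' @param groups Optional named vector sample -> group.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode = c("gene", "general"), gff = NULL, bed = NULL,
                       samples, out_dir,
                       method = c("fixed", "adaptive"), threshold = 0.5,
                       min_gap = 0.1, rep_mode = "all",
                       upstream_bins = 10L, bin_width = 100L,
                       as_gene = FALSE, min_depth = 1L, mapq_min = 0L,
                       merge = FALSE, softcore_fraction = 0.99,
                       repetitions = 100L, seed = 42L,
                       phenotypes = NULL, groups = NULL,
                       chrom_lengths = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (mode == "gene" && is.null(gff)) stop("gene mode requires a GFF file")
  if (mode == "general" && is.null(bed)) stop("general mode requires a BED file")
  if (!length(samples)) stop("at least one sample input required")
  structure(list(
    mode = mode, gff = gff, bed = bed, samples = samples, out_dir = out_dir,
    method = method, threshold = threshold, min_gap = min_gap,
    rep_mode = rep_mode, upstream_bins = upstream_bins,
    bin_width = bin_width, as_gene = as_gene, min_depth = min_depth,
    mapq_min = mapq_min, merge = merge,
    softcore_fraction = softcore_fraction, repetitions = repetitions,
    seed = seed, phenotypes = phenotypes, groups = groups,
    chrom_lengths = chrom_lengths), class = "run_config")
}

.log_stage <- function(log_con, stage, msg = "start") {
  writeLines(sprintf("[%s] %s", stage, msg), log_con)
  flush(log_con)
}

.chrom_lengths_from_inputs <- function(config) {
  if (!is.null(config$chrom_lengths)) return(config$chrom_lengths)
  bams <- config$samples[grepl("\\.bam$", config$samples, ignore.case = TRUE) &
                           file.exists(config$samples)]
  if (length(bams)) {
    return(Rsamtools::scanBamHeader(bams[[1]])[[1]]$targets)
  }
  NULL
}

.run_batch <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  stage <- "config"
  err_marker <- file.path(config$out_dir, "ERROR")
  fail <- function(e) {
    writeLines(paste0("stage ", stage, " failed: ", conditionMessage(e)), log_con)
    writeLines(stage, err_marker)
    stop("batch failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  out <- list()
  tryCatch({
    cl <- .chrom_lengths_from_inputs(config)

    stage <- "coordinates"
    .log_stage(log_con, stage)
    if (config$mode == "gene") {
      genes <- parse_gff(config$gff)
      tx_sel <- NULL
      if (!config$rep_mode %in% c("all", "gene_body", "highest_coverage")) {
        tx_sel <- lapply(genes, select_representative, mode = config$rep_mode)
      } else if (config$rep_mode %in% c("gene_body")) {
        tx_sel <- lapply(genes, function(g) character(0))
      }
      elements <- gff_elements(genes, config$upstream_bins, config$bin_width,
                               cl, tx_sel)
      if (config$rep_mode == "highest_coverage") {
        prof0 <- build_profile(elements, config$samples, config$min_depth,
                               config$mapq_min)
        tx_sel <- lapply(genes, function(g) {
          cvs <- vapply(names(g$transcripts), function(tid) {
            rows <- grepl(tid, prof0$element$info$transcripts, fixed = TRUE) &
              prof0$element$info$parent == g$gene_id &
              prof0$element$info$type == "exon"
            if (!any(rows)) return(NA_real_)
            mean(prof0$element$values[rows, , drop = FALSE])
          }, numeric(1))
          select_representative(g, "highest_coverage", coverages = cvs)
        })
        elements <- gff_elements(genes, config$upstream_bins,
                                 config$bin_width, cl, tx_sel)
      }
    } else {
      elements <- read_bed(config$bed, as_gene = config$as_gene)
    }
    write_bed(elements, file.path(config$out_dir, "elements.bed"))

    stage <- "coverage"
    .log_stage(log_con, stage)
    prof <- build_profile(elements, config$samples, config$min_depth,
                          config$mapq_min)
    if (config$merge) prof$element <- merge_equal_neighbors(prof$element)
    write_profile(prof$region, file.path(config$out_dir, "coverage_region.tsv"))
    write_profile(prof$element, file.path(config$out_dir, "coverage_element.tsv"))

    stage <- "pav_calling"
    .log_stage(log_con, stage)
    call1 <- function(p) {
      if (config$method == "fixed") call_fixed(p, config$threshold)
      else call_adaptive(p, config$min_gap)
    }
    pav_region <- call1(prof$region)
    pav_element <- call1(prof$element)
    write_pav(pav_region, file.path(config$out_dir, "pav_region.tsv"))
    write_pav(pav_element, file.path(config$out_dir, "pav_element.tsv"))

    stage <- "classification"
    .log_stage(log_con, stage)
    cl_region <- classify(pav_region, config$softcore_fraction)
    cl_element <- classify(pav_element, config$softcore_fraction)
    utils::write.table(cl_region, file.path(config$out_dir, "classification_region.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cl_element, file.path(config$out_dir, "classification_element.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "growth"
    .log_stage(log_con, stage)
    growth <- estimate_sizes(pav_region, config$repetitions,
                             config$groups, config$seed)
    utils::write.table(growth, file.path(config$out_dir, "growth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    assoc <- NULL
    if (!is.null(config$phenotypes)) {
      stage <- "phenotype_association"
      .log_stage(log_con, stage)
      ph <- read_phenotypes(config$phenotypes)
      assoc <- associate_all(pav_region, ph,
                             softcore_fraction = config$softcore_fraction,
                             seed = config$seed)
      utils::write.table(assoc, file.path(config$out_dir, "pheno_assoc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "figures"
    .log_stage(log_con, stage)
    fig_dir <- file.path(config$out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    plot_overview(pav_region, "hist", file.path(fig_dir, "classification_hist.png"),
                  softcore_fraction = config$softcore_fraction)
    plot_overview(pav_region, "pav_heat", file.path(fig_dir, "pav_heat.png"),
                  groups = config$groups)
    plot_growth(growth, "line_err", file.path(fig_dir, "growth.png"))
    if (ncol(pav_region$values) >= 3 &&
        any(apply(pav_region$values, 1, stats::var) > 0)) {
      plot_samples(pav_region, "pca", file.path(fig_dir, "pca.png"),
                   groups = config$groups)
      plot_samples(pav_region, "cluster", file.path(fig_dir, "cluster.png"))
    }

    stage <- "manifest"
    .log_stage(log_con, stage)
    inputs <- c(config$gff, config$bed, unname(config$samples), config$phenotypes)
    manifest <- list(
      pavkit_version = as.character(utils::packageVersion("pavkit")),
      mode = config$mode,
      parameters = config[c("method", "threshold", "min_gap", "rep_mode",
                            "upstream_bins", "bin_width", "as_gene",
                            "min_depth", "mapq_min", "merge",
                            "softcore_fraction", "repetitions", "seed")],
      inputs = as.list(setNames(unname(tools::md5sum(inputs)), basename(inputs))),
      samples = as.list(config$samples))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    .log_stage(log_con, "done", "all stages complete")

    out <- list(out_dir = config$out_dir, elements = elements,
                profile = prof, pav_region = pav_region,
                pav_element = pav_element, classification = cl_region,
                growth = growth, association = assoc)
  }, error = fail)
  invisible(out)
}

#' Run the gene-mode batch pipeline
#'
#' Chains coordinate extraction from GFF3, coverage computation, PAV
#' calling, classification, growth-curve estimation, optional phenotype
#' association and preview figures; writes a YAML manifest recording the
#' package version, every parameter and the MD5 checksum of every input.
#' A stage failure leaves the completed stages' outputs plus an `ERROR`
#' marker naming the failed stage.
#'
#' @param config A `run_config` with `mode = "gene"`.
#' @return Invisibly, the in-memory stage results.
#' @export
gene_batch <- function(config) {
  stopifnot(inherits(config, "run_config"), config$mode == "gene")
  .run_batch(config)
}

#' Run the general-mode batch pipeline
#'
#' As [gene_batch()] but ingesting arbitrary target regions from BED
#' (optionally treated as genes via the config's `as_gene`).
#'
#' @param config A `run_config` with `mode = "general"`.
#' @return Invisibly, the in-memory stage results.
#' @export
general_batch <- function(config) {
  stopifnot(inherits(config, "run_config"), config$mode == "general")
  .run_batch(config)
}
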