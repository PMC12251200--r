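# Synthetic cohort generator with a known truth PAV matrix.
#
# The generator emulates the input side of a map-to-pan study: a reference
# chromosome, a GFF3 annotation of multi-exon genes (one multi-transcript
# gene with duplicated exons, to exercise consolidation), per-sample
# alignments or depth tables in which planted deletions have depth 0 and
# everything else sits at a background depth, and phenotypes linked to
# planted deletions. Deletion units are whole gene spans and individual
# flanking bins, so every element is either fully deleted or fully intact
# and the truth PAV matrix is unambiguous.

#' Specify a synthetic cohort
#'
#' @param n_samples Cohort size.
#' @param n_genes Number of genes on the single reference chromosome.
#' @param n_exons Exons per gene.
#' @param exon_len,intron_len,utr_len Gene layout in bp (UTRs are the first
#'   and last `utr_len` bp of the terminal exons).
#' @param upstream_bins,bin_width Flank layout used downstream.
#' @param gene_spacing Distance between consecutive gene starts; must leave
#'   room for both flanks.
#' @param background_depth Expected read depth outside deletions.
#' @param read_length Read length for BAM output mode.
#' @param var_gene_frac Fraction of genes eligible for deletion.
#' @param del_rate Per-sample probability that a variable gene's whole span
#'   is deleted.
#' @param flank_del_rate Per-sample probability that an individual flanking
#'   bin of a variable gene is deleted.
#' @param mode `"depth"` writes 3-column depth tables; `"bam"` writes
#'   sorted, indexed BAM files.
#' @param tiling `"deterministic"` lays evenly spaced error-free reads (or
#'   constant depth in depth mode) so coverage outside deletions is exactly
#'   1; `"poisson"` draws per-base depth (depth mode) or read counts (bam
#'   mode) from a Poisson law with mean `background_depth`.
#' @param pheno_confusion Probability that the linked discrete trait label
#'   is flipped relative to the linked gene's PAV.
#' @param pheno_effect,pheno_sd,pheno_baseline Continuous linked trait:
#'   `baseline + effect * presence + N(0, sd)`.
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 20L, n_genes = 50L, n_exons = 3L,
                        exon_len = 300L, intron_len = 200L, utr_len = 100L,
                        upstream_bins = 10L, bin_width = 100L,
                        gene_spacing = 4000L, background_depth = 20L,
                        read_length = 100L, var_gene_frac = 0.5,
                        del_rate = 0.3, flank_del_rate = 0.02,
                        mode = c("depth", "bam"),
                        tiling = c("deterministic", "poisson"),
                        pheno_confusion = 0.05, pheno_effect = 3,
                        pheno_sd = 1, pheno_baseline = 10, seed = 42L) {
  mode <- match.arg(mode); tiling <- match.arg(tiling)
  gene_len <- n_exons * exon_len + (n_exons - 1L) * intron_len
  flank <- upstream_bins * bin_width
  if (gene_spacing < gene_len + 2L * flank) {
    stop("gene_spacing too small for gene length plus flanks")
  }
  if (background_depth <= 0) stop("background_depth must be positive")
  structure(list(
    n_samples = n_samples, n_genes = n_genes, n_exons = n_exons,
    exon_len = exon_len, intron_len = intron_len, utr_len = utr_len,
    upstream_bins = upstream_bins, bin_width = bin_width,
    gene_spacing = gene_spacing, background_depth = background_depth,
    read_length = read_length, var_gene_frac = var_gene_frac,
    del_rate = del_rate, flank_del_rate = flank_del_rate,
    mode = mode, tiling = tiling,
    pheno_confusion = pheno_confusion, pheno_effect = pheno_effect,
    pheno_sd = pheno_sd, pheno_baseline = pheno_baseline,
    seed = seed, chrom = "chrSim",
    gene_len = gene_len, flank = flank,
    chrom_length = n_genes * gene_spacing + 2L * flank
  ), class = "cohort_spec")
}

#' Generate the reference FASTA and GFF3 for a cohort spec
#'
#' Genes alternate strand along one chromosome. Gene 1 carries a second
#' transcript that shares (duplicates) the first two exons and skips the
#' last, exercising element consolidation downstream.
#'
#' @param spec A `cohort_spec`.
#' @param dir Output directory (created if needed).
#' @return List with `fasta`, `gff`, `chrom_lengths` and the gene layout
#'   table `genes` (0-based half-open gene spans).
#' @export
sim_annotation <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  chrom <- spec$chrom

  seq <- paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE),
               collapse = "")
  fasta <- file.path(dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(seq)
  names(dna) <- chrom
  Biostrings::writeXStringSet(dna, fasta)

  # layout: gene i starts at flank + (i-1)*spacing (0-based)
  gstart <- spec$flank + (seq_len(spec$n_genes) - 1L) * spec$gene_spacing
  gend <- gstart + spec$gene_len
  strand <- rep(c("+", "-"), length.out = spec$n_genes)
  gid <- sprintf("g%03d", seq_len(spec$n_genes))

  exon_iv <- function(s) {
    st <- s + (seq_len(spec$n_exons) - 1L) * (spec$exon_len + spec$intron_len)
    cbind(start = st, end = st + spec$exon_len)
  }

  lines <- c("##gff-version 3")
  for (i in seq_len(spec$n_genes)) {
    ex <- exon_iv(gstart[i])
    g <- gid[i]
    lines <- c(lines, sprintf("%s\tpavkit_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              chrom, gstart[i] + 1L, gend[i], strand[i], g))
    tx_sets <- list(t1 = seq_len(spec$n_exons))
    if (i == 1L && spec$n_exons >= 3L) tx_sets$t2 <- 1:2
    for (tn in names(tx_sets)) {
      tid <- paste0(g, ".", tn)
      keep <- tx_sets[[tn]]
      exk <- ex[keep, , drop = FALSE]
      lines <- c(lines, sprintf(
        "%s\tpavkit_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        chrom, min(exk[, 1]) + 1L, max(exk[, 2]), strand[i], tid, g))
      for (j in seq_len(nrow(exk))) {
        lines <- c(lines, sprintf(
          "%s\tpavkit_sim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
          chrom, exk[j, 1] + 1L, exk[j, 2], strand[i], tid))
      }
      # CDS = exons minus utr_len at each outer end of the transcript
      cds <- exk
      cds[1, 1] <- cds[1, 1] + spec$utr_len
      cds[nrow(cds), 2] <- cds[nrow(cds), 2] - spec$utr_len
      for (j in seq_len(nrow(cds))) {
        if (cds[j, 2] > cds[j, 1]) {
          lines <- c(lines, sprintf(
            "%s\tpavkit_sim\tCDS\t%d\t%d\t.\t%s\t.\tParent=%s",
            chrom, cds[j, 1] + 1L, cds[j, 2], strand[i], tid))
        }
      }
    }
  }
  gff <- file.path(dir, "annotation.gff3")
  writeLines(lines, gff)

  list(fasta = fasta, gff = gff,
       chrom_lengths = setNames(spec$chrom_length, chrom),
       genes = data.frame(gene_id = gid, chrom = chrom, start = gstart,
                          end = gend, strand = strand,
                          stringsAsFactors = FALSE))
}

# Planted deletion plan: data.frame (sample, start, end, unit, parent).
.deletion_plan <- function(spec, genes) {
  set.seed(spec$seed + 1L)
  sid <- sprintf("s%02d", seq_len(spec$n_samples))
  n_var <- ceiling(spec$var_gene_frac * spec$n_genes)
  var_genes <- sort(sample(spec$n_genes, n_var))
  plan <- list()
  for (i in var_genes) {
    g <- genes[i, ]
    del <- stats::runif(spec$n_samples) < spec$del_rate
    for (s in which(del)) {
      plan[[length(plan) + 1L]] <- data.frame(
        sample = sid[s], start = g$start, end = g$end, unit = "gene",
        parent = g$gene_id, stringsAsFactors = FALSE)
    }
    # individual flanking bins on either side
    for (side in c(-1L, 1L)) {
      for (b in seq_len(spec$upstream_bins)) {
        bs <- if (side < 0) g$start - b * spec$bin_width else
          g$end + (b - 1L) * spec$bin_width
        del_b <- stats::runif(spec$n_samples) < spec$flank_del_rate
        for (s in which(del_b)) {
          plan[[length(plan) + 1L]] <- data.frame(
            sample = sid[s], start = bs, end = bs + spec$bin_width,
            unit = "flank_bin", parent = g$gene_id, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(samples = sid, var_genes = genes$gene_id[var_genes],
       plan = if (length(plan)) do.call(rbind, plan) else
         data.frame(sample = character(0), start = integer(0),
                    end = integer(0), unit = character(0),
                    parent = character(0)))
}

# Truth coverage fraction of each element in each sample given the planted
# deletions, and the PAV truth at the calling threshold.
.truth_from_plan <- function(elements, plan, samples, threshold = 0.5) {
  truth <- matrix(1L, nrow(elements), length(samples),
                  dimnames = list(elements$element_id, samples))
  for (s in samples) {
    dels <- plan[plan$sample == s, , drop = FALSE]
    if (!nrow(dels)) next
    dr <- IRanges::reduce(IRanges::IRanges(dels$start + 1L, dels$end))
    er <- IRanges::IRanges(elements$start + 1L, elements$end)
    hit <- IRanges::findOverlaps(er, dr)
    cut <- tapply(
      IRanges::width(IRanges::pintersect(
        er[S4Vectors::queryHits(hit)], dr[S4Vectors::subjectHits(hit)])),
      S4Vectors::queryHits(hit), sum)
    frac_deleted <- numeric(nrow(elements))
    frac_deleted[as.integer(names(cut))] <- cut / IRanges::width(er)[as.integer(names(cut))]
    truth[, s] <- as.integer(1 - frac_deleted >= threshold)
  }
  truth
}

#' Generate per-sample alignments or depth tables plus the truth set
#'
#' Plants whole-gene-span and flanking-bin deletions per sample, writes the
#' per-sample read data (depth tables or sorted+indexed BAMs) and returns
#' the truth PAV matrix over all elements derived from the annotation.
#'
#' @param spec A `cohort_spec`.
#' @param ann Result of [sim_annotation()].
#' @param dir Output directory.
#' @return List with `samples` (named path vector), `truth` (elements x
#'   samples 0/1 matrix at the 0.5-coverage convention), `elements`, and
#'   the deletion `plan`.
#' @export
sim_alignments <- function(spec, ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- parse_gff(ann$gff)
  elements <- gff_elements(genes, spec$upstream_bins, spec$bin_width,
                           ann$chrom_lengths)
  dp <- .deletion_plan(spec, ann$genes)
  truth <- .truth_from_plan(elements, dp$plan, dp$samples)

  set.seed(spec$seed + 2L)
  chrom <- spec$chrom
  L <- spec$chrom_length
  paths <- character(0)
  for (s in dp$samples) {
    dels <- dp$plan[dp$plan$sample == s, , drop = FALSE]
    delr <- if (nrow(dels)) IRanges::reduce(IRanges::IRanges(dels$start + 1L, dels$end))
            else IRanges::IRanges()
    keepr <- IRanges::setdiff(IRanges::IRanges(1L, L), delr)
    if (spec$mode == "depth") {
      pos <- unlist(lapply(seq_along(keepr), function(k)
        seq(IRanges::start(keepr)[k], IRanges::end(keepr)[k])))
      depth <- if (spec$tiling == "deterministic") {
        rep(spec$background_depth, length(pos))
      } else {
        stats::rpois(length(pos), spec$background_depth)
      }
      keep <- depth > 0
      f <- file.path(dir, paste0(s, ".depth.tsv"))
      data.table::fwrite(data.table::data.table(chrom, pos[keep], depth[keep]),
                         f, sep = "\t", col.names = FALSE)
      paths[s] <- f
    } else {
      f <- .write_sim_bam(spec, keepr, file.path(dir, s), chrom, L)
      paths[s] <- f
    }
  }
  list(samples = paths, truth = truth, elements = elements,
       plan = dp$plan, var_genes = dp$var_genes)
}

# Tile each retained interval with reads so that every base of intervals at
# least one read long is covered; intervals shorter than the read length are
# covered by one clipped read. Writes SAM text, converts, sorts and indexes.
.write_sim_bam <- function(spec, keepr, prefix, chrom, chrom_len) {
  rl <- spec$read_length
  step <- max(1L, as.integer(round(rl / spec$background_depth)))
  sam <- file.path(paste0(prefix, ".sam"))
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len)), con)
  qn <- 0L
  for (k in seq_along(keepr)) {
    a <- IRanges::start(keepr)[k]; b <- IRanges::end(keepr)[k]
    len <- b - a + 1L
    if (len >= rl) {
      starts <- unique(c(seq(a, b - rl + 1L, by = step), b - rl + 1L))
      lens <- rep(rl, length(starts))
    } else {
      starts <- a; lens <- len
    }
    if (spec$tiling == "poisson") {
      reps <- stats::rpois(length(starts), 1)
      keep <- rep(seq_along(starts), reps)
      starts <- starts[keep]; lens <- lens[keep]
    }
    for (j in seq_along(starts)) {
      qn <- qn + 1L
      writeLines(sprintf("r%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                         qn, chrom, starts[j], lens[j],
                         paste(rep("A", lens[j]), collapse = "")), con)
    }
  }
  close(con)
  bam0 <- Rsamtools::asBam(sam, paste0(prefix, ".unsorted"), overwrite = TRUE,
                           indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(bam0, prefix)
  Rsamtools::indexBam(sorted)
  unlink(c(sam, bam0))
  sorted
}

#' Generate phenotypes linked to planted deletions
#'
#' Writes a phenotype table with a discrete trait tracking the PAV of one
#' linked variable gene (label flipped with probability `pheno_confusion`),
#' a continuous trait shifted by that gene's presence, and two null traits
#' (a random binary label and pure Gaussian noise).
#'
#' @param spec A `cohort_spec`.
#' @param sim Result of [sim_alignments()].
#' @param dir Output directory.
#' @return List with `path` (phenotype TSV), `linked_gene` and `traits`.
#' @export
sim_phenotypes <- function(spec, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 3L)
  samples <- colnames(sim$truth)
  # pick the variable gene whose gene-body PAV varies most evenly
  gene_rows <- paste0(sim$var_genes, ":gene:1")
  gene_rows <- gene_rows[gene_rows %in% rownames(sim$truth)]
  pres <- sim$truth[gene_rows, , drop = FALSE]
  bal <- abs(rowMeans(pres) - 0.5)
  linked <- sim$var_genes[which.min(bal)]
  pv <- sim$truth[paste0(linked, ":gene:1"), ]

  flip <- stats::runif(length(samples)) < spec$pheno_confusion
  grp <- ifelse(xor(pv == 1, flip), "A", "B")
  height <- spec$pheno_baseline + spec$pheno_effect * pv +
    stats::rnorm(length(samples), 0, spec$pheno_sd)
  null_grp <- sample(c("X", "Y"), length(samples), replace = TRUE)
  null_num <- stats::rnorm(length(samples))

  df <- data.frame(sample = samples, group = grp, height = round(height, 4),
                   null_group = null_grp, null_value = round(null_num, 4),
                   stringsAsFactors = FALSE)
  path <- file.path(dir, "phenotypes.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(path = path, linked_gene = linked,
       traits = c(group = "discrete", height = "continuous",
                  null_group = "discrete", null_value = "continuous"))
}

#' Generate a complete synthetic cohort
#'
#' Runs [sim_annotation()], [sim_alignments()] and [sim_phenotypes()] into
#' one directory.
#'
#' @param spec A `cohort_spec`.
#' @param dir Output directory.
#' @return List combining the three stages' outputs.
#' @export
sim_cohort <- function(spec, dir) {
  ann <- sim_annotation(spec, dir)
  aln <- sim_alignments(spec, ann, dir)
  ph <- sim_phenotypes(spec, aln, dir)
  c(ann, aln, ph[c("path", "linked_gene", "traits")],
    list(pheno = ph$path, spec = spec))
}
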