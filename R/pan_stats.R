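# Pangenome classification and pan/core size estimation.

#' Classify regions into pangenome categories
#'
#' Categories, judged on the number of samples `m` (out of `N`) in which a
#' region is present: `core` (`m == N`), `private` (`m == 1`), `softcore`
#' (`m >= ceiling(softcore_fraction * N)` but below `N`), `distributed`
#' (any other `m >= 1`), and `absent_everywhere` (`m == 0`). The private
#' rule is applied before the softcore rule, which only matters for very
#' small cohorts. Categories are exclusive and exhaustive.
#'
#' @param pav A `PAVMatrix`.
#' @param softcore_fraction Presence fraction defining softcore, in (0, 1).
#' @return Data frame (`element_id`, `presence`, `category`) with the
#'   parameters attached as attributes `softcore_fraction` and `n_samples`.
#' @export
classify <- function(pav, softcore_fraction = 0.99) {
  if (!(softcore_fraction > 0 && softcore_fraction < 1)) {
    stop("softcore_fraction must be in (0, 1)")
  }
  vals <- pav$values
  if (!nrow(vals)) stop("empty PAV matrix")
  n <- ncol(vals)
  m <- rowSums(vals)
  soft_min <- ceiling(softcore_fraction * n)
  category <- ifelse(m == 0, "absent_everywhere",
              ifelse(m == n, "core",
              ifelse(m == 1, "private",
              ifelse(m >= soft_min, "softcore", "distributed"))))
  res <- data.frame(element_id = pav$info$element_id, presence = m,
                    category = category, stringsAsFactors = FALSE)
  attr(res, "softcore_fraction") <- softcore_fraction
  attr(res, "n_samples") <- n
  res
}

#' Estimate pan- and core-genome growth curves by resampling
#'
#' For each subset size `n` from 1 to the cohort size, random sample subsets
#' are drawn without replacement and the pangenome size (regions present in
#' at least one subset member) and core-genome size (regions present in all
#' subset members) are counted. Each repetition draws one random sample
#' permutation and uses its first-`n` prefixes, so subsets are nested within
#' a repetition (pan is non-decreasing and core non-increasing along `n`)
#' while each prefix is still a uniform without-replacement subset.
#' Regions present in no sample are excluded from the counts. With `groups`,
#' the estimation runs independently within each group of samples.
#'
#' @param pav A `PAVMatrix`.
#' @param repetitions Number of random permutations per group.
#' @param groups Optional named character vector sample -> group label.
#' @param seed Optional RNG seed recorded in the output.
#' @return Data frame (`group`, `n`, `rep`, `pan`, `core`) with attributes
#'   `repetitions` and `seed`.
#' @export
estimate_sizes <- function(pav, repetitions = 100L, groups = NULL, seed = NULL) {
  stopifnot(repetitions >= 1)
  if (!is.null(seed)) set.seed(seed)
  vals <- pav$values
  vals <- vals[rowSums(vals) > 0, , drop = FALSE]
  samples <- colnames(vals)
  if (is.null(groups)) {
    groups <- setNames(rep("all", length(samples)), samples)
  } else {
    groups <- groups[intersect(names(groups), samples)]
  }
  out <- list()
  for (g in unique(groups)) {
    gs <- names(groups)[groups == g]
    ng <- length(gs)
    if (ng < 2) warning("group ", g, " has fewer than 2 samples")
    sub <- vals[, gs, drop = FALSE]
    for (r in seq_len(repetitions)) {
      perm <- sample(ng)
      pres_any <- rep(FALSE, nrow(sub))
      pres_all <- rep(TRUE, nrow(sub))
      pan <- integer(ng); core <- integer(ng)
      for (n in seq_len(ng)) {
        col <- sub[, perm[n]] > 0
        pres_any <- pres_any | col
        pres_all <- pres_all & col
        pan[n] <- sum(pres_any)
        core[n] <- sum(pres_all)
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, n = seq_len(ng), rep = r, pan = pan, core = core,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "repetitions") <- repetitions
  attr(res, "seed") <- seed
  res
}

#' Per-sample presence counts and per-category tallies
#'
#' @param pav A `PAVMatrix`.
#' @param softcore_fraction Passed to [classify()].
#' @return List with `sample_counts` (named integer vector of present rows
#'   per sample) and `category_counts` (named integer vector per category).
#' @export
sample_counts <- function(pav, softcore_fraction = 0.99) {
  cl <- classify(pav, softcore_fraction)
  list(
    sample_counts = colSums(pav$values),
    category_counts = c(table(factor(cl$category,
      levels = c("core", "softcore", "distributed", "private",
                 "absent_everywhere"))))
  )
}
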