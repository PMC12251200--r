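# Phenotype association: Fisher's exact test for discrete traits, Wilcoxon
# rank-sum for continuous traits, Benjamini-Hochberg adjustment per trait.

# Relative tolerance used when deciding whether a table/statistic is "as
# extreme as" the observed one; guards against floating-point ties in exact
# enumeration (same convention as common exact-test implementations).
.TIE_TOL <- 1e-7

#' Fisher's exact test for a 2 x k contingency table
#'
#' Two-sided exact p-value for independence of the two row categories
#' (e.g. presence/absence) and k column categories (trait levels). The
#' p-value is the total conditional probability, given the margins, of
#' tables whose probability does not exceed the observed table's (with a
#' small relative tolerance for floating-point ties). For k = 2 the
#' hypergeometric support is enumerated directly; for k > 2 all tables with
#' the observed margins are enumerated when the table total is at most
#' `enumeration_limit`, otherwise a seeded Monte Carlo estimate over random
#' margin-preserving tables is returned.
#'
#' @param table 2 x k matrix of non-negative counts (k >= 2).
#' @param enumeration_limit Maximum table total for exact k > 2 enumeration.
#' @param mc_replicates Monte Carlo replicates beyond the limit.
#' @param seed Seed for the Monte Carlo path.
#' @return List with `p_value`, `method` (`"exact"` or `"monte_carlo"`),
#'   `degenerate` (`TRUE` when a margin is zero, in which case p = 1).
#' @export
fisher_exact <- function(table, enumeration_limit = 200L,
                         mc_replicates = 1e5, seed = 1L) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2, ncol(table) >= 2, all(table >= 0))
  rs <- rowSums(table); cs <- colSums(table); N <- sum(table)
  if (N < 1) stop("empty table")
  if (any(rs == 0) || any(cs == 0)) {
    return(list(p_value = 1, method = "exact", degenerate = TRUE))
  }
  if (ncol(table) == 2) {
    # condition on margins; x = top-left cell
    x_obs <- table[1, 1]
    lo <- max(0, rs[1] - cs[2]); hi <- min(rs[1], cs[1])
    support <- lo:hi
    probs <- stats::dhyper(support, cs[1], cs[2], rs[1])
    p_obs <- probs[support == x_obs]
    p <- sum(probs[probs <= p_obs * (1 + .TIE_TOL)])
    return(list(p_value = min(1, p), method = "exact", degenerate = FALSE))
  }
  # 2 x k, k > 2: P(table | margins) = prod_j C(c_j, x_1j) / C(N, r_1)
  lp_table <- function(x1) sum(lchoose(cs, x1)) - lchoose(N, rs[1])
  lp_obs <- lp_table(table[1, ])
  if (N <= enumeration_limit) {
    k <- length(cs)
    acc <- 0
    rec <- function(j, remaining, x1) {
      if (j == k) {
        if (remaining <= cs[k]) {
          lp <- lp_table(c(x1, remaining))
          if (lp <= lp_obs + log1p(.TIE_TOL)) acc <<- acc + exp(lp)
        }
        return(invisible())
      }
      for (v in 0:min(cs[j], remaining)) rec(j + 1L, remaining - v, c(x1, v))
    }
    rec(1L, rs[1], integer(0))
    return(list(p_value = min(1, acc), method = "exact", degenerate = FALSE))
  }
  # Monte Carlo over random tables with the observed margins
  set.seed(seed)
  sims <- stats::r2dtable(mc_replicates, rs, cs)
  lps <- vapply(sims, function(tb) lp_table(tb[1, ]), numeric(1))
  hits <- sum(lps <= lp_obs + log1p(.TIE_TOL))
  list(p_value = (hits + 1) / (mc_replicates + 1), method = "monte_carlo",
       degenerate = FALSE, replicates = mc_replicates)
}

# Distribution of the group-1 rank sum for a midrank multiset: dynamic
# programme counting the subsets of size n1 by (doubled, hence integer)
# rank sum. Returns P(S = s) over s = 0..max.
.ranksum_distribution <- function(ranks2, n1) {
  maxsum <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n1)])
  counts <- matrix(0, n1 + 1L, maxsum + 1L)
  counts[1L, 1L] <- 1
  for (v in ranks2) {
    for (k in n1:1) {
      shifted <- c(rep(0, v), counts[k, seq_len(maxsum + 1L - v)])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  counts[n1 + 1L, ] / choose(length(ranks2), n1)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided test that two samples come from the same distribution. For
#' combined sizes up to `exact_limit` the exact null distribution of the
#' rank sum is computed by dynamic programming over midranks (so ties are
#' handled exactly); the two-sided p is twice the smaller tail probability,
#' capped at 1. Beyond the limit, a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric vectors (missing values dropped); both must be
#'   non-empty after dropping.
#' @param exact_limit Largest `length(x) + length(y)` for the exact path.
#' @return List with `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`), `n_used`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 30L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  if (N <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    pmf <- .ranksum_distribution(ranks2, n1)
    s_obs <- as.integer(round(2 * W))
    cdf <- cumsum(pmf)
    p_le <- cdf[s_obs + 1L]
    p_ge <- 1 - if (s_obs >= 1L) cdf[s_obs] else 0
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = U, p_value = p, method = "exact", n_used = N))
  }
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = U, p_value = 1, method = "normal_approx", n_used = N))
  }
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  list(statistic = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal_approx", n_used = N)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; order-preserving and capped
#' at 1. Thin wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Read a phenotype table
#'
#' TSV with the sample id in the first column and one trait per remaining
#' column. Trait kind is inferred (numeric -> continuous, otherwise
#' discrete) unless declared in `kinds`.
#'
#' @param path TSV path.
#' @param kinds Optional named character vector trait -> `"discrete"` or
#'   `"continuous"`.
#' @return Data frame of traits with rownames = sample ids and attribute
#'   `kinds`.
#' @export
read_phenotypes <- function(path, kinds = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  rownames(df) <- df[[1]]
  df <- df[, -1, drop = FALSE]
  inferred <- vapply(df, function(v) {
    if (is.numeric(v)) "continuous" else "discrete"
  }, character(1))
  if (!is.null(kinds)) inferred[names(kinds)] <- kinds
  for (tr in names(inferred)[inferred == "discrete"]) df[[tr]] <- as.character(df[[tr]])
  attr(df, "kinds") <- inferred
  df
}

#' Test PAV-phenotype association for every region and trait
#'
#' Discrete traits are tested with [fisher_exact()] on the 2 x k table of
#' presence/absence against trait levels; continuous traits with
#' [wilcoxon_rank_sum()] comparing trait values between the presence and
#' absence groups (set `continuous_mode = "coverage"` with a
#' `coverage_profile` to instead compare the region's coverage between PAV
#' groups). By default only regions that vary in the cohort are tested
#' (core and absent-everywhere rows are skipped). Samples missing a trait
#' are dropped per test. Benjamini-Hochberg adjustment is applied per trait
#' across testable regions.
#'
#' @param pav A `PAVMatrix`.
#' @param phenotypes Data frame from [read_phenotypes()] (rownames =
#'   samples) or a compatible data frame.
#' @param distributed_only Skip core and absent-everywhere regions.
#' @param continuous_mode `"phenotype"` (default) tests trait values split
#'   by PAV group; `"coverage"` tests the region's coverage split by PAV
#'   group.
#' @param coverage_profile Required for `continuous_mode = "coverage"`.
#' @param softcore_fraction Passed to [classify()] for the restriction.
#' @param seed Seed forwarded to the Monte Carlo path of [fisher_exact()].
#' @return Data frame with columns `region`, `trait`, `test`, `statistic`,
#'   `p_value`, `p_adjusted`, `n_used`, `effect` (difference in presence
#'   fraction between extreme levels for discrete traits; difference in
#'   group medians for continuous), `note`.
#' @export
associate_all <- function(pav, phenotypes, distributed_only = TRUE,
                          continuous_mode = c("phenotype", "coverage"),
                          coverage_profile = NULL, softcore_fraction = 0.99,
                          seed = 1L) {
  continuous_mode <- match.arg(continuous_mode)
  if (continuous_mode == "coverage" && is.null(coverage_profile)) {
    stop("continuous_mode='coverage' requires coverage_profile")
  }
  samples <- intersect(colnames(pav$values), rownames(phenotypes))
  if (!length(samples)) stop("no overlapping samples between PAV and phenotypes")
  vals <- pav$values[, samples, drop = FALSE]
  kinds <- attr(phenotypes, "kinds")
  if (is.null(kinds)) {
    kinds <- vapply(phenotypes, function(v)
      if (is.numeric(v)) "continuous" else "discrete", character(1))
  }

  rows <- seq_len(nrow(vals))
  if (distributed_only) {
    m <- rowSums(vals)
    rows <- which(m > 0 & m < length(samples))
  }

  out <- list()
  for (trait in colnames(phenotypes)) {
    tv <- phenotypes[samples, trait]
    ok <- !is.na(tv)
    if (kinds[[trait]] == "discrete" && length(unique(tv[ok])) < 2) {
      warning("trait ", trait, " has a single level; skipped")
      next
    }
    res_t <- vector("list", length(rows))
    for (ri in seq_along(rows)) {
      i <- rows[ri]
      pres <- vals[i, ] == 1
      use <- ok
      rec <- list(region = pav$info$element_id[i], trait = trait,
                  statistic = NA_real_, p_value = NA_real_,
                  n_used = sum(use), effect = NA_real_, note = "")
      if (kinds[[trait]] == "discrete") {
        rec$test <- "fisher"
        tab <- table(factor(pres[use], levels = c(TRUE, FALSE)), tv[use])
        if (ncol(tab) < 2) { rec$note <- "single_level"; res_t[[ri]] <- rec; next }
        ft <- fisher_exact(tab, seed = seed)
        rec$p_value <- ft$p_value
        if (ft$degenerate) rec$note <- "degenerate_margin"
        pf <- tab[1, ] / colSums(tab)
        rec$effect <- max(pf) - min(pf)
        if (ncol(tab) == 2) {
          rec$statistic <- unname((tab[1, 1] * tab[2, 2]) /
                                  max(1, tab[1, 2] * tab[2, 1]))
        }
      } else {
        rec$test <- "wilcoxon"
        vv <- if (continuous_mode == "phenotype") tv else
          coverage_profile$values[pav$info$element_id[i], samples]
        a <- vv[use & pres]; b <- vv[use & !pres]
        if (!length(a) || !length(b)) {
          rec$note <- "untestable_group_empty"; res_t[[ri]] <- rec; next
        }
        wt <- wilcoxon_rank_sum(a, b)
        rec$statistic <- wt$statistic
        rec$p_value <- wt$p_value
        rec$n_used <- wt$n_used
        rec$effect <- stats::median(a) - stats::median(b)
      }
      res_t[[ri]] <- rec
    }
    df <- do.call(rbind, lapply(res_t, function(r)
      data.frame(r[c("region", "trait", "test", "statistic", "p_value",
                     "n_used", "effect", "note")], stringsAsFactors = FALSE)))
    if (is.null(df)) next
    df$p_adjusted <- NA_real_
    testable <- !is.na(df$p_value)
    df$p_adjusted[testable] <- bh_adjust(df$p_value[testable])
    out[[trait]] <- df
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no testable trait")
  rownames(res) <- NULL
  res[, c("region", "trait", "test", "statistic", "p_value", "p_adjusted",
          "n_used", "effect", "note")]
}
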