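# Plot functions: the testable surface is each plot's sidecar TSV.

viz_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- shared_cohort()
      prof <- build_profile(sim$elements, sim$samples)
      pav_r <- call_fixed(prof$region, 0.5)
      pav_e <- call_fixed(prof$element, 0.5)
      ph <- read_phenotypes(sim$pheno)
      res <- associate_all(pav_r, ph, seed = 3)
      growth <- estimate_sizes(pav_r, repetitions = 30, seed = 5)
      cache <<- list(sim = sim, prof = prof, pav_r = pav_r, pav_e = pav_e,
                     ph = ph, res = res, growth = growth)
    }
    cache
  }
})

test_that("overview plots emit consistent sidecar tables", {
  fx <- viz_fixture()
  dir <- withr::local_tempdir()

  r <- plot_overview(fx$pav_r, "pav_heat", file.path(dir, "heat.png"))
  expect_gt(file.size(r$file), 0)
  heat <- read.table(r$data_file, header = TRUE, sep = "\t")
  expect_equal(nrow(heat), nrow(fx$pav_r$values) * ncol(fx$pav_r$values))

  r2 <- plot_overview(fx$pav_r, "hist", file.path(dir, "hist.png"))
  tab <- read.table(r2$data_file, header = TRUE, sep = "\t")
  expect_equal(sum(tab$Freq), nrow(fx$pav_r$values))

  r3 <- plot_overview(fx$pav_r, "bar", file.path(dir, "bar.png"))
  bar <- read.table(r3$data_file, header = TRUE, sep = "\t")
  sums <- tapply(bar$proportion, bar$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  r4 <- plot_overview(fx$pav_r, "stat", file.path(dir, "stat.png"))
  st <- read.table(r4$data_file, header = TRUE, sep = "\t")
  expect_equal(sort(st$present), sort(unname(colSums(fx$pav_r$values))))

  empty <- fx$pav_r
  empty$values <- empty$values[0, , drop = FALSE]
  empty$info <- empty$info[0, , drop = FALSE]
  expect_error(plot_overview(empty, "stat", file.path(dir, "no.png")), "empty")
})

test_that("growth plots agree with the deterministic full-cohort point", {
  fx <- viz_fixture()
  dir <- withr::local_tempdir()
  files <- character(0)
  for (style in c("line_err", "jitter", "ribbon")) {
    r <- plot_growth(fx$growth, style, file.path(dir, paste0(style, ".png")))
    expect_gt(file.size(r$file), 0)
    files <- c(files, r$file)
  }
  expect_equal(length(unique(files)), 3)
  summ <- read.table(sub("png$", "tsv", files[1]), header = TRUE, sep = "\t")
  N <- length(fx$sim$samples)
  cl <- classify(fx$pav_r)
  at_n <- summ[summ$n == N, ]
  expect_equal(at_n$mean[at_n$series == "pan"],
               sum(cl$category != "absent_everywhere"))
  expect_equal(at_n$mean[at_n$series == "core"],
               sum(cl$category == "core"))
  expect_equal(at_n$sd, c(0, 0))

  # single-sample cohort degenerates to a single point, no error
  solo <- make_pav(matrix(c(1L, 0L, 1L), 3, 1))
  suppressWarnings(g1 <- estimate_sizes(solo, 5, seed = 1))
  r1 <- plot_growth(g1, "line_err", file.path(dir, "solo.png"))
  expect_equal(unique(read.table(r1$data_file, header = TRUE)$n), 1)
})

test_that("PCA separates planted sample groups and is reproducible", {
  # two groups with disjoint private region sets
  vals <- cbind(matrix(rep(c(1L, 0L), each = 10), 20, 4),
                matrix(rep(c(0L, 1L), each = 10), 20, 4))
  colnames(vals) <- paste0("s", 1:8)
  pav <- make_pav(vals)
  dir <- withr::local_tempdir()
  r <- plot_samples(pav, "pca", file.path(dir, "pca.png"))
  co <- r$coords
  g1 <- co$PC1[1:4]; g2 <- co$PC1[5:8]
  expect_true(max(g1) < min(g2) || min(g1) > max(g2))
  r2 <- plot_samples(pav, "pca", file.path(dir, "pca2.png"))
  expect_equal(r2$coords$PC1, co$PC1)

  expect_error(plot_samples(make_pav(matrix(1L, 3, 5)), "pca",
                            file.path(dir, "const.png")), "variance")
})

test_that("duplicate samples merge first in the Jaccard dendrogram", {
  set.seed(19)
  base <- matrix(rbinom(60, 1, 0.5), 20, 3)
  vals <- cbind(base, base[, 3])  # s4 duplicates s3
  colnames(vals) <- paste0("s", 1:4)
  pav <- make_pav(vals)
  dir <- withr::local_tempdir()
  r <- plot_samples(pav, "cluster", file.path(dir, "clu.png"))
  hc <- r$hclust
  first <- sort(-hc$merge[1, ])
  expect_equal(first, c(3, 4))
  expect_equal(hc$height[1], 0)
  ord <- read.table(r$data_file, header = TRUE, sep = "\t")
  expect_setequal(ord$sample, paste0("s", 1:4))
})

test_that("association plots flag the planted region and normalise blocks", {
  fx <- viz_fixture()
  dir <- withr::local_tempdir()
  linked <- paste0(fx$sim$linked_gene, ":gene:1")

  r <- plot_association(fx$res, "manhattan", file.path(dir, "man.png"),
                        trait = "group", pav = fx$pav_r)
  man <- read.table(r$data_file, header = TRUE, sep = "\t")
  expect_true(man$top5[man$region == linked])
  expect_equal(man$neglog10_p, -log10(pmax(man$p_value, 1e-300)))

  rb <- plot_association(fx$res, "pheno_block", file.path(dir, "blk.png"),
                         trait = "group", region = linked, pav = fx$pav_r,
                         phenotypes = fx$ph)
  blk <- read.table(rb$data_file, header = TRUE, sep = "\t")
  sums <- tapply(blk$proportion, blk$level, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  rv <- plot_association(fx$res, "pheno_vio", file.path(dir, "vio.png"),
                         trait = "height", region = linked, pav = fx$pav_r,
                         phenotypes = fx$ph)
  expect_gt(file.size(rv$file), 0)
  rh <- plot_association(fx$res, "pheno_heat", file.path(dir, "ph.png"))
  expect_gt(file.size(rh$file), 0)

  expect_error(plot_association(fx$res, "manhattan", file.path(dir, "x.png"),
                                trait = "no_such_trait", pav = fx$pav_r),
               "matches nothing")
})

test_that("all p = 1 gives flat zero Manhattan heights", {
  fx <- viz_fixture()
  res <- fx$res[fx$res$trait == "group" & !is.na(fx$res$p_value), ]
  res$p_value <- 1
  dir <- withr::local_tempdir()
  r <- plot_association(res, "manhattan", file.path(dir, "flat.png"),
                        trait = "group", pav = fx$pav_r)
  man <- read.table(r$data_file, header = TRUE, sep = "\t")
  expect_true(all(man$neglog10_p == 0))
})

test_that("element heatmaps reproduce the PAV matrix cell-for-cell", {
  fx <- viz_fixture()
  dir <- withr::local_tempdir()
  gid <- fx$sim$linked_gene
  r <- plot_elements(gid, fx$pav_e, "pav", file.path(dir, "ele.png"),
                     phenotypes = fx$ph, traits = "group")
  long <- read.table(r$data_file, header = TRUE, sep = "\t")
  for (k in sample(nrow(long), 20)) {
    expect_equal(long$value[k],
                 unname(fx$pav_e$values[long$element[k], long$sample[k]]))
  }
  # phenotype strip aligns with the sample order
  expect_equal(unname(long$pheno_group),
               unname(fx$ph[long$sample, "group"]))

  rc <- plot_elements(gid, fx$prof$element, "cov", file.path(dir, "cov.png"))
  expect_gt(file.size(rc$file), 0)
  rd <- plot_elements(gid, fx$prof$element, "depth", file.path(dir, "dep.png"))
  expect_gt(file.size(rd$file), 0)
  expect_error(plot_elements("nope", fx$pav_e, "pav", file.path(dir, "n.png")),
               "unknown parent")

  # single-element parent renders a one-column heatmap
  one <- fx$pav_e
  keep <- which(one$info$element_id == long$element[1])
  solo <- pavkit:::new_pav(one$info[keep, , drop = FALSE],
                           one$values[keep, , drop = FALSE], one$meta)
  rs <- plot_elements(solo$info$parent[1], solo, "pav",
                      file.path(dir, "solo.png"))
  expect_equal(length(unique(read.table(rs$data_file, header = TRUE,
                                        sep = "\t")$element)), 1)
})
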