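# normalization, dispersion estimation, NB testing, contrasts, Venn, FPKM

test_that("median-of-ratios matches the hand-computed example", {
  m <- matrix(c(10, 30, 20, 60), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- medianOfRatios(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  # identical columns -> unit factors
  m2 <- cbind(a = c(5, 9, 11), b = c(5, 9, 11))
  expect_equal(unname(medianOfRatios(m2)), c(1, 1))
  # doubling one column doubles its factor and leaves the other fixed
  # up to the shared geometric-mean rescaling
  m3 <- m2; m3[, 2] <- m3[, 2] * 2
  sf3 <- medianOfRatios(m3)
  expect_equal(sf3[["b"]] / sf3[["a"]], 2, tolerance = 1e-10)
  expect_error(medianOfRatios(matrix(c(0, 1, 1, 0), 2)), "positive")
})

test_that("size-factor ratios agree with an independent implementation", {
  set.seed(19)
  m <- matrix(rnbinom(200 * 6, mu = 80, size = 5), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  m[, 3] <- m[, 3] * 3L  # one deep library
  mine <- medianOfRatios(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # both estimators are defined up to a common scale: compare ratios
  expect_equal(unname(mine / mine[1]), unname(ref / ref[1]),
               tolerance = 1e-10)
})

test_that("size factors of a normalized matrix are 1", {
  set.seed(3)
  m <- matrix(rpois(300, 50) + 1, 50, 6)
  norm <- sweep(m, 2, medianOfRatios(m), "/")
  expect_equal(unname(medianOfRatios(norm)), rep(1, 6), tolerance = 1e-6)
})

test_that("log2 fold change reproduces printed table values and edge rules", {
  expect_equal(round(as.numeric(log2FoldChange(157.6, 517199.6)), 1), 11.7)
  expect_equal(round(as.numeric(log2FoldChange(120.8, 25.0)), 1), -2.3)
  expect_equal(as.numeric(log2FoldChange(7, 7)), 0)
  both0 <- log2FoldChange(0, 0)
  expect_true(is.na(as.numeric(both0)))
  expect_true(attr(both0, "undefined"))
  one0 <- log2FoldChange(0, 15)
  expect_true(attr(one0, "pseudo"))
  expect_equal(as.numeric(one0), log2(16 / 1))
})

test_that("all 35 fixture rows reproduce the printed log2 FC within 0.1", {
  t1 <- loadFixture("table1")
  for (ln in c("RL", "YL")) {
    h <- t1[[paste0("readcount_heat_", ln)]]
    c0 <- t1[[paste0("readcount_control_", ln)]]
    ok <- !is.na(h)
    got <- round(as.numeric(log2FoldChange(c0[ok], h[ok])), 1)
    expect_true(all(abs(got - t1[[paste0("log2fc_", ln)]][ok]) <=
                      0.1 + 1e-9))
  }
})

test_that("dispersion estimation recovers a known dispersion", {
  sim <- makeTwoGroupCE(n_genes = 5000, mu = 500, alpha = 0.1, seed = 5)
  ce <- estimateDispersions(sim$ce)
  gw <- SummarizedExperiment::rowData(ce)$dispersion_genewise
  expect_equal(mean(gw), 0.1, tolerance = 0.2)
  # Poisson data: trend intercept and typical final dispersion near zero
  simP <- makeTwoGroupCE(n_genes = 3000, mu = 200, alpha = 0, seed = 6)
  ceP <- estimateDispersions(simP$ce)
  expect_lt(median(dispersions(ceP)), 0.01)
  expect_lt(S4Vectors::metadata(ceP)$dispersion_trend[["a0"]], 0.01)
})

test_that("constant replicates give a zero gene-wise estimate", {
  cnt <- matrix(rep(c(10L, 20L, 40L), each = 6), 3, 6, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:6)))
  suppressWarnings({
    ce <- CountExperiment(cnt, line = rep("L", 6),
                          condition = rep(c("c", "h"), each = 3))
    ce <- estimateDispersions(ce)
  })
  expect_true(all(SummarizedExperiment::rowData(ce)$dispersion_genewise == 0))
})

test_that("identical groups give zero fold change and p = 1", {
  cnt <- matrix(rep(c(10L, 25L, 100L, 3L), 6), 4, 6,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  ce <- CountExperiment(cnt, line = rep("L", 6),
                        condition = rep(c("c", "h"), each = 3))
  suppressWarnings(res <- nbTest(ce, paste0("s", 1:3), paste0("s", 4:6)))
  tb <- resultsTable(res)
  expect_equal(tb$log2_fc, rep(0, 4))
  expect_equal(tb$p_value, rep(1, 4))
  expect_false(any(tb$de_flag))
})

test_that("the Wald test is calibrated and powerful on spiked data", {
  sim <- makeTwoGroupCE(n_genes = 4000, mu = 200, alpha = 0.05,
                        lfc = 2, n_de = 200, seed = 7)
  res <- nbTest(sim$ce, paste0("s", 1:3), paste0("s", 4:6))
  tb <- resultsTable(res)
  recall <- mean(tb$de_flag[match(rownames(sim$ce)[sim$de], tb$gene_id)])
  expect_gte(recall, 0.9)
  fpr <- mean(tb$p_value[match(rownames(sim$ce)[!sim$de], tb$gene_id)] <
                0.05, na.rm = TRUE)
  expect_lt(fpr, 0.09)
})

test_that("DE filter biconditional holds gene by gene", {
  sim <- makeTwoGroupCE(n_genes = 800, mu = 50, alpha = 0.2, lfc = 3,
                        n_de = 80, seed = 8)
  tb <- resultsTable(nbTest(sim$ce, paste0("s", 1:3), paste0("s", 4:6)))
  manual <- !is.na(tb$p_value) & tb$p_value < 0.05 & abs(tb$log2_fc) > 1
  expect_identical(tb$de_flag, manual)
  expect_true(all(tb$direction[tb$de_flag & tb$log2_fc > 0] == "up"))
  expect_true(all(tb$direction[tb$de_flag & tb$log2_fc < 0] == "down"))
  expect_true(all(tb$direction[!tb$de_flag] == "ns"))
})

test_that("group preconditions are enforced", {
  sim <- makeTwoGroupCE(n_genes = 20, seed = 9)
  expect_error(nbTest(sim$ce, paste0("s", 1:3), paste0("s", 3:5)),
               "disjoint")
  expect_error(nbTest(sim$ce, "s1", paste0("s", 4:6)), "2 samples")
  expect_error(nbTest(sim$ce, c("s1", "nope"), paste0("s", 4:6)),
               "unknown sample")
})

test_that("the four standard contrasts share one gene universe", {
  ce <- simulateCounts(countSimParams(n_genes = 600L, seed = 10L))
  cons <- runContrasts(ce)
  expect_named(cons, c("I", "II", "III", "IV"))
  universes <- lapply(cons, function(r) resultsTable(r)$gene_id)
  for (u in universes[-1]) expect_identical(u, universes[[1]])
  # labels round-trip
  expect_equal(cons$III@contrast, "III")
  expect_match(cons$III@label_B, "heat")
})

test_that("a missing design cell is reported by name", {
  ce <- simulateCounts(countSimParams(
    n_genes = 50L,
    design = data.frame(line = "sensitive", condition = c("control", "heat"),
                        n_replicates = 3L),
    de_fraction = c(sensitive = 0), seed = 11L))
  expect_error(runContrasts(ce), "tolerant")
})

test_that("more spiked genes in the sensitive line yield more DEGs there", {
  wins <- vapply(1:5, function(i) {
    ce <- simulateCounts(countSimParams(n_genes = 1500L, seed = 100L + i))
    cons <- runContrasts(ce)
    length(degs(cons$III)) > length(degs(cons$IV))
  }, logical(1))
  expect_true(all(wins))
})

test_that("Venn partition obeys the set identities", {
  vp <- vennPartition(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(vp$common, c("b", "c"))
  expect_setequal(vp$only_A, "a")
  expect_setequal(vp$only_B, "d")
  empty <- vennPartition(c("a", "b"), character(0))
  expect_length(empty$common, 0)
  set.seed(12)
  for (i in 1:20) {
    A <- sample(letters, sample(0:15, 1))
    B <- sample(letters, sample(0:15, 1))
    vp <- vennPartition(A, B)
    expect_equal(length(vp$common) + length(vp$only_A), length(A))
    expect_equal(length(vp$common) + length(vp$only_B), length(B))
    expect_length(intersect(vp$only_A, vp$only_B), 0)
  }
})

test_that("discordant direction in shared DEGs is kept and flagged", {
  mk <- function(lfc) data.frame(gene_id = "g1", base_mean_A = 10,
                                 base_mean_B = 10 * 2^lfc, log2_fc = lfc,
                                 p_value = 1e-4, de_flag = TRUE,
                                 direction = ifelse(lfc > 0, "up", "down"))
  rA <- new("ContrastResult", table = mk(2), contrast = "III",
            label_A = "a", label_B = "b", p_thr = 0.05, lfc_thr = 1)
  rB <- new("ContrastResult", table = mk(-2), contrast = "IV",
            label_A = "a", label_B = "b", p_thr = 0.05, lfc_thr = 1)
  vp <- vennPartition(rA, rB)
  expect_identical(vp$common, "g1")
  expect_identical(vp$discordant, "g1")
})

test_that("FPKM arithmetic and scale properties hold", {
  cnt <- matrix(c(100L, 0L), 2, 1,
                dimnames = list(c("g1", "g2"), "s1"))
  cnt <- cbind(cnt, s2 = c(100L, 0L))
  cnt["g2", "s2"] <- 999900L  # pad library to 1e6
  cnt["g2", "s1"] <- 999900L
  ce <- CountExperiment(cnt, line = c("L", "L"),
                        condition = c("control", "heat"),
                        gene_length = c(1000, 500))
  f <- fpkm(ce)
  expect_equal(f["g1", "s1"], 100)
  # doubling the library depth (same gene count) halves FPKM
  cnt2 <- cnt; cnt2["g2", "s2"] <- 1999900L
  ce2 <- CountExperiment(cnt2, line = c("L", "L"),
                         condition = c("control", "heat"),
                         gene_length = c(1000, 500))
  expect_equal(fpkm(ce2)["g1", "s2"], 50)
  ce3 <- CountExperiment(cnt, line = c("L", "L"),
                         condition = c("control", "heat"))
  expect_error(fpkm(ce3), "length")
})

test_that("counts reader validates inputs and round-trips", {
  ce <- simulateCounts(countSimParams(n_genes = 30L, seed = 13L))
  d <- tempfile(); dir.create(d)
  cf <- file.path(d, "counts.tsv"); sf <- file.path(d, "samples.tsv")
  write.table(data.frame(gene_id = rownames(ce),
                         SummarizedExperiment::assay(ce),
                         check.names = FALSE),
              cf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = colnames(ce),
                         line = SummarizedExperiment::colData(ce)$line,
                         condition =
                           SummarizedExperiment::colData(ce)$condition),
              sf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readCounts(cf, sf)
  expect_equal(SummarizedExperiment::assay(back),
               SummarizedExperiment::assay(ce))
  bad <- file.path(d, "bad.tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t5\t-2"), bad)
  expect_error(readCounts(bad, sf), "bad.tsv")
  unlink(d, recursive = TRUE)
})
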