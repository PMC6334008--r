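#' @include AllClasses.R AllGenerics.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#'   rowData<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Construct a CountExperiment
#'
#' @param counts gene x sample matrix of non-negative integers with row and
#'   column names.
#' @param line,condition per-sample factors (heat-sensitive/tolerant line and
#'   control/heat condition).
#' @param gene_length optional per-gene transcript length in bp.
#' @return a \linkS4class{CountExperiment}.
#' @export
#' @examples
#' m <- matrix(rpois(40, 20), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' ce <- CountExperiment(m, line = rep("RL", 4),
#'                       condition = rep(c("control", "heat"), each = 2))
CountExperiment <- function(counts, line, condition, gene_length = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  cd <- DataFrame(line = line, condition = condition,
                  row.names = colnames(counts))
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(gene_length)) rd$gene_length <- gene_length
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = cd, rowData = rd)
  new("CountExperiment", se)
}

#' Read a gene x sample count matrix and its sample table from TSV
#'
#' The counts file has a header of sample identifiers and gene identifiers in
#' the first column; the sample table maps sample_id to line and condition.
#'
#' @param counts_tsv path to the counts TSV.
#' @param samples_tsv path to the sample-metadata TSV (columns sample_id,
#'   line, condition).
#' @param annotation_tsv optional gene annotation TSV with a gene_id column
#'   and, if present, length_bp stored as gene lengths.
#' @return a \linkS4class{CountExperiment}.
#' @export
readCounts <- function(counts_tsv, samples_tsv, annotation_tsv = NULL) {
  cts <- utils::read.delim(counts_tsv, row.names = 1, check.names = FALSE)
  cts <- as.matrix(cts)
  if (!is.numeric(cts)) suppressWarnings(storage.mode(cts) <- "numeric")
  if (any(is.na(cts)) || any(cts < 0))
    stop("corrupt counts file ", counts_tsv,
         ": non-numeric, missing or negative entries (first at row ",
         which(is.na(cts) | cts < 0)[1], ")")
  smp <- utils::read.delim(samples_tsv)
  if (!all(c("sample_id", "line", "condition") %in% names(smp)))
    stop("sample table ", samples_tsv,
         " needs columns sample_id, line, condition")
  missing <- setdiff(colnames(cts), smp$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  smp <- smp[match(colnames(cts), smp$sample_id), ]
  len <- NULL
  if (!is.null(annotation_tsv)) {
    ann <- utils::read.delim(annotation_tsv)
    if ("length_bp" %in% names(ann))
      len <- ann$length_bp[match(rownames(cts), ann$gene_id)]
  }
  CountExperiment(cts, line = smp$line, condition = smp$condition,
                  gene_length = len)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-positive genes of the ratio of its
#' count to the gene's geometric mean across samples; the factors are then
#' standardized to geometric mean 1, which makes the estimator idempotent
#' (the size factors of an already-normalized matrix are all 1).
#'
#' @param counts gene x sample matrix.
#' @return per-sample size factors.
#' @export
#' @examples
#' medianOfRatios(matrix(c(10, 30, 20, 60), 2))  # 0.7071, 1.4142
medianOfRatios <- function(counts) {
  counts <- as.matrix(counts)
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok))
    stop("no gene has positive counts in every sample; ",
         "filter samples or genes before normalizing")
  logsf <- apply(counts, 2, function(col)
    median(log(col[ok]) - loggeo[ok]))
  exp(logsf - mean(logsf))
}

#' @describeIn medianOfRatios estimate and store size factors on a
#'   \linkS4class{CountExperiment}.
#' @param object a \linkS4class{CountExperiment}.
#' @param ... unused.
#' @export
setMethod("estimateSizeFactors", "CountExperiment", function(object, ...) {
  sf <- medianOfRatios(assay(object, "counts"))
  colData(object)$sizeFactor <- sf
  object
})

#' @describeIn medianOfRatios stored size factors.
#' @export
setMethod("sizeFactors", "CountExperiment", function(object) {
  colData(object)$sizeFactor
})

#' @describeIn medianOfRatios counts divided by their sample's size factor.
#' @export
setMethod("normalizedCounts", "CountExperiment", function(object) {
  sf <- sizeFactors(object)
  if (is.null(sf)) sf <- medianOfRatios(assay(object, "counts"))
  sweep(assay(object, "counts"), 2, sf, "/")
})

#' Log2 fold change between two normalized means
#'
#' Computes log2(mean_heat / mean_control).  When exactly one of the two
#' means is zero, a pseudocount of 1 is added to both (flagged in the
#' "pseudo" attribute); when both are zero the result is NA (flagged in the
#' "undefined" attribute).
#'
#' @param mean_control,mean_heat non-negative normalized-count means
#'   (vectorized).
#' @param pseudocount value added to both means when one is zero.
#' @return numeric log2 ratios with attributes "pseudo" and "undefined".
#' @export
#' @examples
#' round(log2FoldChange(157.6, 517199.6), 1)  # 11.7
#' round(log2FoldChange(120.8, 25.0), 1)      # -2.3
log2FoldChange <- function(mean_control, mean_heat, pseudocount = 1) {
  stopifnot(length(mean_control) == length(mean_heat),
            all(mean_control >= 0, na.rm = TRUE),
            all(mean_heat >= 0, na.rm = TRUE))
  undef <- mean_control == 0 & mean_heat == 0
  pseudo <- !undef & (mean_control == 0 | mean_heat == 0)
  a <- ifelse(pseudo, mean_control + pseudocount, mean_control)
  b <- ifelse(pseudo, mean_heat + pseudocount, mean_heat)
  out <- ifelse(undef, NA_real_, log2(b / a))
  attr(out, "pseudo") <- pseudo
  attr(out, "undefined") <- undef
  out
}

#' Estimate per-gene negative-binomial dispersions
#'
#' Method-of-moments gene-wise estimates on normalized counts,
#' alpha_g = max(0, (s2_g - mu_g) / mu_g^2), with s2_g the pooled
#' within-replicate-group variance (groups = line x condition cells), then a
#' decreasing trend alpha(mu) = a0 + a1/mu fitted by least squares to the
#' positive gene-wise estimates.  The final dispersion is the maximum of the
#' gene-wise estimate and the trend value (conservative sharing).  All-zero
#' genes get NA.
#'
#' @param object a \linkS4class{CountExperiment}.
#' @param trend_min_mu genes with normalized mean below this are excluded
#'   from the trend fit (the gene-wise moment estimator carries an O(1/mu)
#'   ratio bias that would inflate the fitted intercept); the trend is still
#'   evaluated for all genes.
#' @param ... unused.
#' @return the object with rowData columns dispersion_genewise, dispersion
#'   and metadata entry dispersion_trend = c(a0, a1).
#' @export
setMethod("estimateDispersions", "CountExperiment",
          function(object, trend_min_mu = 20, ...) {
  if (is.null(sizeFactors(object))) object <- estimateSizeFactors(object)
  q <- normalizedCounts(object)
  cell <- interaction(colData(object)$line, colData(object)$condition,
                      drop = TRUE)
  mu <- rowMeans(q)
  num <- 0; den <- 0
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    if (length(idx) < 2) next
    v <- apply(q[, idx, drop = FALSE], 1, var)
    num <- num + (length(idx) - 1) * v
    den <- den + (length(idx) - 1)
  }
  if (den == 0) stop("need at least 2 replicates in some line x condition cell")
  s2 <- num / den
  genewise <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), NA_real_)
  ## the moment estimator's ratio bias is O(1/mu), so fit the trend where it
  ## is approximately unbiased and evaluate it everywhere
  pos <- which(!is.na(genewise) & genewise > 0 & mu >= trend_min_mu)
  if (length(pos) < 10)
    pos <- which(!is.na(genewise) & genewise > 0)
  if (length(pos) >= 10) {
    fit <- lm(genewise[pos] ~ I(1 / mu[pos]))
    a <- coef(fit)
  } else {
    a <- c(mean(genewise, na.rm = TRUE), 0)
  }
  trend <- pmax(a[1] + a[2] / mu, 1e-8)
  final <- ifelse(is.na(genewise), NA_real_, pmax(genewise, trend))
  rowData(object)$dispersion_genewise <- genewise
  rowData(object)$dispersion <- final
  metadata(object)$dispersion_trend <- setNames(as.numeric(a), c("a0", "a1"))
  object
})

#' @describeIn estimateDispersions-CountExperiment-method stored final
#'   dispersions.
#' @export
setMethod("dispersions", "CountExperiment", function(object) {
  rowData(object)$dispersion
})

#' Per-gene negative-binomial Wald test between two sample groups
#'
#' For each gene, compares normalized-count means between groups A
#' (reference) and B with a Wald test on the difference of log means.  Under
#' the NB model Var(q_ij) = mu/s_j + alpha mu^2, so the delta-method variance
#' of log(mean) is (1/n^2) sum_j (1/(mu s_j) + alpha); the two-sided p-value
#' uses the normal reference distribution.  The log2 fold change is B
#' relative to A with the zero-mean pseudocount rule of
#' \code{\link{log2FoldChange}}, and the strict filter de_flag = (p < p_thr)
#' and (|log2 FC| > lfc_thr) is applied.
#'
#' @param object a \linkS4class{CountExperiment} (size factors and
#'   dispersions are estimated on the full object if absent).
#' @param group_A,group_B disjoint character vectors of sample names (or
#'   logical/integer column indices), each of length >= 2.
#' @param p_thr,lfc_thr DE filter thresholds.
#' @param genes optional gene universe; default: genes with nonzero total
#'   count across the compared samples.
#' @param contrast,label_A,label_B labels stored in the result.
#' @return a \linkS4class{ContrastResult}.
#' @export
nbTest <- function(object, group_A, group_B, p_thr = 0.05, lfc_thr = 1,
                   genes = NULL, contrast = "custom",
                   label_A = "A", label_B = "B") {
  stopifnot(is(object, "CountExperiment"))
  idx <- function(g) {
    if (is.character(g)) match(g, colnames(object))
    else if (is.logical(g)) which(g)
    else as.integer(g)
  }
  iA <- idx(group_A); iB <- idx(group_B)
  if (anyNA(iA) || anyNA(iB)) stop("unknown sample names in group definition")
  if (length(intersect(iA, iB))) stop("groups must be disjoint")
  if (length(iA) < 2 || length(iB) < 2)
    stop("each group needs at least 2 samples")
  if (is.null(sizeFactors(object))) object <- estimateSizeFactors(object)
  if (is.null(dispersions(object))) object <- estimateDispersions(object)
  cts <- assay(object, "counts")
  if (is.null(genes))
    genes <- rownames(cts)[rowSums(cts[, c(iA, iB), drop = FALSE]) > 0]
  sf <- sizeFactors(object)
  q <- sweep(cts, 2, sf, "/")[genes, , drop = FALSE]
  alpha <- dispersions(object)[match(genes, rownames(object))]
  muA <- rowMeans(q[, iA, drop = FALSE])
  muB <- rowMeans(q[, iB, drop = FALSE])
  lfc <- log2FoldChange(muA, muB)
  pseudo <- attr(lfc, "pseudo"); undef <- attr(lfc, "undefined")
  ## pseudocounted means for the variance of log means
  mA <- ifelse(pseudo, muA + 1, muA)
  mB <- ifelse(pseudo, muB + 1, muB)
  alpha_use <- ifelse(is.na(alpha), 0, alpha)
  vlA <- (1 / length(iA)^2) *
    (rowSums(outer(1 / mA, 1 / sf[iA])) + length(iA) * alpha_use)
  vlB <- (1 / length(iB)^2) *
    (rowSums(outer(1 / mB, 1 / sf[iB])) + length(iB) * alpha_use)
  z <- (log(mB) - log(mA)) / sqrt(vlA + vlB)
  p <- 2 * pnorm(-abs(z))
  p[undef] <- NA_real_
  lfc_num <- as.numeric(lfc)
  de <- !is.na(p) & !is.na(lfc_num) & p < p_thr & abs(lfc_num) > lfc_thr
  direction <- ifelse(!de, "ns", ifelse(lfc_num > 0, "up", "down"))
  tb <- data.frame(gene_id = genes, base_mean_A = muA, base_mean_B = muB,
                   log2_fc = lfc_num, p_value = p,
                   padj = p.adjust(p, "BH"), de_flag = de,
                   direction = direction, pseudo_flag = pseudo,
                   undefined_flag = undef, row.names = NULL)
  new("ContrastResult", table = tb, contrast = contrast,
      label_A = label_A, label_B = label_B, p_thr = p_thr, lfc_thr = lfc_thr)
}

#' Run the four standard line-by-condition contrasts
#'
#' I: sensitive vs tolerant at control temperature; II: sensitive vs tolerant
#' at heat; III: heat vs control within the sensitive line; IV: heat vs
#' control within the tolerant line.  Fold changes are B relative to A where
#' A is the tolerant line (I, II) or the control condition (III, IV).  All
#' four results share the gene universe of nonzero-total genes.
#'
#' @param object a \linkS4class{CountExperiment}.
#' @param sensitive,tolerant line labels in \code{colData(object)$line}.
#' @param control,heat condition labels.
#' @param p_thr,lfc_thr DE filter thresholds.
#' @return named list of four \linkS4class{ContrastResult}s ("I".."IV").
#' @export
runContrasts <- function(object, sensitive = "sensitive",
                         tolerant = "tolerant", control = "control",
                         heat = "heat", p_thr = 0.05, lfc_thr = 1) {
  stopifnot(is(object, "CountExperiment"))
  cd <- colData(object)
  cellOf <- function(ln, cond) {
    s <- colnames(object)[cd$line == ln & cd$condition == cond]
    if (length(s) < 2)
      stop("design cell (", ln, ", ", cond, ") is missing or has < 2 samples")
    s
  }
  sc <- cellOf(sensitive, control); sh <- cellOf(sensitive, heat)
  tc <- cellOf(tolerant, control); th <- cellOf(tolerant, heat)
  if (is.null(sizeFactors(object))) object <- estimateSizeFactors(object)
  if (is.null(dispersions(object))) object <- estimateDispersions(object)
  universe <- rownames(object)[rowSums(assay(object, "counts")) > 0]
  list(
    I = nbTest(object, tc, sc, p_thr, lfc_thr, genes = universe,
               contrast = "I", label_A = paste0(tolerant, ":", control),
               label_B = paste0(sensitive, ":", control)),
    II = nbTest(object, th, sh, p_thr, lfc_thr, genes = universe,
                contrast = "II", label_A = paste0(tolerant, ":", heat),
                label_B = paste0(sensitive, ":", heat)),
    III = nbTest(object, sc, sh, p_thr, lfc_thr, genes = universe,
                 contrast = "III", label_A = paste0(sensitive, ":", control),
                 label_B = paste0(sensitive, ":", heat)),
    IV = nbTest(object, tc, th, p_thr, lfc_thr, genes = universe,
                contrast = "IV", label_A = paste0(tolerant, ":", control),
                label_B = paste0(tolerant, ":", heat)))
}

#' Partition two DEG sets as in a two-set Venn diagram
#'
#' Splits the DEG sets of two contrasts into shared and contrast-specific
#' subsets and tallies up/down directions.  Genes DE in both contrasts with
#' opposite directions are kept and flagged discordant.
#'
#' @param res_A,res_B \linkS4class{ContrastResult}s (or character gene sets,
#'   in which case directions are unavailable).
#' @param label_A,label_B set labels for the summary table.
#' @return object of class \code{degPartition}: common, only_A, only_B,
#'   counts (up/down/total per set), discordant.
#' @export
vennPartition <- function(res_A, res_B, label_A = NULL, label_B = NULL) {
  getSet <- function(r) if (is(r, "ContrastResult")) degs(r) else as.character(r)
  getDir <- function(r, g) {
    if (!is(r, "ContrastResult")) return(setNames(rep(NA_character_,
                                                      length(g)), g))
    tb <- resultsTable(r)
    setNames(tb$direction[match(g, tb$gene_id)], g)
  }
  A <- getSet(res_A); B <- getSet(res_B)
  if (is.null(label_A))
    label_A <- if (is(res_A, "ContrastResult")) res_A@contrast else "A"
  if (is.null(label_B))
    label_B <- if (is(res_B, "ContrastResult")) res_B@contrast else "B"
  common <- intersect(A, B)
  dirA <- getDir(res_A, A); dirB <- getDir(res_B, B)
  discordant <- common[!is.na(dirA[common]) & !is.na(dirB[common]) &
                         dirA[common] != dirB[common]]
  counts <- data.frame(
    set = c(label_A, label_B),
    up = c(sum(dirA == "up", na.rm = TRUE), sum(dirB == "up", na.rm = TRUE)),
    down = c(sum(dirA == "down", na.rm = TRUE),
             sum(dirB == "down", na.rm = TRUE)),
    total = c(length(A), length(B)))
  structure(list(common = common, only_A = setdiff(A, B),
                 only_B = setdiff(B, A), counts = counts,
                 discordant = discordant,
                 labels = c(label_A, label_B)),
            class = "degPartition")
}

#' @export
print.degPartition <- function(x, ...) {
  cat("DEG partition:", x$labels[1], "vs", x$labels[2], "\n")
  cat(sprintf("  common %d | only %s %d | only %s %d | discordant %d\n",
              length(x$common), x$labels[1], length(x$only_A),
              x$labels[2], length(x$only_B), length(x$discordant)))
  print(x$counts)
  invisible(x)
}

#' FPKM expression values
#'
#' FPKM[g, j] = counts[g, j] * 1e9 / (gene_length[g] * total_counts[j]).
#'
#' @param object a \linkS4class{CountExperiment} with rowData gene_length.
#' @return gene x sample FPKM matrix.
#' @export
setMethod("fpkm", "CountExperiment", function(object) {
  len <- rowData(object)$gene_length
  if (is.null(len)) stop("gene lengths are required for FPKM; ",
                         "set rowData(object)$gene_length")
  if (any(is.na(len) | len <= 0)) stop("gene lengths must be positive")
  cts <- assay(object, "counts")
  sweep(cts * 1e9 / len, 2, colSums(cts), "/")
})
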