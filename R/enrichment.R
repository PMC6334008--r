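#' @include AllClasses.R AllGenerics.R
NULL

#' Fit a length-bias probability weighting function
#'
#' Gene-level differential-expression calls are biased toward long genes
#' (more reads, more power).  The PWF estimates P(DE | length) as a monotone
#' non-decreasing function of length: genes are split into equal-count
#' length bins, the DE proportion per bin is pooled by isotonic regression
#' in length order, and each gene receives its bin's fitted value, clipped
#' to (1e-6, 1 - 1e-6).
#'
#' @param de logical (or 0/1) per-gene DE indicator, named by gene.
#' @param lengths per-gene lengths in bp, same order.
#' @param nbins number of equal-count length bins.
#' @return named per-gene weights in (0, 1); attribute "bins" carries the
#'   bin summary used for the fit.
#' @export
fitPWF <- function(de, lengths, nbins = 20) {
  stopifnot(length(de) == length(lengths))
  de <- as.logical(de)
  ok <- !is.na(de) & !is.na(lengths) & lengths > 0
  if (sum(ok) < 50) stop("need at least 50 genes with lengths to fit a PWF")
  genes <- if (!is.null(names(de))) names(de) else as.character(seq_along(de))
  w <- rep(NA_real_, length(de)); names(w) <- genes
  frac <- mean(de[ok])
  if (frac == 0 || frac == 1) {
    warning("all genes ", if (frac == 1) "DE" else "non-DE",
            ": flat weights")
    w[ok] <- min(max(frac, 1e-6), 1 - 1e-6)
    return(w)
  }
  nbins <- min(nbins, max(2, floor(sum(ok) / 10)))
  ord <- order(lengths[ok])
  bin <- ceiling(seq_along(ord) / (sum(ok) / nbins))
  bin <- pmin(bin, nbins)
  prop <- tapply(de[ok][ord], bin, mean)
  midlen <- tapply(lengths[ok][ord], bin, median)
  iso <- isoreg(seq_along(prop), as.numeric(prop))$yf
  wk <- pmin(pmax(iso, 1e-6), 1 - 1e-6)
  w[ok][ord] <- wk[bin]
  attr(w, "bins") <- data.frame(bin = seq_along(wk), median_length = midlen,
                                prop_de = as.numeric(prop), weight = wk)
  w
}

## ---- Wallenius non-central hypergeometric tail ------------------------------

## Exact dynamic program over sequential biased draws: m1 genes of weight w,
## m2 of weight 1, n draws without replacement.  Returns the full pmf.
.walleniusPMFRecursive <- function(m1, m2, n, w) {
  probs <- c(1, rep(0, min(n, m1)))  # P(i successes) after j draws
  for (j in seq_len(n)) {
    upper <- min(j, m1)
    newp <- numeric(min(n, m1) + 1)
    for (i in 0:min(j - 1, m1)) {
      p <- probs[i + 1]
      if (p == 0) next
      wc <- (m1 - i) * w
      wo <- m2 - (j - 1 - i)
      tot <- wc + wo
      if (tot <= 0) next
      if (wc > 0 && i + 1 <= min(n, m1))
        newp[i + 2] <- newp[i + 2] + p * wc / tot
      if (wo > 0) newp[i + 1] <- newp[i + 1] + p * wo / tot
    }
    probs <- newp
  }
  probs
}

## Wallenius pmf at k via the integral representation
##   P(k) = C(m1,k) C(m2,n-k) * Int_0^1 (1 - t^(w/D))^k (1 - t^(1/D))^(n-k) dt
## with D = w(m1-k) + (m2-(n-k)); substituting t = u^D spreads the mass over
## (0,1) (the raw integrand is confined to an O(exp(-D)) sliver at 0)
.walleniusPMFIntegral <- function(k, m1, m2, n, w) {
  D <- w * (m1 - k) + (m2 - (n - k))
  if (D <= 0) D <- .Machine$double.eps
  lc <- lchoose(m1, k) + lchoose(m2, n - k)
  f <- function(u) {
    lg <- (D - 1) * log(u)
    if (k > 0) lg <- lg + k * log1p(-u^w)
    if (n - k > 0) lg <- lg + (n - k) * log1p(-u)
    out <- D * exp(lg + lc)
    out[!is.finite(out)] <- 0
    out
  }
  val <- tryCatch(integrate(f, 0, 1, rel.tol = 1e-9,
                            subdivisions = 500L)$value,
                  error = function(e) NA_real_)
  if (is.na(val)) return(NA_real_)
  val
}

#' Upper-tail probability of the Wallenius non-central hypergeometric
#'
#' P(X >= k) when n genes are drawn without replacement from m1 category
#' genes of relative weight \code{odds} and m2 background genes of weight 1.
#' Computed by an exact sequential-draw recursion for moderate problem
#' sizes and by numerical integration of the standard integral
#' representation otherwise.  With odds = 1 this reduces to the central
#' hypergeometric tail.
#'
#' @param k observed category successes.
#' @param m1 category size, m2 background size, n number of draws.
#' @param odds weight ratio (category vs background).
#' @param max_recursive use the exact recursion when n <= this value.
#' @return P(X >= k).
#' @export
pWalleniusTail <- function(k, m1, m2, n, odds, max_recursive = 500) {
  stopifnot(m1 >= 0, m2 >= 0, n >= 0, n <= m1 + m2, odds > 0)
  if (k <= 0) return(1)
  if (k > min(n, m1)) return(0)
  if (odds == 1) return(phyper(k - 1, m1, m2, n, lower.tail = FALSE))
  if (n <= max_recursive) {
    pmf <- .walleniusPMFRecursive(m1, m2, n, odds)
    return(min(1, max(0, sum(pmf[(k + 1):length(pmf)]))))
  }
  ks <- k:min(n, m1)
  p <- sum(vapply(ks, .walleniusPMFIntegral, numeric(1),
                  m1 = m1, m2 = m2, n = n, w = odds))
  min(1, max(0, p))
}

#' Category enrichment with length-bias correction (Wallenius test)
#'
#' For each category, the observed number of DE genes is compared against a
#' Wallenius non-central hypergeometric null in which genes are drawn with
#' odds equal to the ratio of mean PWF weight inside the category to mean
#' weight outside, so that categories of long (DE-prone) genes are not
#' called enriched merely through length bias.
#'
#' @param de_genes character vector of DE gene identifiers.
#' @param categories named list mapping category to member gene identifiers.
#' @param weights named per-gene PWF weights from \code{\link{fitPWF}}; the
#'   gene universe is \code{names(weights)} (genes with defined weight).
#' @return data.frame with category, n_de_in_cat, n_cat, n_de, n_universe,
#'   odds, p_wallenius, padj (BH across tested categories).  Categories
#'   disjoint from the universe are skipped with a message.
#' @export
walleniusEnrichment <- function(de_genes, categories, weights) {
  universe <- names(weights)[!is.na(weights)]
  w <- weights[universe]
  de <- intersect(de_genes, universe)
  rows <- lapply(names(categories), function(cat) {
    members <- intersect(categories[[cat]], universe)
    if (!length(members)) {
      message("category '", cat, "' has no genes in the universe; skipped")
      return(NULL)
    }
    m1 <- length(members)
    m2 <- length(universe) - m1
    k <- length(intersect(de, members))
    w_in <- mean(w[members])
    w_out <- if (m2 > 0) mean(w[setdiff(universe, members)]) else w_in
    odds <- w_in / w_out
    data.frame(category = cat, n_de_in_cat = k, n_cat = m1,
               n_de = length(de), n_universe = length(universe),
               odds = odds,
               p_wallenius = pWalleniusTail(k, m1, m2, length(de), odds))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$padj <- p.adjust(out$p_wallenius, "BH")
  out[order(out$p_wallenius), ]
}

#' Category enrichment with the central hypergeometric test
#'
#' Upper-tail hypergeometric p per category (the standard pathway
#' over-representation test), with BH adjustment across categories.
#'
#' @param de_genes character vector of DE gene identifiers.
#' @param categories named list mapping category to member genes.
#' @param universe character vector of background gene identifiers.
#' @return data.frame as in \code{\link{walleniusEnrichment}} with column
#'   p_hypergeom.
#' @export
hypergeomEnrichment <- function(de_genes, categories, universe) {
  de <- intersect(de_genes, universe)
  rows <- lapply(names(categories), function(cat) {
    members <- intersect(categories[[cat]], universe)
    if (!length(members)) {
      message("category '", cat, "' has no genes in the universe; skipped")
      return(NULL)
    }
    m1 <- length(members)
    k <- length(intersect(de, members))
    data.frame(category = cat, n_de_in_cat = k, n_cat = m1,
               n_de = length(de), n_universe = length(universe),
               p_hypergeom = phyper(k - 1, m1, length(universe) - m1,
                                    length(de), lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$padj <- p.adjust(out$p_hypergeom, "BH")
  out[order(out$p_hypergeom), ]
}

## coerce a ContrastResult or data.frame to (gene_id, log2_fc, de_flag,
## direction)
.asDETable <- function(x) {
  if (is(x, "ContrastResult")) x <- resultsTable(x)
  stopifnot(is.data.frame(x), all(c("gene_id", "log2_fc", "de_flag") %in%
                                    names(x)))
  if (is.null(x$direction))
    x$direction <- ifelse(!x$de_flag, "ns",
                          ifelse(x$log2_fc > 0, "up", "down"))
  x[, c("gene_id", "log2_fc", "de_flag", "direction")]
}

#' Gene-family partition and per-line average fold change
#'
#' Partitions the DE members of a gene family (e.g. the heat shock proteins)
#' between two within-line heat contrasts into genes DE in both lines, in
#' line A only and in line B only, and reports each line's mean signed log2
#' fold change over its own DE family members (optionally of absolute
#' values).
#'
#' @param res_A,res_B \linkS4class{ContrastResult}s (or data.frames with
#'   gene_id, log2_fc, de_flag) for the two lines' heat-vs-control
#'   contrasts.
#' @param families named character vector or data.frame(gene_id, family)
#'   mapping genes to family labels.
#' @param family family label to summarize.
#' @param absolute use |log2 FC| in the averages.
#' @return object of class \code{familySummary}: per-gene table in the
#'   two-line layout, partition counts and per-line means.
#' @export
familySummary <- function(res_A, res_B, families, family,
                          absolute = FALSE) {
  tA <- .asDETable(res_A); tB <- .asDETable(res_B)
  if (is.data.frame(families))
    families <- setNames(families$family, families$gene_id)
  members <- names(families)[families == family]
  if (!length(members)) {
    warning("family '", family, "' not present in the annotation")
    return(structure(list(table = data.frame(), counts = c(both = 0,
                                                           A_only = 0,
                                                           B_only = 0),
                          mean_lfc = c(A = NA_real_, B = NA_real_),
                          family = family),
                     class = "familySummary"))
  }
  deA <- members %in% tA$gene_id[tA$de_flag]
  deB <- members %in% tB$gene_id[tB$de_flag]
  lfcA <- tA$log2_fc[match(members, tA$gene_id)]
  lfcB <- tB$log2_fc[match(members, tB$gene_id)]
  membership <- ifelse(deA & deB, "both",
                       ifelse(deA, "A_only", ifelse(deB, "B_only", "none")))
  tb <- data.frame(gene_id = members,
                   de_A = deA, de_B = deB,
                   log2_fc_A = ifelse(deA, lfcA, NA_real_),
                   log2_fc_B = ifelse(deB, lfcB, NA_real_),
                   membership = membership, row.names = NULL)
  tb <- tb[tb$membership != "none", , drop = FALSE]
  val <- function(v) if (absolute) abs(v) else v
  structure(list(
    table = tb,
    counts = c(both = sum(tb$membership == "both"),
               A_only = sum(tb$membership == "A_only"),
               B_only = sum(tb$membership == "B_only")),
    mean_lfc = c(A = mean(val(tb$log2_fc_A), na.rm = TRUE),
                 B = mean(val(tb$log2_fc_B), na.rm = TRUE)),
    family = family), class = "familySummary")
}

#' @export
print.familySummary <- function(x, ...) {
  cat("Family '", x$family, "': ", sum(x$counts), " DE members (",
      "both ", x$counts["both"], ", A only ", x$counts["A_only"],
      ", B only ", x$counts["B_only"], ")\n", sep = "")
  cat(sprintf("  mean log2 FC over own DE members: A %.2f | B %.2f\n",
              x$mean_lfc["A"], x$mean_lfc["B"]))
  invisible(x)
}

#' Count DE genes of a pathway by direction, per line
#'
#' Counts pathway-annotated genes that are differentially expressed with the
#' given direction in each of two within-line heat contrasts.
#'
#' @param res_A,res_B \linkS4class{ContrastResult}s or data.frames as in
#'   \code{\link{familySummary}}.
#' @param pathways data.frame(gene_id, pathway) where pathway may be a
#'   semicolon-separated list, or a named list mapping pathway to genes.
#' @param pathway pathway label.
#' @param direction "up" or "down".
#' @return named integer vector c(A = , B = ).
#' @export
pathwayUpDownCounts <- function(res_A, res_B, pathways, pathway,
                                direction = c("down", "up")) {
  direction <- match.arg(direction)
  tA <- .asDETable(res_A); tB <- .asDETable(res_B)
  if (is.data.frame(pathways)) {
    spl <- strsplit(as.character(pathways$pathway), ";", fixed = TRUE)
    spl <- lapply(spl, trimws)
    members <- pathways$gene_id[vapply(spl, function(p) pathway %in% p,
                                       logical(1))]
  } else {
    members <- pathways[[pathway]]
  }
  if (is.null(members) || !length(members)) {
    warning("pathway '", pathway, "' not present in the annotation")
    return(c(A = 0L, B = 0L))
  }
  cnt <- function(tb) sum(tb$gene_id %in% members & tb$de_flag &
                            tb$direction == direction)
  c(A = cnt(tA), B = cnt(tB))
}
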