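# shared builders for small simulated objects

# exact two-segment data in Arrhenius coordinates, continuous at x_break
makeTwoSegment <- function(x_break = 3.30, slope_pre = -3, slope_post = 15,
                           y_break = 4, n_side = 10, span = 0.06) {
  x_pre <- seq(x_break + span / n_side, x_break + span, length.out = n_side)
  x_post <- seq(x_break - span, x_break - span / n_side, length.out = n_side)
  y_pre <- y_break + slope_pre * (x_pre - x_break)
  y_post <- y_break + slope_post * (x_post - x_break)
  data.frame(x = c(x_post, x_pre), y = c(y_post, y_pre))
}

# independent brute-force broken-stick oracle: exhaustive splits, lm() fits
bruteForceSplitRSS <- function(x, y, min_seg = 4) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  best <- Inf
  for (k in min_seg:(n - min_seg)) {
    r1 <- sum(resid(lm(y[1:k] ~ x[1:k]))^2)
    r2 <- sum(resid(lm(y[(k + 1):n] ~ x[(k + 1):n]))^2)
    best <- min(best, r1 + r2)
  }
  best
}

# small two-cell count experiment
makeTwoGroupCE <- function(n_genes = 200, mu = 200, alpha = 0.05,
                           lfc = 0, n_de = 0, seed = 1) {
  set.seed(seed)
  de <- rep(FALSE, n_genes)
  if (n_de > 0) de[seq_len(n_de)] <- TRUE
  muB <- ifelse(de, mu * 2^lfc, mu)
  draw <- function(m) {
    if (alpha == 0) rpois(n_genes, m) else rnbinom(n_genes, mu = m,
                                                   size = 1 / alpha)
  }
  cnt <- cbind(draw(mu), draw(mu), draw(mu), draw(muB), draw(muB), draw(muB))
  dimnames(cnt) <- list(sprintf("g%04d", seq_len(n_genes)),
                        paste0("s", 1:6))
  ce <- CountExperiment(cnt, line = rep("L", 6),
                        condition = rep(c("control", "heat"), each = 3))
  list(ce = ce, de = de)
}

# sequential-biased-urn enumeration oracle for the Wallenius upper tail:
# sum over all ordered draws of n distinct items
enumWalleniusTail <- function(k, m1, m2, n, w) {
  weights <- c(rep(w, m1), rep(1, m2))
  is_cat <- c(rep(TRUE, m1), rep(FALSE, m2))
  total <- 0
  recurse <- function(remaining, n_left, n_cat, p_acc) {
    if (n_left == 0) {
      if (n_cat >= k) total <<- total + p_acc
      return(invisible())
    }
    wsum <- sum(weights[remaining])
    for (i in remaining) {
      recurse(setdiff(remaining, i), n_left - 1,
              n_cat + is_cat[i], p_acc * weights[i] / wsum)
    }
  }
  recurse(seq_len(m1 + m2), n, 0, 1)
  total
}
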