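#' @include AllClasses.R
NULL

#' One-way analysis of variance across selective lines
#'
#' Standard fixed-effects decomposition SS_total = SS_between + SS_within
#' with F = MS_between / MS_within on (k - 1, N - k) degrees of freedom.
#'
#' @param values numeric measurements (e.g. per-individual ABT or maximum
#'   heart rate).
#' @param group group labels, one per value.
#' @return an object of class \code{abtAnova}: f_stat, df_between,
#'   df_within, p_value, ms_within, group_means, group_sds, group_n, note.
#' @export
#' @examples
#' oneWayAnova(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("a", "b", "c"), each = 3))
oneWayAnova <- function(values, group) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  ok <- is.finite(values)
  values <- values[ok]; group <- droplevels(group[ok])
  k <- nlevels(group)
  n_i <- tabulate(group)
  if (k < 2) stop("need at least 2 groups")
  if (any(n_i < 2)) stop("every group needs at least 2 values")
  N <- length(values)
  m_i <- tapply(values, group, mean)
  grand <- mean(values)
  ssb <- sum(n_i * (m_i - grand)^2)
  ssw <- sum((values - m_i[group])^2)
  dfb <- k - 1L; dfw <- N - k
  msw <- ssw / dfw
  note <- NULL
  if (msw == 0) {
    if (ssb == 0) {
      f <- NaN; p <- NA_real_
      note <- "zero within- and between-group variance: F undefined"
    } else {
      f <- Inf; p <- 0
      note <- "zero within-group variance with unequal means"
    }
  } else {
    f <- (ssb / dfb) / msw
    p <- pf(f, dfb, dfw, lower.tail = FALSE)
  }
  structure(list(f_stat = f, df_between = dfb, df_within = dfw,
                 p_value = p, ss_between = ssb, ss_within = ssw,
                 ms_within = msw,
                 group_means = m_i,
                 group_sds = tapply(values, group, sd),
                 group_n = setNames(n_i, levels(group)),
                 note = note),
            class = "abtAnova")
}

#' @export
print.abtAnova <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_between, ",", x$df_within, ") = ",
      sprintf("%.4g", x$f_stat), ", p = ", sprintf("%.4g", x$p_value),
      "\n", sep = "")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Duncan's multiple range test with compact letter display
#'
#' Orders the group means and compares every stretch of p adjacent ordered
#' means against the critical range q(alpha_p, p, df_within) *
#' sqrt(MS_within / n_h), where alpha_p = 1 - (1 - alpha)^(p - 1) is
#' Duncan's protection level and n_h the harmonic mean group size.  Following
#' the usual multiple-range protection rule, any stretch contained in a
#' non-significant stretch is itself declared non-significant.  Shared
#' letters are assigned to maximal non-significant stretches (insert-and-
#' absorb); two groups share a letter iff they are not significantly
#' different.
#'
#' For k = 2 groups the decision coincides exactly with the pooled two-sample
#' t-test at level alpha (q(alpha, 2, df) = sqrt(2) t(alpha/2, df)).
#'
#' @param values,group as in \code{\link{oneWayAnova}}.
#' @param alpha significance level.
#' @return an object of class \code{duncanGroups}: ordered means, per-stretch
#'   critical ranges, pairwise significance matrix, letters.
#' @export
duncanMRT <- function(values, group, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  aov_res <- oneWayAnova(values, group)
  means <- sort(aov_res$group_means, decreasing = TRUE)
  ## ties in means: stable alphabetical order among tied labels
  means <- means[order(-means, names(means))]
  k <- length(means)
  n_i <- aov_res$group_n[names(means)]
  if (length(unique(n_i)) > 1)
    message("unbalanced groups: using harmonic mean group size")
  n_h <- k / sum(1 / n_i)
  dfw <- aov_res$df_within
  se <- sqrt(aov_res$ms_within / n_h)
  crit <- c(NA_real_,
            vapply(2:k, function(p)
              qtukey((1 - alpha)^(p - 1), p, dfw) * se, numeric(1)))
  ## mark non-significant stretches, longest first (protection rule)
  ns_cover <- matrix(FALSE, k, k)  # [i, j]: stretch i..j declared NS
  covered <- function(i, j) {
    for (a in seq_len(i)) for (b in j:k)
      if (ns_cover[a, b] && !(a == i && b == j)) return(TRUE)
    FALSE
  }
  if (k >= 2) {
    for (p in k:2) {
      for (i in seq_len(k - p + 1)) {
        j <- i + p - 1
        if (covered(i, j)) next
        if (abs(means[i] - means[j]) <= crit[p]) ns_cover[i, j] <- TRUE
      }
    }
  }
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ns <- FALSE
    for (a in seq_len(i)) for (b in j:k) if (ns_cover[a, b]) ns <- TRUE
    sig[i, j] <- sig[j, i] <-
      !ns && abs(means[i] - means[j]) > crit[j - i + 1]
  }
  letters_ <- .compactLetters(sig)
  structure(list(means = means, group_n = n_i, critical_ranges = crit,
                 significant = sig, letters = letters_, alpha = alpha,
                 df_within = dfw, ms_within = aov_res$ms_within),
            class = "duncanGroups")
}

## compact letter display from a pairwise significance matrix whose rows are
## ordered by decreasing mean: maximal non-significant runs get one letter
.compactLetters <- function(sig) {
  k <- nrow(sig)
  if (k == 1) return(setNames("a", rownames(sig)))
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    runs[[length(runs) + 1]] <- c(i, j)
  }
  ## absorb runs contained in another run
  keep <- vapply(seq_along(runs), function(r) {
    !any(vapply(seq_along(runs), function(s) {
      s != r && runs[[s]][1] <= runs[[r]][1] && runs[[s]][2] >= runs[[r]][2]
    }, logical(1)))
  }, logical(1))
  runs <- unique(runs[keep])
  lab <- rep("", k)
  for (r in seq_along(runs)) {
    idx <- runs[[r]][1]:runs[[r]][2]
    lab[idx] <- paste0(lab[idx], letters[r])
  }
  setNames(lab, rownames(sig))
}

#' @export
print.duncanGroups <- function(x, ...) {
  cat("Duncan's multiple range test (alpha =", x$alpha, ")\n")
  print(data.frame(mean = x$means, n = x$group_n,
                   letters = x$letters[names(x$means)]))
  invisible(x)
}

#' Per-line summary table with significance letters
#'
#' Mean and sample standard deviation (n - 1 denominator) per line, joined
#' with the Duncan compact letter display when at least two lines with
#' replication are present.
#'
#' @param values,group as in \code{\link{oneWayAnova}}.
#' @param alpha level for the letter display.
#' @return data.frame with line, n, mean, sd, letters (sorted by decreasing
#'   mean).
#' @export
#' @examples
#' summarizeLines(c(31.2, 31.9, 32.6, 27.0, 28.5, 30.0),
#'                rep(c("YL", "RL"), each = 3))
summarizeLines <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  m <- tapply(values, group, mean)
  s <- tapply(values, group, function(v) if (length(v) > 1) sd(v) else NA_real_)
  n <- tapply(values, group, length)
  out <- data.frame(line = names(m), n = as.integer(n), mean = as.numeric(m),
                    sd = as.numeric(s))
  out <- out[order(-out$mean, out$line), ]
  rownames(out) <- NULL
  if (nlevels(group) >= 2 && all(n >= 2)) {
    dg <- duncanMRT(values, group, alpha = alpha)
    out$letters <- dg$letters[out$line]
  }
  out
}
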