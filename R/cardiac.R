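#' @include AllClasses.R AllGenerics.R
NULL

#' Detect heart beats in a pulse trace
#'
#' Simple prominence-and-refractory peak picking: local maxima rising at
#' least \code{min_prominence} above the signal median are taken as beats,
#' scanned in time order with a refractory period so that no two beats lie
#' closer than \code{refractory_s}.
#'
#' @param trace a \linkS4class{CardiacTrace} sampled uniformly.
#' @param min_prominence minimum height above the signal median, in signal
#'   units.
#' @param refractory_s minimum separation between beats, seconds.
#' @return strictly increasing beat times in seconds (empty, with a warning,
#'   for a flat signal).
#' @export
detectBeats <- function(trace, min_prominence = 0.5, refractory_s = 0.2) {
  stopifnot(is(trace, "CardiacTrace"), refractory_s > 0)
  s <- trace@signal
  n <- length(s)
  if (n < 3 || diff(range(s)) == 0) {
    warning("flat signal: no beats detected")
    return(numeric(0))
  }
  base <- median(s)
  mid <- 2:(n - 1)
  cand <- mid[s[mid] >= s[mid - 1] & s[mid] > s[mid + 1] &
                s[mid] - base >= min_prominence]
  if (!length(cand)) {
    warning("no peaks exceed min_prominence: no beats detected")
    return(numeric(0))
  }
  t <- trace@time_s[cand]
  keep <- logical(length(t))
  last <- -Inf
  for (i in seq_along(t)) {
    if (t[i] - last >= refractory_s) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  t[keep]
}

#' Bin beats into temperature windows and compute heart rate
#'
#' Partitions the ramp into consecutive temperature windows of width
#' \code{window_C}; each window's heart rate is 60 times the number of beats
#' divided by the window's duration in seconds.  Windows overlapping flagged
#' (arrhythmic) samples are excluded, as are windows with fewer than 2 beats;
#' both exclusions are tallied in the diagnostics.
#'
#' @param beats beat times in seconds, e.g. from \code{\link{detectBeats}}.
#' @param trace the \linkS4class{CardiacTrace} the beats came from.
#' @param window_C temperature window width, degrees C.
#' @return a \linkS4class{HeartRateSeries} (window midpoint temperatures).
#' @export
heartRateByTemperature <- function(beats, trace, window_C = 0.5) {
  stopifnot(is(trace, "CardiacTrace"), window_C > 0)
  t0 <- min(trace@temp_C)
  edges <- seq(t0, max(trace@temp_C) + window_C, by = window_C)
  nw <- length(edges) - 1
  mid <- edges[-length(edges)] + window_C / 2
  hr <- nb <- rep(NA_real_, nw)
  n_sparse <- n_arrhythmic <- 0L
  for (w in seq_len(nw)) {
    in_w <- trace@temp_C >= edges[w] & trace@temp_C < edges[w + 1]
    if (!any(in_w)) next
    t_lo <- min(trace@time_s[in_w]); t_hi <- max(trace@time_s[in_w])
    if (t_hi <= t_lo) next
    if (any(trace@window_flag[in_w])) {  # arrhythmic windows are dropped
      n_arrhythmic <- n_arrhythmic + 1L
      next
    }
    k <- sum(beats >= t_lo & beats < t_hi)
    if (k < 2) {
      n_sparse <- n_sparse + 1L
      next
    }
    nb[w] <- k
    hr[w] <- 60 * k / (t_hi - t_lo)
  }
  keep <- !is.na(hr) & hr > 0
  new("HeartRateSeries", temp_C = mid[keep], hr_bpm = hr[keep],
      n_beats = nb[keep], flagged = rep(FALSE, sum(keep)),
      diagnostics = list(n_excluded_sparse = n_sparse,
                         n_excluded_arrhythmic = n_arrhythmic))
}

#' Arrhenius transform of a heart-rate series
#'
#' Maps retained (non-arrhythmic) records to Arrhenius coordinates:
#' x = 1000/(temp_C + 273.15), y = ln(heart rate in beats per minute).
#'
#' @param object a \linkS4class{HeartRateSeries}.
#' @param ... unused.
#' @return an \linkS4class{ArrheniusSeries}.
#' @export
setMethod("arrheniusTransform", "HeartRateSeries", function(object, ...) {
  keep <- !object@flagged
  hr <- object@hr_bpm[keep]
  if (any(hr <= 0)) {
    bad <- which(hr <= 0)[1]
    stop("non-positive heart rate at retained record ", bad,
         " (temp ", object@temp_C[keep][bad], " degC)")
  }
  new("ArrheniusSeries", x = .xOf(object@temp_C[keep]), y = log(hr))
})

#' @rdname arrheniusTransform-HeartRateSeries-method
#' @export
setMethod("arrheniusTransform", "data.frame", function(object, ...) {
  stopifnot(all(c("temp_C", "hr_bpm") %in% names(object)))
  if (any(object$hr_bpm <= 0))
    stop("non-positive heart rate at record ",
         which(object$hr_bpm <= 0)[1])
  new("ArrheniusSeries", x = .xOf(object$temp_C), y = log(object$hr_bpm))
})

## OLS on (x, y): returns c(intercept, slope, rss); x must have variance
.olsFit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(NULL)
  b <- sum((x - mx) * (y - my)) / sxx
  a <- my - b * mx
  r <- y - a - b * x
  c(a, b, sum(r * r))
}

#' Fit a broken-stick (two-segment) regression in Arrhenius coordinates
#'
#' Exhaustively evaluates every split of the x-sorted data into a
#' high-temperature (low x) and a low-temperature (high x) segment with at
#' least \code{min_seg} points each, fits ordinary least squares
#' independently on each side (the segments are not constrained to meet) and
#' selects the split minimizing the total residual sum of squares.  Ties are
#' broken toward the split with more pre-breakpoint (low-temperature) points,
#' then toward the lower breakpoint temperature.
#'
#' The reported breakpoint is, under the default \code{"intersection"}
#' convention, the abscissa where the two fitted lines cross, provided it
#' falls between the two data points bracketing the split; otherwise (and
#' always under \code{"split_midpoint"}) the midpoint of the bracketing x
#' values is used.  The breakpoint temperature is 1000/x_break - 273.15.
#'
#' A fit whose RSS improves on a single straight line by less than 5 percent
#' is flagged \code{no_distinct_break}.
#'
#' @param aseries an \linkS4class{ArrheniusSeries} (or data.frame with
#'   columns x, y) with distinct x values.
#' @param min_seg minimum points per segment (default 4, keeping both OLS
#'   fits overdetermined).
#' @param convention breakpoint convention, "intersection" or
#'   "split_midpoint".
#' @return a \linkS4class{BrokenStickFit}.
#' @export
#' @examples
#' p <- cardiacSimParams(abt_true = 30, noise_sd = 0, arrhythmia_prob = 0)
#' fit <- fitBrokenStick(arrheniusTransform(simulateHeartRateSeries(p)))
#' abt(fit)
fitBrokenStick <- function(aseries, min_seg = 4,
                           convention = c("intersection", "split_midpoint")) {
  convention <- match.arg(convention)
  if (is.data.frame(aseries))
    aseries <- new("ArrheniusSeries", x = aseries$x, y = aseries$y)
  stopifnot(is(aseries, "ArrheniusSeries"))
  ord <- order(aseries@x)
  x <- aseries@x[ord]; y <- aseries@y[ord]
  n <- length(x)
  if (n < 2 * min_seg)
    stop("need at least ", 2 * min_seg, " points (2 x min_seg); got ", n)
  if (anyDuplicated(x))
    stop("x values must be distinct")
  best <- NULL
  ## split after index k (ascending x): 1..k = high-temperature (post)
  ## segment, (k+1)..n = low-temperature (pre) segment
  for (k in min_seg:(n - min_seg)) {
    post <- .olsFit(x[1:k], y[1:k])
    pre <- .olsFit(x[(k + 1):n], y[(k + 1):n])
    if (is.null(post) || is.null(pre))
      stop("degenerate segment with zero x-variance at split ", k)
    rss <- post[3] + pre[3]
    xb <- .breakAbscissa(pre, post, x[k], x[k + 1], convention)
    cand <- list(k = k, pre = pre, post = post, rss = rss, xb = xb,
                 abt = 1000 / xb - 273.15, n_pre = n - k, n_post = k)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 &&
           (cand$n_pre > best$n_pre ||
              (cand$n_pre == best$n_pre && cand$abt < best$abt))))
      best <- cand
  }
  single <- .olsFit(x, y)
  rss1 <- if (is.null(single)) Inf else single[3]
  no_break <- is.finite(rss1) &&
    (rss1 - best$rss) < 0.05 * max(rss1, .Machine$double.eps)
  new("BrokenStickFit",
      slope_pre = best$pre[2], intercept_pre = best$pre[1],
      slope_post = best$post[2], intercept_post = best$post[1],
      x_break = best$xb, abt_C = best$abt,
      rss_total = best$rss, rss_single = rss1,
      n_pre = as.integer(best$n_pre), n_post = as.integer(best$n_post),
      no_distinct_break = no_break, convention = convention)
}

## breakpoint abscissa between bracketing points x_lo < x_hi
.breakAbscissa <- function(pre, post, x_lo, x_hi, convention) {
  mid <- (x_lo + x_hi) / 2
  if (convention == "split_midpoint") return(mid)
  ds <- pre[2] - post[2]
  if (abs(ds) < .Machine$double.eps) return(mid)
  xb <- (post[1] - pre[1]) / ds
  if (xb >= x_lo && xb <= x_hi) xb else mid
}

#' Maximum heart rate of a series
#'
#' Maximum over retained (non-arrhythmic) windows, with the temperature at
#' which it occurred; ties report the first (coolest) temperature.
#'
#' @param object a \linkS4class{HeartRateSeries}.
#' @param ... unused.
#' @return one-row data.frame with hr_bpm and temp_C.
#' @export
setMethod("maxHeartRate", "HeartRateSeries", function(object, ...) {
  keep <- !object@flagged
  if (!any(keep)) stop("no retained records in series")
  hr <- object@hr_bpm[keep]; tc <- object@temp_C[keep]
  i <- which.max(hr)
  data.frame(hr_bpm = hr[i], temp_C = tc[i])
})

#' Estimate the ABT of one individual from a heart-rate series
#'
#' Convenience wrapper: Arrhenius transform of the retained records followed
#' by the exhaustive broken-stick fit.
#'
#' @param series a \linkS4class{HeartRateSeries}.
#' @param min_seg,convention passed to \code{\link{fitBrokenStick}}.
#' @return a \linkS4class{BrokenStickFit}.
#' @export
estimateABT <- function(series, min_seg = 4, convention = "intersection") {
  fitBrokenStick(arrheniusTransform(series), min_seg = min_seg,
                 convention = convention)
}

#' Read a cardiac trace or heart-rate series from CSV
#'
#' Accepts either a raw trace (columns time_s, temp_C, signal and optional
#' window_flag) or a pre-computed rate series (columns temp_C, hr_bpm).
#'
#' @param path CSV file path.
#' @return a \linkS4class{CardiacTrace} or \linkS4class{HeartRateSeries},
#'   depending on the columns present.
#' @export
readCardiacCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("time_s", "temp_C", "signal") %in% names(df))) {
    wf <- if ("window_flag" %in% names(df)) as.logical(df$window_flag)
          else rep(FALSE, nrow(df))
    return(new("CardiacTrace", time_s = df$time_s, temp_C = df$temp_C,
               signal = df$signal, window_flag = wf))
  }
  if (all(c("temp_C", "hr_bpm") %in% names(df))) {
    fl <- if ("window_flag" %in% names(df)) as.logical(df$window_flag)
          else if ("flagged" %in% names(df)) as.logical(df$flagged)
          else rep(FALSE, nrow(df))
    nb <- if ("n_beats" %in% names(df)) as.numeric(df$n_beats)
          else rep(NA_real_, nrow(df))
    ord <- order(df$temp_C)
    return(new("HeartRateSeries", temp_C = df$temp_C[ord],
               hr_bpm = df$hr_bpm[ord], n_beats = nb[ord],
               flagged = fl[ord]))
  }
  stop("unrecognized cardiac CSV layout in ", path,
       ": expected (time_s, temp_C, signal) or (temp_C, hr_bpm)")
}
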