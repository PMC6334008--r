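#' @include AllClasses.R
NULL

#' @export
setGeneric("arrheniusTransform", function(object, ...)
  standardGeneric("arrheniusTransform"))

#' @export
setGeneric("maxHeartRate", function(object, ...)
  standardGeneric("maxHeartRate"))

#' @export
setGeneric("abt", function(object) standardGeneric("abt"))

#' @export
setGeneric("estimateSizeFactors", function(object, ...)
  standardGeneric("estimateSizeFactors"))

#' @export
setGeneric("sizeFactors", function(object) standardGeneric("sizeFactors"))

#' @export
setGeneric("estimateDispersions", function(object, ...)
  standardGeneric("estimateDispersions"))

#' @export
setGeneric("dispersions", function(object) standardGeneric("dispersions"))

#' @export
setGeneric("normalizedCounts", function(object)
  standardGeneric("normalizedCounts"))

#' @export
setGeneric("fpkm", function(object) standardGeneric("fpkm"))

#' @export
setGeneric("resultsTable", function(object) standardGeneric("resultsTable"))

#' @export
setGeneric("degs", function(object, ...) standardGeneric("degs"))

## ---- simple accessors and show methods --------------------------------------

#' Extract the Arrhenius breakpoint temperature
#'
#' @param object a \linkS4class{BrokenStickFit}.
#' @return breakpoint temperature in degrees Celsius.
#' @export
#' @rdname abt
setMethod("abt", "BrokenStickFit", function(object) object@abt_C)

#' @describeIn abt breakpoint abscissa in 1000/K.
#' @export
xBreak <- function(object) {
  stopifnot(is(object, "BrokenStickFit"))
  object@x_break
}

#' @describeIn abt total residual sum of squares of the two-segment fit.
#' @export
rssTotal <- function(object) {
  stopifnot(is(object, "BrokenStickFit"))
  object@rss_total
}

#' Segment parameters of a broken-stick fit
#'
#' @param object a \linkS4class{BrokenStickFit}.
#' @return data.frame with one row per segment (pre = low-temperature side,
#'   post = high-temperature side): slope, intercept and number of points.
#' @export
segmentTable <- function(object) {
  stopifnot(is(object, "BrokenStickFit"))
  data.frame(
    segment = c("pre", "post"),
    slope = c(object@slope_pre, object@slope_post),
    intercept = c(object@intercept_pre, object@intercept_post),
    n = c(object@n_pre, object@n_post))
}

setMethod("show", "BrokenStickFit", function(object) {
  cat("BrokenStickFit (", object@convention, " convention)\n", sep = "")
  cat(sprintf("  ABT: %.2f degC  (x_break = %.5f 1000/K)\n",
              object@abt_C, object@x_break))
  cat(sprintf("  segments: pre n=%d slope=%.3f | post n=%d slope=%.3f\n",
              object@n_pre, object@slope_pre, object@n_post,
              object@slope_post))
  cat(sprintf("  RSS: %.4g (single line %.4g)%s\n", object@rss_total,
              object@rss_single,
              if (object@no_distinct_break) "  [no distinct breakpoint]"
              else ""))
})

setMethod("show", "HeartRateSeries", function(object) {
  cat("HeartRateSeries with", length(object@temp_C), "windows (",
      sum(object@flagged), "flagged )\n")
  cat(sprintf("  temp %.1f-%.1f degC, hr %.1f-%.1f bpm\n",
              min(object@temp_C), max(object@temp_C),
              min(object@hr_bpm), max(object@hr_bpm)))
})

setMethod("show", "CardiacTrace", function(object) {
  cat("CardiacTrace:", length(object@time_s), "samples over",
      sprintf("%.0f s,", diff(range(object@time_s))),
      sprintf("%.1f-%.1f degC\n", min(object@temp_C), max(object@temp_C)))
})

setMethod("show", "ContrastResult", function(object) {
  tb <- object@table
  cat("ContrastResult", object@contrast, ":", object@label_B, "vs",
      object@label_A, "\n")
  cat(sprintf("  %d genes, %d DE (p < %g, |log2 FC| > %g): %d up, %d down\n",
              nrow(tb), sum(tb$de_flag), object@p_thr, object@lfc_thr,
              sum(tb$direction == "up" & tb$de_flag),
              sum(tb$direction == "down" & tb$de_flag)))
})

#' @describeIn nbTest per-gene result table of a contrast.
#' @export
setMethod("resultsTable", "ContrastResult", function(object) object@table)

#' @describeIn nbTest gene identifiers flagged as differentially expressed.
#' @param direction optional filter: "up", "down" or NULL for both.
#' @export
setMethod("degs", "ContrastResult", function(object, direction = NULL) {
  tb <- object@table
  keep <- tb$de_flag
  if (!is.null(direction)) keep <- keep & tb$direction == direction
  tb$gene_id[keep]
})

## data.frame convenience converters

#' Convert a HeartRateSeries to a data.frame
#'
#' @param x a \linkS4class{HeartRateSeries}.
#' @param ... unused.
#' @export
as.data.frame.HeartRateSeries <- function(x, ...) {
  data.frame(temp_C = x@temp_C, hr_bpm = x@hr_bpm, n_beats = x@n_beats,
             flagged = x@flagged)
}

#' Convert an ArrheniusSeries to a data.frame
#'
#' @param x an \linkS4class{ArrheniusSeries}.
#' @param ... unused.
#' @export
as.data.frame.ArrheniusSeries <- function(x, ...) {
  data.frame(x = x@x, y = x@y)
}

#' Convert a CardiacTrace to a data.frame
#'
#' @param x a \linkS4class{CardiacTrace}.
#' @param ... unused.
#' @export
as.data.frame.CardiacTrace <- function(x, ...) {
  data.frame(time_s = x@time_s, temp_C = x@temp_C, signal = x@signal,
             window_flag = x@window_flag)
}
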