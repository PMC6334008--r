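#' @import methods
#' @importFrom stats median rnorm runif rbinom rnbinom rpois approx coef lm pf
#'   pnorm pt qt phyper qtukey p.adjust isoreg integrate setNames sd var
#'   aggregate complete.cases
NULL

## ---- cardiac data containers ------------------------------------------------

#' Raw cardiac sensor trace
#'
#' Holds a uniformly sampled infrared pulse signal recorded while seawater
#' temperature is ramped, together with per-sample quality flags marking
#' windows corrupted by arrhythmia.
#'
#' @slot time_s numeric, strictly increasing sample times in seconds.
#' @slot temp_C numeric, body temperature at each sample (degrees Celsius).
#' @slot signal numeric, sensor signal in arbitrary units.
#' @slot window_flag logical, TRUE where the sample lies in a corrupted window.
#' @slot metadata list, generator bookkeeping (true beat times, corrupted
#'   window intervals, sampling rate).
#'
#' @exportClass CardiacTrace
setClass("CardiacTrace",
  representation(time_s = "numeric", temp_C = "numeric", signal = "numeric",
                 window_flag = "logical", metadata = "list"),
  prototype(metadata = list()))

setValidity("CardiacTrace", function(object) {
  n <- length(object@time_s)
  if (length(object@temp_C) != n || length(object@signal) != n ||
      length(object@window_flag) != n)
    return("time_s, temp_C, signal and window_flag must have equal length")
  if (n > 1 && any(diff(object@time_s) <= 0))
    return("time_s: sample times must be strictly increasing")
  if (any(object@temp_C <= -5 | object@temp_C >= 50))
    return("temp_C: temperatures must lie in (-5, 50) degrees C")
  TRUE
})

#' Windowed heart-rate series
#'
#' One record per temperature window: window midpoint temperature, heart rate
#' in beats per minute and the number of beats counted.  Windows flagged as
#' arrhythmic are retained in the object but excluded from downstream fitting.
#'
#' @slot temp_C numeric, non-decreasing window midpoint temperatures.
#' @slot hr_bpm numeric, heart rate in beats per minute.
#' @slot n_beats numeric, beats counted per window (NA for simulated series).
#' @slot flagged logical, TRUE for windows affected by arrhythmia.
#' @slot diagnostics list, exclusion counts and generator truth.
#'
#' @exportClass HeartRateSeries
setClass("HeartRateSeries",
  representation(temp_C = "numeric", hr_bpm = "numeric", n_beats = "numeric",
                 flagged = "logical", diagnostics = "list"),
  prototype(diagnostics = list()))

setValidity("HeartRateSeries", function(object) {
  n <- length(object@temp_C)
  if (length(object@hr_bpm) != n || length(object@flagged) != n)
    return("temp_C, hr_bpm and flagged must have equal length")
  if (n > 1 && any(diff(object@temp_C) < 0))
    return("temp_C: window temperatures must be non-decreasing")
  if (any(object@hr_bpm[!object@flagged] <= 0))
    return("hr_bpm: retained (non-flagged) heart rates must be positive")
  TRUE
})

#' Arrhenius-transformed heart-rate series
#'
#' Coordinates for the Arrhenius plot: x = 1000/K with K the absolute
#' temperature, y = ln(heart rate in beats per minute).  x decreases strictly
#' as temperature increases.
#'
#' @slot x numeric, inverse absolute temperature scaled by 1000 (1/K).
#' @slot y numeric, natural log of heart rate.
#'
#' @exportClass ArrheniusSeries
setClass("ArrheniusSeries", representation(x = "numeric", y = "numeric"))

setValidity("ArrheniusSeries", function(object) {
  if (length(object@x) != length(object@y))
    return("x and y must have equal length")
  if (any(object@x <= 0)) return("x: 1000/K must be positive")
  if (any(!is.finite(object@y))) return("y: ln(heart rate) must be finite")
  TRUE
})

#' Broken-stick (two-segment) regression fit
#'
#' Result of the exhaustive two-segment least-squares fit in Arrhenius
#' coordinates.  The pre-breakpoint segment covers the low-temperature (high
#' x) side, the post-breakpoint segment the high-temperature side.  The
#' Arrhenius breakpoint temperature (ABT) is derived from the breakpoint
#' abscissa as 1000/x_break - 273.15.
#'
#' @slot slope_pre,intercept_pre numeric, OLS line for the low-temperature side.
#' @slot slope_post,intercept_post numeric, OLS line for the high-temperature side.
#' @slot x_break numeric, breakpoint in 1000/K.
#' @slot abt_C numeric, breakpoint temperature in degrees Celsius.
#' @slot rss_total numeric, summed residual sum of squares of both segments.
#' @slot rss_single numeric, RSS of a single straight-line fit (diagnostic).
#' @slot n_pre,n_post integer, points in each segment.
#' @slot no_distinct_break logical, TRUE when the two-segment fit improves on
#'   the single line by less than 5 percent.
#' @slot convention character, breakpoint convention used ("intersection" or
#'   "split_midpoint").
#'
#' @exportClass BrokenStickFit
setClass("BrokenStickFit",
  representation(slope_pre = "numeric", intercept_pre = "numeric",
                 slope_post = "numeric", intercept_post = "numeric",
                 x_break = "numeric", abt_C = "numeric",
                 rss_total = "numeric", rss_single = "numeric",
                 n_pre = "integer", n_post = "integer",
                 no_distinct_break = "logical", convention = "character"))

setValidity("BrokenStickFit", function(object) {
  if (object@rss_total < 0) return("rss_total must be non-negative")
  if (abs(object@abt_C - (1000 / object@x_break - 273.15)) > 1e-8)
    return("abt_C must equal 1000/x_break - 273.15")
  TRUE
})

## ---- simulation parameter objects ------------------------------------------

#' Parameters of the two-phase cardiac thermal-performance simulator
#'
#' Describes a temperature-ramp experiment on one individual: in Arrhenius
#' coordinates the expected log heart rate is piecewise linear and continuous,
#' with slope \code{slope_pre} below the true breakpoint temperature
#' \code{abt_true} and \code{slope_post} above it.  The curve is anchored by
#' the heart rate at 20 degrees C.
#'
#' @slot abt_true numeric, true breakpoint temperature (degrees C).
#' @slot slope_pre numeric, d ln(HR) / d(1000/K) on the low-temperature side
#'   (negative: rate rises with temperature).
#' @slot slope_post numeric, same units on the high-temperature side
#'   (large positive: rate collapses above the breakpoint).
#' @slot hr_at_20C numeric, heart rate at 20 degrees C (beats per minute).
#' @slot ramp_rate numeric, warming rate in degrees C per minute.
#' @slot temp_range numeric length 2, ramp start and end temperature.
#' @slot noise_sd numeric, sd of Gaussian noise added to ln(HR).
#' @slot arrhythmia_prob numeric in [0,1), probability that a window is
#'   corrupted by arrhythmia.
#' @slot n_points integer, number of heart-rate observations along the ramp.
#' @slot seed integer or NA, RNG seed.
#'
#' @exportClass CardiacSimParams
setClass("CardiacSimParams",
  representation(abt_true = "numeric", slope_pre = "numeric",
                 slope_post = "numeric", hr_at_20C = "numeric",
                 ramp_rate = "numeric", temp_range = "numeric",
                 noise_sd = "numeric", arrhythmia_prob = "numeric",
                 n_points = "integer", seed = "integer"))

setValidity("CardiacSimParams", function(object) {
  if (length(object@temp_range) != 2 ||
      object@temp_range[1] >= object@temp_range[2])
    return("temp_range: must be an increasing pair of temperatures")
  if (object@abt_true <= object@temp_range[1] ||
      object@abt_true >= object@temp_range[2])
    return("abt_true: breakpoint must lie strictly inside temp_range")
  if (object@hr_at_20C <= 0) return("hr_at_20C: must be positive")
  if (object@noise_sd < 0) return("noise_sd: must be non-negative")
  if (object@arrhythmia_prob < 0 || object@arrhythmia_prob >= 1)
    return("arrhythmia_prob: must lie in [0, 1)")
  if (object@ramp_rate <= 0) return("ramp_rate: must be positive")
  if (object@n_points < 4) return("n_points: need at least 4 observations")
  TRUE
})

#' Parameters of the negative-binomial count simulator
#'
#' Gene baseline means are log-normal; counts are negative binomial with a
#' decreasing mean-dispersion trend alpha(mu) = alpha0 + alpha1/mu.
#' Differential expression is spiked per line for the heat condition, with a
#' configurable fraction of DE genes and log2 fold-change distribution.
#'
#' @slot n_genes integer, number of genes.
#' @slot design data.frame with columns line, condition, n_replicates.
#' @slot mean_log_expression numeric length 2, meanlog and sdlog of the
#'   log-normal baseline mean distribution.
#' @slot dispersion_alpha0 numeric, asymptotic dispersion.
#' @slot dispersion_alpha1 numeric, 1/mu coefficient of the dispersion trend.
#' @slot de_fraction named numeric, per-line fraction of genes DE under heat.
#' @slot lfc_range numeric length 2, support of the |log2 FC| distribution.
#' @slot prob_up numeric, probability a DE gene is up-regulated under heat.
#' @slot lib_size_factors numeric or NULL, per-sample depth multipliers.
#' @slot seed integer or NA, RNG seed.
#'
#' @exportClass CountSimParams
setClass("CountSimParams",
  representation(n_genes = "integer", design = "data.frame",
                 mean_log_expression = "numeric",
                 dispersion_alpha0 = "numeric", dispersion_alpha1 = "numeric",
                 de_fraction = "numeric", lfc_range = "numeric",
                 prob_up = "numeric", lib_size_factors = "numeric",
                 seed = "integer"))

setValidity("CountSimParams", function(object) {
  if (object@n_genes <= 0) return("n_genes: must be positive")
  d <- object@design
  if (!all(c("line", "condition", "n_replicates") %in% names(d)))
    return("design: needs columns line, condition, n_replicates")
  if (any(d$n_replicates < 2))
    return("design: all replicate counts must be >= 2")
  if (any(object@de_fraction < 0 | object@de_fraction > 1))
    return("de_fraction: fractions must lie in [0, 1]")
  if (length(object@lib_size_factors) &&
      any(object@lib_size_factors <= 0))
    return("lib_size_factors: must be positive")
  if (object@dispersion_alpha0 < 0 || object@dispersion_alpha1 < 0)
    return("dispersion_alpha0/dispersion_alpha1: must be non-negative")
  TRUE
})

## ---- expression containers --------------------------------------------------

#' Gene-by-sample count container
#'
#' A \linkS4class{SummarizedExperiment} holding non-negative integer counts
#' with sample metadata columns \code{line} and \code{condition}, optional
#' per-gene lengths in \code{rowData} and, for simulated data, the truth
#' table in \code{metadata}.
#'
#' @exportClass CountExperiment
setClass("CountExperiment", contains = "SummarizedExperiment")

setValidity("CountExperiment", function(object) {
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0)) return("counts: negative entries are not allowed")
  if (any(abs(cts - round(cts)) > 1e-8))
    return("counts: entries must be integers")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("line", "condition") %in% names(cd)))
    return("colData must contain 'line' and 'condition'")
  TRUE
})

#' Per-gene result of one differential-expression contrast
#'
#' Gene-level normalized means for the two groups, log2 fold change (B
#' relative to A), Wald p-value, BH-adjusted p, and the strict DE filter flag
#' de_flag = (p < p_thr) and (|log2 FC| > lfc_thr).
#'
#' @slot table data.frame with one row per gene in the universe.
#' @slot contrast character, contrast label (e.g. "III").
#' @slot label_A,label_B character, group descriptions (A is the reference).
#' @slot p_thr,lfc_thr numeric, DE filter thresholds.
#'
#' @exportClass ContrastResult
setClass("ContrastResult",
  representation(table = "data.frame", contrast = "character",
                 label_A = "character", label_B = "character",
                 p_thr = "numeric", lfc_thr = "numeric"))

setValidity("ContrastResult", function(object) {
  tb <- object@table
  need <- c("gene_id", "base_mean_A", "base_mean_B", "log2_fc", "p_value",
            "de_flag", "direction")
  if (!all(need %in% names(tb)))
    return(paste("table is missing columns:",
                 paste(setdiff(need, names(tb)), collapse = ", ")))
  ok <- !is.na(tb$p_value) & !is.na(tb$log2_fc)
  expect <- ok & tb$p_value < object@p_thr & abs(tb$log2_fc) > object@lfc_thr
  expect[is.na(expect)] <- FALSE
  if (!identical(as.logical(tb$de_flag), as.logical(expect)))
    return("de_flag must equal (p_value < p_thr) & (|log2_fc| > lfc_thr)")
  TRUE
})
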