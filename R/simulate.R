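#' @include AllClasses.R
NULL

## run expr with a local, restored RNG state when seed is given
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.xOf <- function(temp_C) 1000 / (temp_C + 273.15)

#' Construct simulation parameters for a cardiac temperature ramp
#'
#' Defaults describe a heat-tolerant individual: breakpoint at 31.9 degrees C,
#' a Q10-of-2-like warming slope (-6 in d ln(HR)/d(1000/K)), an abrupt
#' post-breakpoint collapse, 34 bpm at 20 degrees C (placing the peak rate
#' near 75 bpm at the breakpoint), a 0.1 degC/min ramp over 20-34 degrees C
#' observed at 60 points, and lognormal heart-rate noise of 0.05 on the ln
#' scale.
#'
#' @param abt_true true breakpoint temperature, degrees C.
#' @param slope_pre,slope_post segment slopes in Arrhenius coordinates.
#' @param hr_at_20C heart rate at 20 degrees C, beats per minute.
#' @param ramp_rate warming rate, degrees C per minute.
#' @param temp_range ramp start/end temperatures, degrees C.
#' @param noise_sd sd of Gaussian noise on ln(heart rate).
#' @param arrhythmia_prob probability that an observation window is corrupted.
#' @param n_points number of heart-rate observations along the ramp.
#' @param seed integer RNG seed, or NA to use the current RNG state.
#' @return a validated \linkS4class{CardiacSimParams}.
#' @export
#' @examples
#' p <- cardiacSimParams(abt_true = 30, noise_sd = 0, arrhythmia_prob = 0)
#' s <- simulateHeartRateSeries(p)
cardiacSimParams <- function(abt_true = 31.9, slope_pre = -6,
                             slope_post = 40, hr_at_20C = 34,
                             ramp_rate = 0.1, temp_range = c(20, 34),
                             noise_sd = 0.05, arrhythmia_prob = 0.05,
                             n_points = 60L, seed = NA_integer_) {
  new("CardiacSimParams", abt_true = abt_true, slope_pre = slope_pre,
      slope_post = slope_post, hr_at_20C = hr_at_20C, ramp_rate = ramp_rate,
      temp_range = as.numeric(temp_range), noise_sd = noise_sd,
      arrhythmia_prob = arrhythmia_prob, n_points = as.integer(n_points),
      seed = as.integer(seed))
}

## expected ln(heart rate) of the continuous two-phase model at temp_C
.lnhrModel <- function(params, temp_C) {
  xb <- .xOf(params@abt_true)
  x20 <- .xOf(20)
  yb <- log(params@hr_at_20C) - params@slope_pre * (x20 - xb)
  x <- .xOf(temp_C)
  ifelse(x >= xb,
         yb + params@slope_pre * (x - xb),
         yb + params@slope_post * (x - xb))
}

#' Simulate a windowed heart-rate series along a temperature ramp
#'
#' Samples the continuous two-phase Arrhenius model at \code{n_points}
#' equally spaced temperatures, adds Gaussian noise on the ln scale and flags
#' a fraction of windows as arrhythmic (their rates are additionally
#' perturbed so that filtering is observable).
#'
#' @param params a \linkS4class{CardiacSimParams}.
#' @return a \linkS4class{HeartRateSeries}; diagnostics carry the true
#'   breakpoint and model slopes.
#' @export
simulateHeartRateSeries <- function(params) {
  stopifnot(is(params, "CardiacSimParams"))
  validObject(params)
  .withSeed(params@seed, {
    temps <- seq(params@temp_range[1], params@temp_range[2],
                 length.out = params@n_points)
    y <- .lnhrModel(params, temps)
    if (params@noise_sd > 0)
      y <- y + rnorm(params@n_points, 0, params@noise_sd)
    flagged <- runif(params@n_points) < params@arrhythmia_prob
    if (any(flagged))  # arrhythmia: erratic, mostly depressed rate
      y[flagged] <- y[flagged] + rnorm(sum(flagged), -0.5, 0.5)
    new("HeartRateSeries", temp_C = temps, hr_bpm = exp(y),
        n_beats = rep(NA_real_, params@n_points), flagged = flagged,
        diagnostics = list(abt_true = params@abt_true,
                           slope_pre = params@slope_pre,
                           slope_post = params@slope_post))
  })
}

#' Simulate a raw pulse sensor trace
#'
#' Generates a uniformly sampled sensor signal with one Gaussian-shaped pulse
#' per heart beat.  Beat times are obtained by integrating the instantaneous
#' rate implied by the two-phase Arrhenius model along the temperature ramp
#' (ramp duration = temperature span / ramp rate).  Windows of
#' \code{window_s} seconds are independently corrupted with probability
#' \code{arrhythmia_prob}: their beats are dropped and their samples flagged.
#'
#' @param params a \linkS4class{CardiacSimParams}; \code{noise_sd} here acts
#'   as additive Gaussian noise on the signal (in pulse-amplitude units).
#' @param sampling_hz sampling rate; must be at least 10 times the maximum
#'   instantaneous beat rate in Hz.
#' @param window_s corruption window length in seconds.
#' @return a \linkS4class{CardiacTrace}; metadata holds \code{beat_times}
#'   (clean beats actually present in the signal), \code{beat_times_all}, the
#'   corrupted window intervals and the sampling rate.
#' @export
simulatePulseTrace <- function(params, sampling_hz = 20, window_s = 30) {
  stopifnot(is(params, "CardiacSimParams"))
  validObject(params)
  .withSeed(params@seed, {
    dur_s <- diff(params@temp_range) / params@ramp_rate * 60
    time_s <- seq(0, dur_s, by = 1 / sampling_hz)
    temp_C <- params@temp_range[1] + params@ramp_rate * time_s / 60
    rate_hz <- exp(.lnhrModel(params, temp_C)) / 60
    max_hz <- max(rate_hz)
    if (sampling_hz < 10 * max_hz)
      stop("sampling_hz too low for the maximum beat rate (",
           sprintf("%.2f", max_hz), " Hz); use sampling_hz >= ",
           sprintf("%.1f", 10 * max_hz))
    ## cumulative expected beat count; beats centred at crossings of k - 1/2
    ## so that a whole number of beats never places a pulse on the trace edge
    cum <- c(0, cumsum((rate_hz[-1] + rate_hz[-length(rate_hz)]) / 2 *
                         diff(time_s)))
    n_beats <- floor(cum[length(cum)] + 0.5 - 1e-9)
    beat_all <- approx(cum, time_s, xout = seq_len(n_beats) - 0.5,
                       ties = "ordered", rule = 2)$y
    ## corrupted windows
    edges <- seq(0, dur_s + window_s, by = window_s)
    corrupt <- runif(length(edges) - 1) < params@arrhythmia_prob
    win_of <- function(t) pmin(findInterval(t, edges), length(edges) - 1)
    keep <- !corrupt[win_of(beat_all)]
    beats <- beat_all[keep]
    window_flag <- corrupt[win_of(time_s)]
    ## pulse train: Gaussian bump per retained beat (sd 10 percent of the
    ## shortest interbeat interval, so pulses stay well separated)
    width <- 0.1 / max_hz
    signal <- numeric(length(time_s))
    for (b in beats) {
      idx <- which(abs(time_s - b) < 4 * width)
      signal[idx] <- signal[idx] + exp(-(time_s[idx] - b)^2 / (2 * width^2))
    }
    if (params@noise_sd > 0)
      signal <- signal + rnorm(length(signal), 0, params@noise_sd)
    new("CardiacTrace", time_s = time_s, temp_C = temp_C, signal = signal,
        window_flag = window_flag,
        metadata = list(beat_times = beats, beat_times_all = beat_all,
                        corrupted_windows = which(corrupt),
                        window_s = window_s, sampling_hz = sampling_hz))
  })
}

#' Construct parameters for the negative-binomial count simulator
#'
#' Defaults emulate a 2-line x 2-condition x 3-replicate heat-stress design
#' with roughly 2.5 times as many heat-responsive genes in the sensitive line
#' as in the tolerant line, |log2 FC| spikes spanning 1.6-11.9 and a 65
#' percent up-regulation bias, log-normal baseline means centred near 100
#' counts, a decreasing dispersion trend alpha(mu) = 0.05 + 2/mu and modest
#' library-depth variation.
#'
#' @param n_genes number of genes.
#' @param design data.frame(line, condition, n_replicates).
#' @param mean_log_expression c(meanlog, sdlog) of baseline means.
#' @param dispersion_alpha0,dispersion_alpha1 dispersion trend coefficients.
#' @param de_fraction named per-line fraction of heat-responsive genes.
#' @param lfc_range support of |log2 FC| for spiked genes.
#' @param prob_up probability a spiked gene is up-regulated under heat.
#' @param lib_size_factors per-sample depth multipliers; NULL for a fixed
#'   geometric spread around 1.
#' @param seed integer RNG seed, or NA.
#' @return a validated \linkS4class{CountSimParams}.
#' @export
countSimParams <- function(n_genes = 5000L,
                           design = data.frame(
                             line = rep(c("sensitive", "tolerant"), each = 2),
                             condition = rep(c("control", "heat"), 2),
                             n_replicates = 3L),
                           mean_log_expression = c(meanlog = log(100),
                                                   sdlog = 1.5),
                           dispersion_alpha0 = 0.05,
                           dispersion_alpha1 = 2,
                           de_fraction = c(sensitive = 0.10,
                                           tolerant = 0.04),
                           lfc_range = c(1.6, 11.9),
                           prob_up = 0.65,
                           lib_size_factors = NULL,
                           seed = NA_integer_) {
  n_samples <- sum(design$n_replicates)
  if (is.null(lib_size_factors))
    lib_size_factors <- exp(seq(-0.2, 0.2, length.out = n_samples))
  new("CountSimParams", n_genes = as.integer(n_genes), design = design,
      mean_log_expression = as.numeric(mean_log_expression),
      dispersion_alpha0 = dispersion_alpha0,
      dispersion_alpha1 = dispersion_alpha1,
      de_fraction = de_fraction, lfc_range = as.numeric(lfc_range),
      prob_up = prob_up, lib_size_factors = as.numeric(lib_size_factors),
      seed = as.integer(seed))
}

#' Simulate a count matrix with known differential expression
#'
#' Draws gene baseline means from a log-normal, spikes per-line log2 fold
#' changes into the heat condition according to \code{de_fraction} and
#' \code{lfc_range}, scales by library size factors and samples negative
#' binomial counts with dispersion alpha(mu) = alpha0 + alpha1/mu.
#'
#' @param params a \linkS4class{CountSimParams}.
#' @return a \linkS4class{CountExperiment}; the truth table (per-gene true
#'   log2 FC per line) is in \code{metadata(ce)$truth} and also attached to
#'   \code{rowData}.
#' @export
simulateCounts <- function(params) {
  stopifnot(is(params, "CountSimParams"))
  validObject(params)
  .withSeed(params@seed, {
    d <- params@design
    line <- rep(d$line, d$n_replicates)
    condition <- rep(d$condition, d$n_replicates)
    n_s <- length(line)
    stopifnot(length(params@lib_size_factors) == n_s)
    gid <- sprintf("gene_%05d", seq_len(params@n_genes))
    mu0 <- exp(rnorm(params@n_genes, params@mean_log_expression[1],
                     params@mean_log_expression[2]))
    lines <- unique(d$line)
    truth <- data.frame(gene_id = gid, baseline_mean = mu0)
    lfc <- matrix(0, params@n_genes, length(lines),
                  dimnames = list(gid, lines))
    for (ln in lines) {
      frac <- if (ln %in% names(params@de_fraction))
        params@de_fraction[[ln]] else 0
      is_de <- runif(params@n_genes) < frac
      mag <- runif(sum(is_de), params@lfc_range[1], params@lfc_range[2])
      sgn <- ifelse(runif(sum(is_de)) < params@prob_up, 1, -1)
      lfc[is_de, ln] <- mag * sgn
      truth[[paste0("lfc_", ln)]] <- lfc[, ln]
    }
    alpha <- params@dispersion_alpha0 + params@dispersion_alpha1 / mu0
    counts <- matrix(0L, params@n_genes, n_s,
                     dimnames = list(gid, sprintf("%s_%s_%d", line, condition,
                                                  unlist(lapply(d$n_replicates,
                                                                seq_len)))))
    pois <- alpha == 0  # Poisson limit of the NB model
    for (j in seq_len(n_s)) {
      mu_j <- mu0 * params@lib_size_factors[j]
      if (condition[j] == "heat") mu_j <- mu_j * 2^lfc[, line[j]]
      cj <- integer(params@n_genes)
      if (any(pois)) cj[pois] <- rpois(sum(pois), mu_j[pois])
      if (any(!pois)) cj[!pois] <- rnbinom(sum(!pois), mu = mu_j[!pois],
                                           size = 1 / alpha[!pois])
      counts[, j] <- cj
    }
    ce <- CountExperiment(counts, line = line, condition = condition)
    S4Vectors::metadata(ce)$truth <- truth
    S4Vectors::metadata(ce)$sim_params <- params
    ce
  })
}
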