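# Offline ERD analysis: CSP component segments, Morlet time-frequency
# power, percent power change vs baseline, the 10-25 Hz / 0.5-1.5 s
# statistic, ERD onset latency, and the six-criterion CSP quality rubric.

#' Extract per-trial CSP component segments
#'
#' Applies one spatial filter to the (broadband) recording and cuts -2 to
#' 3 s segments around the MI onsets. Artifact screening as in
#' [reject_artifacts()] is applied across segments.
#'
#' @param recording An [eeg_recording()].
#' @param events Event tibble with `flexion_onset` / `extension_onset`
#'   markers.
#' @param filter Numeric spatial filter of length `n_channels`.
#' @param tmin,tmax Segment window in seconds relative to MI onset.
#' @param z_thresh Artifact rejection threshold (`Inf` disables).
#' @return An object of class `component_segments`: list with `data`
#'   (trial x sample matrix), `times`, `labels`, `fs`. Trials whose window
#'   leaves the recording are dropped with a warning.
#' @export
csp_component_segments <- function(recording, events, filter,
                                   tmin = -2, tmax = 3, z_thresh = 5) {
  if (length(filter) != length(recording$channels)) {
    abort_validation("`filter` length must equal the channel count")
  }
  fs <- recording$fs
  comp <- drop(recording$data %*% as.numeric(filter))
  onsets <- events[events$label %in% c("flexion_onset", "extension_onset"), ]
  i0 <- round((onsets$time + tmin) * fs) + 1
  len <- round((tmax - tmin) * fs) + 1
  ok <- i0 >= 1 & (i0 + len - 1) <= length(comp)
  if (any(!ok)) {
    warn(sprintf("dropped %d segment(s) outside recording bounds", sum(!ok)))
  }
  i0 <- i0[ok]
  labels <- sub("_onset$", "", onsets$label[ok])
  if (length(i0) == 0) abort_validation("no usable MI segments")
  data <- t(vapply(i0, function(s) comp[s:(s + len - 1)], numeric(len)))
  if (is.finite(z_thresh)) {
    peak <- apply(abs(data), 1, max)
    v <- apply(data, 1, var)
    rz <- function(x) {
      s <- mad(x); if (s < 1e-12) s <- max(sd(x), 1e-12)
      (x - median(x)) / s
    }
    bad <- rz(peak) > z_thresh | rz(v) > z_thresh
    if (all(bad)) abort_numerical("all segments rejected as artifactual")
    data <- data[!bad, , drop = FALSE]
    labels <- labels[!bad]
  }
  structure(list(data = data, labels = labels, fs = fs,
                 times = seq(tmin, tmax, by = 1 / fs)[seq_len(len)]),
            class = "component_segments")
}

# Complex Morlet wavelet coefficients of one signal via FFT convolution.
morlet_coefs <- function(x, fs, freq, n_cycles) {
  n <- length(x)
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- ceiling(4 * sigma_t * fs)
  tw <- (-half:half) / fs
  w <- exp(2i * pi * freq * tw) * exp(-tw^2 / (2 * sigma_t^2))
  w <- w / sum(abs(w))
  m <- stats::nextn(n + length(w) - 1, 2)
  conv <- fft(fft(c(x, rep(0, m - n))) *
                fft(c(w, rep(0, m - length(w)))), inverse = TRUE) / m
  conv[(half + 1):(half + n)]
}

#' Morlet time-frequency power of component segments
#'
#' Continuous Morlet wavelet transform (fixed number of cycles at all
#' frequencies), squared magnitude, on a 5-50 Hz grid in 1 Hz steps,
#' computed from -0.8 to 2.3 s around MI onset and resampled onto a 10 ms
#' time grid. Edge-contaminated times beyond that window are excluded
#' downstream.
#'
#' @param segments A [csp_component_segments()] object (or a plain numeric
#'   matrix trial x sample with attributes `fs`, `times`).
#' @param freqs Frequency grid in Hz.
#' @param n_cycles Morlet cycles (default 6).
#' @param tlim Computed time window in seconds relative to MI onset.
#' @param tstep Output time step in seconds.
#' @return An object of class `tf_power`: list with `power` (array freq x
#'   time x trial, raw power), `freqs`, `times`, `labels`.
#' @export
morlet_tf <- function(segments, freqs = 5:50, n_cycles = 6,
                      tlim = c(-0.8, 2.3), tstep = 0.01) {
  fs <- segments$fs
  seg_times <- segments$times
  widest <- ceiling(4 * (n_cycles / (2 * pi * min(freqs))) * fs)
  if (ncol(segments$data) <= 2 * widest) {
    abort_validation("segments too short for the widest wavelet")
  }
  out_times <- seq(tlim[1], tlim[2], by = tstep)
  out_idx <- round((out_times - seg_times[1]) * fs) + 1
  if (any(out_idx < 1 | out_idx > length(seg_times))) {
    abort_validation("requested time window extends beyond the segments")
  }
  ntr <- nrow(segments$data)
  power <- array(0, dim = c(length(freqs), length(out_times), ntr))
  for (tr in seq_len(ntr)) {
    x <- segments$data[tr, ]
    for (fi in seq_along(freqs)) {
      cf <- morlet_coefs(x, fs, freqs[fi], n_cycles)
      power[fi, , tr] <- Mod(cf[out_idx])^2
    }
  }
  structure(list(power = power, freqs = freqs, times = out_times,
                 labels = segments$labels),
            class = "tf_power")
}

#' Percent power change relative to baseline
#'
#' Per trial and frequency, power is converted to decibels
#' (`10 * log10`), the mean baseline (-0.5 to 0 s) level is subtracted, and
#' the dB difference is mapped back to a linear percent change
#' `100 * (10^(dB/10) - 1)`, so a power drop to a quarter reads -75%.
#' Values are restricted to the analyzed window (default -0.5 to 2 s) to
#' avoid wavelet edge artifacts.
#'
#' @param tf A [morlet_tf()] object.
#' @param baseline Baseline window in seconds.
#' @param analyze Analyzed time window in seconds.
#' @return An object of class `tf_map`: list with `values` (freq x time,
#'   percent change averaged across trials), `per_trial` (freq x time x
#'   trial array), `freqs`, `times`, `labels`, `baseline`.
#' @export
percent_power_change <- function(tf, baseline = c(-0.5, 0),
                                 analyze = c(-0.5, 2)) {
  if (baseline[1] < min(tf$times) || baseline[2] > max(tf$times)) {
    abort_validation("baseline window outside the computed time range")
  }
  keep <- tf$times >= analyze[1] & tf$times <= analyze[2] + 1e-9
  times <- tf$times[keep]
  base_idx <- which(tf$times >= baseline[1] & tf$times <= baseline[2] + 1e-9)
  ntr <- dim(tf$power)[3]
  eps <- .Machine$double.xmin
  per_trial <- array(0, dim = c(length(tf$freqs), sum(keep), ntr))
  floored <- FALSE
  for (tr in seq_len(ntr)) {
    p <- tf$power[, , tr]
    # baseline reference: mean baseline power per frequency (linear scale)
    base <- rowMeans(p[, base_idx, drop = FALSE])
    if (any(base <= 0)) { floored <- TRUE; base <- pmax(base, eps) }
    db <- 10 * log10(pmax(p[, keep, drop = FALSE], eps)) -
      rep(10 * log10(base), sum(keep))
    per_trial[, , tr] <- 100 * (10^(db / 10) - 1)
  }
  if (floored) warn("zero baseline power floored at machine minimum")
  structure(list(values = apply(per_trial, c(1, 2), mean),
                 per_trial = per_trial, freqs = tf$freqs, times = times,
                 labels = tf$labels, baseline = baseline),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d freqs (%g-%g Hz) x %d times (%.2f-%.2f s), %d trials\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              min(x$times), max(x$times), dim(x$per_trial)[3]))
  invisible(x)
}

#' Mean sensorimotor-rhythm power change
#'
#' Mean percent power change over the 10-25 Hz band and the 1 s analysis
#' window beginning 0.5 s after MI onset; averaged within each trial, then
#' across trials.
#'
#' @param tf_map A [percent_power_change()] map.
#' @param band Frequency band in Hz.
#' @param window Time window in seconds.
#' @param trials Optional logical/integer trial subset (e.g. one class).
#' @return Scalar percent change (negative = desynchronization).
#' @export
mean_smr_change <- function(tf_map, band = c(10, 25), window = c(0.5, 1.5),
                            trials = NULL) {
  fi <- tf_map$freqs >= band[1] & tf_map$freqs <= band[2]
  ti <- tf_map$times >= window[1] & tf_map$times <= window[2] + 1e-9
  if (!any(fi) || !any(ti)) {
    abort_validation("band/window selects an empty submatrix")
  }
  arr <- tf_map$per_trial
  if (!is.null(trials)) arr <- arr[, , trials, drop = FALSE]
  per_trial <- apply(arr[fi, ti, , drop = FALSE], 3, mean)
  mean(per_trial)
}

#' Per-trial band power traces
#'
#' Percent change averaged over the band, then smoothed with a short
#' moving average (default 0.2 s) to suppress within-band beating before
#' single-trial onset detection.
#'
#' @param tf_map A [percent_power_change()] map.
#' @param band Frequency band in Hz.
#' @param smooth Moving-average length in seconds (0 disables).
#' @return Matrix trial x time of percent change, with the time grid as
#'   attribute `times`.
#' @export
band_power_traces <- function(tf_map, band = c(10, 25), smooth = 0.2) {
  fi <- tf_map$freqs >= band[1] & tf_map$freqs <= band[2]
  out <- t(apply(tf_map$per_trial[fi, , , drop = FALSE], c(2, 3), mean))
  if (smooth > 0 && ncol(out) > 3) {
    dt <- diff(tf_map$times[1:2])
    k <- max(1L, round(smooth / dt))
    if (k > 1) {
      kern <- rep(1 / k, k)
      out <- t(apply(out, 1, function(x) {
        as.numeric(stats::filter(x, kern, sides = 2, circular = FALSE))
      }))
      # moving-average edges are undefined; hold the nearest valid value
      for (r in seq_len(nrow(out))) {
        v <- out[r, ]
        ok <- which(!is.na(v))
        v[seq_len(ok[1] - 1)] <- v[ok[1]]
        if (ok[length(ok)] < length(v)) {
          v[(ok[length(ok)] + 1):length(v)] <- v[ok[length(ok)]]
        }
        out[r, ] <- v
      }
    }
  }
  attr(out, "times") <- tf_map$times
  out
}

#' ERD onset latency
#'
#' Per trial, the ERD onset is the first analyzed time point at or after MI
#' onset at which the percent band-power change is at or below `threshold`
#' (default -30%). Trials never crossing are excluded; the participant
#' latency is the 20th percentile (linear interpolation) of the per-trial
#' onsets, which damps late-onset outliers.
#'
#' @param traces Trial x time matrix of percent change (see
#'   [band_power_traces()]), or a `tf_map` (band 10-25 Hz used).
#' @param times Time grid in seconds (taken from `traces` if attached).
#' @param threshold Percent-change threshold (default -30).
#' @param pctile Percentile of per-trial onsets (default 20).
#' @param sustain Seconds the trace must stay at or below the threshold for
#'   a time point to count as the onset (default 0.1; rejects isolated
#'   noise dips). 0 restores the plain first-crossing rule.
#' @return A list with `latency` (seconds; `NA` if no trial crosses),
#'   `onsets` (per-trial onset times) and `n_crossing`.
#' @export
erd_latency <- function(traces, times = attr(traces, "times"),
                        threshold = -30, pctile = 20, sustain = 0.1) {
  if (inherits(traces, "tf_map")) {
    traces <- band_power_traces(traces)
    times <- attr(traces, "times")
  }
  if (is.null(times) || length(times) != ncol(traces)) {
    abort_validation("`times` must match the trace length")
  }
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  k <- max(1L, round(sustain / dt))
  post <- which(times >= 0)
  onsets <- apply(traces, 1, function(tr) {
    below <- tr <= threshold
    # forward run length of below-threshold points starting at each index;
    # the onset needs k consecutive such points
    runlen <- integer(length(below))
    acc <- 0L
    for (i in rev(seq_along(below))) {
      acc <- if (below[i]) acc + 1L else 0L
      runlen[i] <- acc
    }
    hit <- post[which(runlen[post] >= k)]
    if (length(hit) == 0) NA_real_ else times[hit[1]]
  })
  crossing <- onsets[!is.na(onsets)]
  latency <- if (length(crossing) == 0) NA_real_ else {
    unname(quantile(crossing, pctile / 100, type = 7))
  }
  list(latency = latency, onsets = onsets, n_crossing = length(crossing))
}

# --- CSP quality rubric ------------------------------------------------------

cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  if (sp < 1e-12) return(0)
  (mean(x) - mean(y)) / sp
}

auc_stat <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Percent band power change of MI vs rest epochs on weighted channels.
weighted_band_change <- function(epochs_mi, epochs_rest, weights, channels,
                                 target, band = c(10, 25)) {
  idx <- match(target, channels)
  keep <- !is.na(idx)
  idx <- idx[keep]
  w <- abs(weights[idx])
  if (sum(w) < 1e-12) w <- rep(1, length(idx))
  w <- w / sum(w)
  band_power <- function(ep) {
    fs <- ep$fs
    vapply(seq_along(idx), function(k) {
      p <- 0
      for (i in seq_len(n_trials(ep))) {
        x <- ep$data[, idx[k], i]
        sp <- Mod(fft(x - mean(x)))^2
        f <- (seq_along(sp) - 1) * fs / length(sp)
        p <- p + sum(sp[f >= band[1] & f <= band[2]])
      }
      p / n_trials(ep)
    }, numeric(1))
  }
  p_mi <- band_power(epochs_mi)
  p_rest <- band_power(epochs_rest)
  100 * (sum(w * p_mi) / sum(w * p_rest) - 1)
}

score_one_filter <- function(model, component, epochs, mi_class, rest_class,
                             smr_set, contra_set, d_cut, auc_cut, erd_cut,
                             conc_cut) {
  idx_mi <- which(epochs$labels == mi_class)
  idx_rest <- which(epochs$labels == rest_class)
  pat <- model$patterns[, component]
  fil <- model$filters[, component]
  crit <- c(
    pattern_sensorimotor =
      weight_concentration(pat, model$channels, smr_set) >= conc_cut,
    filter_sensorimotor =
      weight_concentration(fil, model$channels, smr_set) >= conc_cut,
    power_discriminability = FALSE,
    single_trial_discriminability = FALSE,
    lateralized_erd = FALSE,
    power_normality = FALSE)
  if (length(idx_mi) < 3 || length(idx_rest) < 3) {
    warn(sprintf("fewer than 3 trials per class for %s filter; criteria 3/4/6 scored FALSE",
                 mi_class))
    return(crit)
  }
  feats <- logvar_features(epochs, model, components = component)
  f_mi <- feats[idx_mi, 1]
  f_rest <- feats[idx_rest, 1]
  crit["power_discriminability"] <- abs(cohens_d(f_mi, f_rest)) >= d_cut
  crit["single_trial_discriminability"] <-
    max(auc_stat(f_mi, f_rest), auc_stat(f_rest, f_mi)) >= auc_cut
  ep_mi <- subset_epochs(epochs, idx_mi)
  ep_rest <- subset_epochs(epochs, idx_rest)
  crit["lateralized_erd"] <-
    weighted_band_change(ep_mi, ep_rest, pat, model$channels,
                         contra_set) <= erd_cut
  sw <- function(x) {
    if (length(unique(round(x, 10))) < 3) return(0)
    shapiro.test(x)$p.value
  }
  crit["power_normality"] <- sw(f_mi) > 0.05 && sw(f_rest) > 0.05
  crit
}

# Pick the designated component: best class separation (criterion 3 proxy)
# among sensorimotor-concentrated candidates, preferring components whose
# MI-class variance is the lower one (the ERD signature expected during
# imagery); falls back to all candidates.
choose_component <- function(model, epochs, mi_class, rest_class,
                             smr_set = sensorimotor_channels(),
                             conc_cut = 0.5) {
  cand <- model$selected
  conc <- vapply(cand, function(j)
    weight_concentration(model$patterns[, j], model$channels, smr_set),
    numeric(1))
  pool <- cand[conc >= conc_cut]
  if (length(pool) == 0) pool <- cand
  idx_mi <- which(epochs$labels == mi_class)
  idx_rest <- which(epochs$labels == rest_class)
  dvals <- vapply(pool, function(j) {
    f <- logvar_features(epochs, model, components = j)
    cohens_d(f[idx_mi, 1], f[idx_rest, 1])
  }, numeric(1))
  if (any(dvals < 0)) pool[which.min(dvals)] else pool[which.max(dvals)]
}

#' Score CSP filter quality on the six-criterion rubric
#'
#' One flexion-contrast and one extension-contrast filter are each scored
#' on six binary criteria: (1) pattern concentrated over sensorimotor
#' channels; (2) filter concentrated over sensorimotor channels; (3)
#' recognizable class separation of the log-variance distributions
#' (|Cohen's d| >= `d_cut`); (4) single-trial discriminability (AUC >=
#' `auc_cut`); (5) contralateral sensorimotor ERD present (weighted band
#' power change <= `erd_cut` %); (6) per-class log-variance distributions
#' normally distributed (Shapiro-Wilk p > 0.05 for both). The total over
#' 2 filters x 6 criteria has a maximum of 12; totals >= 10 indicate
#' plausible filters. The visual-judgment criteria of filter vetting are
#' replaced here by these quantitative proxies.
#'
#' @param model_flexion,model_extension [fit_csp()] models contrasting
#'   flexion vs rest-open and extension vs rest-closed.
#' @param epochs Labelled training [epoch_set()].
#' @param components Optional length-2 vector of designated component
#'   indices; by default the best-separating sensorimotor candidate of each
#'   model is chosen.
#' @param smr_set,contra_set Sensorimotor channel set, and the channel set
#'   expected to carry the ERD of a right-hand movement (left-hemisphere
#'   plus midline hand-area sites).
#' @param d_cut,auc_cut,erd_cut,conc_cut Criterion cut-offs.
#' @return An object of class `csp_quality_report`: list with `criteria`
#'   (tibble criterion x filter), `total` (0-12) and `plausible`
#'   (`total >= 10`).
#' @export
csp_quality_score <- function(model_flexion, model_extension, epochs,
                              components = NULL,
                              smr_set = sensorimotor_channels(),
                              contra_set = c("C3", "CP1", "CP5", "FC1", "CZ", "CPz"),
                              d_cut = 0.5, auc_cut = 0.65, erd_cut = -20,
                              conc_cut = 0.5) {
  comp_f <- if (is.null(components)) {
    choose_component(model_flexion, epochs, "flexion", "rest_open",
                     smr_set, conc_cut)
  } else components[1]
  comp_e <- if (is.null(components)) {
    choose_component(model_extension, epochs, "extension", "rest_closed",
                     smr_set, conc_cut)
  } else components[2]
  crit_f <- score_one_filter(model_flexion, comp_f, epochs, "flexion",
                             "rest_open", smr_set, contra_set, d_cut,
                             auc_cut, erd_cut, conc_cut)
  crit_e <- score_one_filter(model_extension, comp_e, epochs, "extension",
                             "rest_closed", smr_set, contra_set, d_cut,
                             auc_cut, erd_cut, conc_cut)
  total <- sum(crit_f) + sum(crit_e)
  structure(list(
    criteria = tibble(criterion = names(crit_f),
                      flexion = unname(crit_f), extension = unname(crit_e)),
    components = c(flexion = comp_f, extension = comp_e),
    total = as.integer(total), plausible = total >= 10),
    class = "csp_quality_report")
}

#' @export
print.csp_quality_report <- function(x, ...) {
  cat(sprintf("<csp_quality_report> total %d / 12 — %s\n", x$total,
              if (x$plausible) "plausible" else "not plausible"))
  print(as.data.frame(x$criteria))
  invisible(x)
}

#' Recover ERD depth and latency from a time-frequency map
#'
#' Combines the band statistic and the onset estimator into a parameter
#' estimate of the underlying desynchronization: the latency is the
#' [erd_latency()] 20th-percentile onset, and the fractional depth is the
#' (sign-flipped) [mean_smr_change()] corrected for the part of the
#' 0.5-1.5 s analysis window that precedes the estimated onset, during
#' which no desynchronization can be present.
#'
#' @param tf_map A [percent_power_change()] map.
#' @param trials Optional trial subset (e.g. one MI class).
#' @param band,window Band and window of the depth statistic.
#' @param ... Passed to [erd_latency()].
#' @return A tibble `depth` (fraction in `[0, 1]`), `latency` (s),
#'   `smr_change` (the raw percent statistic) and `n_crossing`.
#' @export
estimate_erd_parameters <- function(tf_map, trials = NULL, band = c(10, 25),
                                    window = c(0.5, 1.5), ...) {
  traces <- band_power_traces(tf_map, band = band)
  times <- attr(traces, "times")
  if (!is.null(trials)) traces <- traces[trials, , drop = FALSE]
  lat <- erd_latency(traces, times = times, ...)
  smr <- mean_smr_change(tf_map, band = band, window = window,
                         trials = trials)
  overlap <- if (is.na(lat$latency)) 1 else {
    (window[2] - min(max(window[1], lat$latency), window[2])) /
      (window[2] - window[1])
  }
  depth <- if (overlap > 0) pmin(pmax(-smr / 100 / overlap, 0), 1) else NA_real_
  tibble(depth = depth, latency = lat$latency, smr_change = smr,
         n_crossing = lat$n_crossing)
}
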