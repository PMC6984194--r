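# Signal processing: band-pass filtering, epoching, artifact rejection,
# CSP spatial filtering and log-variance features.

#' Band-pass filter a recording
#'
#' 4th-order Butterworth band-pass (8-28 Hz by default, the band used for
#' classifier training). `causal` applies a single forward pass, as required
#' on the online controller path; `zero_phase` applies forward-backward
#' filtering for offline analysis.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param mode `"zero_phase"` (default) or `"causal"`.
#' @param order Butterworth order per pass.
#' @return The filtered [eeg_recording()].
#' @export
bandpass <- function(recording, low = 8, high = 28,
                     mode = c("zero_phase", "causal"), order = 4) {
  mode <- match.arg(mode)
  fs <- recording$fs
  if (!(low > 0 && high > low && high < fs / 2)) {
    abort_validation("band edges must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- recording$data
  for (ch in seq_len(ncol(out))) {
    out[, ch] <- if (mode == "causal") {
      as.numeric(signal::filter(bf, out[, ch]))
    } else {
      as.numeric(signal::filtfilt(bf, out[, ch]))
    }
  }
  eeg_recording(out, fs = fs, channels = recording$channels)
}

#' Construct an epoch set
#'
#' @param data Numeric array `[sample, channel, trial]`.
#' @param labels Per-trial class labels (`flexion`, `extension`,
#'   `rest_open`, `rest_closed`).
#' @param fs Sampling rate in Hz.
#' @param t0 Epoch start in seconds relative to the MI onset.
#' @param meta Optional per-trial tibble (e.g. `run`, `onset_time`).
#' @param channels Channel labels.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, t0 = 0, meta = NULL, channels = NULL) {
  if (length(dim(data)) != 3L) {
    abort_validation("`data` must be a sample x channel x trial array")
  }
  if (dim(data)[3] != length(labels)) {
    abort_validation("`labels` length must equal the trial count")
  }
  if (is.null(channels)) channels <- dimnames(data)[[2]]
  structure(list(data = data, labels = as.character(labels), fs = fs,
                 t0 = t0, meta = meta, channels = channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[3], dim(x$data)[2], dim(x$data)[1], x$fs))
  print(table(x$labels))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[3]

subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[, , idx, drop = FALSE], epochs$labels[idx],
            fs = epochs$fs, t0 = epochs$t0,
            meta = if (is.null(epochs$meta)) NULL else epochs$meta[idx, , drop = FALSE],
            channels = epochs$channels)
}

#' Epoch a training-block recording
#'
#' Cuts one 1.5 s epoch per flexion and extension onset and two rest epochs
#' per run, one from each 5 s rest period. Rest epochs start 1.75 s into the
#' rest period (centered, clear of movement-offset transients) and are
#' labelled by the hand state at rest: `rest_open` before flexion trials,
#' `rest_closed` before extension trials — giving twice as many rest trials
#' as flexion or extension trials.
#'
#' @param recording An [eeg_recording()] (typically band-pass filtered).
#' @param events Event tibble with MI onset and rest onset markers.
#' @param epoch_length Epoch length in seconds.
#' @param rest_offset Seconds into each rest period at which the rest epoch
#'   starts.
#' @return An [epoch_set()]; epochs extending past the recording bounds are
#'   dropped with a warning.
#' @export
epoch_training <- function(recording, events, epoch_length = 1.5,
                           rest_offset = 1.75) {
  fs <- recording$fs
  n <- n_samples(recording)
  len <- round(epoch_length * fs)
  if (nrow(events) == 0) {
    return(epoch_set(array(0, dim = c(len, length(recording$channels), 0)),
                     character(), fs = fs, channels = recording$channels))
  }
  ev <- events
  is_mi <- ev$label %in% c("flexion_onset", "extension_onset")
  is_rest <- ev$label == "rest_onset"
  # rest label = hand state, inferred from the MI trial the rest precedes
  spec <- list()
  for (i in which(is_mi)) {
    spec[[length(spec) + 1]] <- list(
      start = ev$time[i], label = sub("_onset$", "", ev$label[i]),
      run = if ("run" %in% names(ev)) ev$run[i] else NA_integer_)
  }
  rest_idx <- which(is_rest)
  for (i in rest_idx) {
    nxt <- which(is_mi & seq_len(nrow(ev)) > i)
    lab <- if (length(nxt) == 0) "rest_open"
           else if (ev$label[min(nxt)] == "flexion_onset") "rest_open"
           else "rest_closed"
    spec[[length(spec) + 1]] <- list(
      start = ev$time[i] + rest_offset, label = lab,
      run = if ("run" %in% names(ev)) ev$run[i] else NA_integer_)
  }
  starts <- vapply(spec, `[[`, numeric(1), "start")
  labels <- vapply(spec, `[[`, character(1), "label")
  runs <- vapply(spec, `[[`, numeric(1), "run")
  ord <- order(starts)
  starts <- starts[ord]; labels <- labels[ord]; runs <- runs[ord]

  i0 <- round(starts * fs) + 1
  ok <- i0 >= 1 & (i0 + len - 1) <= n
  if (any(!ok)) {
    warn(sprintf("dropped %d epoch(s) extending past recording bounds (%s)",
                 sum(!ok), paste(labels[!ok], collapse = ", ")))
  }
  i0 <- i0[ok]; labels <- labels[ok]; starts <- starts[ok]; runs <- runs[ok]
  data <- array(0, dim = c(len, length(recording$channels), length(i0)))
  for (k in seq_along(i0)) {
    data[, , k] <- recording$data[i0[k]:(i0[k] + len - 1), ]
  }
  epoch_set(data, labels, fs = fs, t0 = 0,
            meta = tibble(onset_time = starts, run = runs),
            channels = recording$channels)
}

#' Reject artifact-contaminated epochs
#'
#' Automatic amplitude/variance screening: epochs whose peak absolute
#' amplitude or total variance exceeds `z_thresh` robust z-scores
#' (median/MAD across epochs) are removed.
#'
#' @param epochs An [epoch_set()].
#' @param z_thresh Robust z-score threshold (default 5; `Inf` keeps all).
#' @return The cleaned [epoch_set()], with a `rejection` attribute listing
#'   the removed trial indices and the statistic that triggered removal.
#' @export
reject_artifacts <- function(epochs, z_thresh = 5) {
  nt <- n_trials(epochs)
  if (nt == 0) abort_validation("`epochs` must contain at least one trial")
  peak <- apply(abs(epochs$data), 3, max)
  v <- apply(epochs$data, 3, function(x) var(as.vector(x)))
  rz <- function(x) {
    s <- mad(x)
    if (s < 1e-12) s <- sd(x)
    if (s < 1e-12) return(rep(0, length(x)))
    (x - median(x)) / s
  }
  z_peak <- rz(peak); z_var <- rz(v)
  bad <- z_peak > z_thresh | z_var > z_thresh
  if (all(bad)) {
    abort_numerical("all epochs rejected as artifactual; pipeline cannot proceed")
  }
  out <- subset_epochs(epochs, which(!bad))
  attr(out, "rejection") <- tibble(
    trial = which(bad),
    reason = ifelse(z_peak[bad] > z_thresh, "amplitude", "variance"))
  out
}

#' Fit common spatial patterns for a class pair
#'
#' Solves the generalized eigenproblem `Sigma_A w = lambda (Sigma_A +
#' Sigma_B) w` on trace-normalized, trial-averaged class covariances. The
#' filters simultaneously diagonalize both class covariances; eigenvalues
#' (the class-A variance ratios) are sorted descending, so the first
#' components maximize class-A variance and the last maximize class-B
#' variance. The first four and last four components are marked as
#' candidates, matching the 24-filter / first-four-plus-last-four selection
#' used for classifier calibration.
#'
#' @param epochs_a,epochs_b [epoch_set()]s of the two contrasted classes
#'   (>= 2 trials each).
#' @param shrinkage Ledoit-Wolf-style shrinkage fraction toward the scaled
#'   identity (default 0).
#' @param n_candidates Components marked from each end (default 4).
#' @return An object of class `csp_model` with fields `filters` (channel x
#'   component matrix W), `patterns` (A = t(W)^-1), `eigenvalues`,
#'   `selected` (candidate component indices), `class_pair`, `channels`.
#' @export
fit_csp <- function(epochs_a, epochs_b, shrinkage = 0, n_candidates = 4) {
  if (n_trials(epochs_a) < 2 || n_trials(epochs_b) < 2) {
    abort_validation("fit_csp needs at least 2 epochs per class")
  }
  cov_a <- class_covariance(epochs_a, shrinkage)
  cov_b <- class_covariance(epochs_b, shrinkage)
  p <- ncol(cov_a)
  r_inv_sqrt <- sym_inv_sqrt(cov_a + cov_b)
  m <- r_inv_sqrt %*% cov_a %*% r_inv_sqrt
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  w <- r_inv_sqrt %*% e$vectors           # descending lambda
  w <- apply(w, 2, function(col) col / sqrt(sum(col^2)))
  a <- t(solve(w))
  # sign convention: largest-magnitude pattern weight positive
  for (j in seq_len(p)) {
    s <- sign(a[which.max(abs(a[, j])), j])
    if (s < 0) { w[, j] <- -w[, j]; a[, j] <- -a[, j] }
  }
  channels <- epochs_a$channels
  rownames(w) <- rownames(a) <- channels
  k <- min(n_candidates, floor(p / 2))
  structure(list(
    filters = w, patterns = a, eigenvalues = e$values,
    selected = c(seq_len(k), (p - k + 1):p),
    class_pair = c(unique(epochs_a$labels)[1], unique(epochs_b$labels)[1]),
    channels = channels),
    class = "csp_model")
}

class_covariance <- function(epochs, shrinkage = 0) {
  nt <- n_trials(epochs)
  p <- dim(epochs$data)[2]
  acc <- matrix(0, p, p)
  for (i in seq_len(nt)) {
    x <- epochs$data[, , i]
    cc <- crossprod(x)
    tr <- sum(diag(cc))
    if (tr < 1e-300) next
    acc <- acc + cc / tr
  }
  cov <- acc / nt
  if (shrinkage > 0) {
    cov <- (1 - shrinkage) * cov + shrinkage * (sum(diag(cov)) / p) * diag(p)
  }
  cov
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %s vs %s: %d filters, %d selected\n",
              x$class_pair[1], x$class_pair[2], ncol(x$filters),
              length(x$selected)))
  invisible(x)
}

#' Log-variance features of CSP-projected epochs
#'
#' `feature[i, j] = log(var(w_j' x_i))` for each trial `i` and selected
#' component `j`. Zero-variance projections are floored at machine epsilon
#' with a warning.
#'
#' @param epochs An [epoch_set()].
#' @param model A [fit_csp()] model.
#' @param components Component indices (default `model$selected`).
#' @return Numeric trial x component matrix; all entries finite.
#' @export
logvar_features <- function(epochs, model, components = model$selected) {
  if (length(components) == 0) {
    abort_validation("`components` must be non-empty")
  }
  w <- model$filters[, components, drop = FALSE]
  nt <- n_trials(epochs)
  out <- matrix(0, nrow = nt, ncol = ncol(w))
  for (i in seq_len(nt)) {
    proj <- epochs$data[, , i] %*% w
    out[i, ] <- apply(proj, 2, var)
  }
  if (any(out < .Machine$double.eps)) {
    warn("zero-variance projected epoch(s); features floored at machine epsilon")
    out <- pmax(out, .Machine$double.eps)
  }
  colnames(out) <- paste0("csp", components)
  log(out)
}

# Fraction of squared pattern/filter weight on a channel set.
weight_concentration <- function(weights, channels, target) {
  idx <- match(target, channels)
  idx <- idx[!is.na(idx)]
  sum(weights[idx]^2) / sum(weights^2)
}

#' Retain physiologically plausible CSP components
#'
#' Automatic proxy for visual filter inspection: among the candidate
#' components (first four + last four), keep those whose pattern
#' concentrates at least `min_concentration` of its squared weight over the
#' sensorimotor channel set. At least one component is always retained (the
#' best concentrated one).
#'
#' @param model A [fit_csp()] model.
#' @param channels Sensorimotor channel labels
#'   (default [sensorimotor_channels()]).
#' @param min_concentration Squared-weight fraction cut-off (default 0.5).
#' @return The model with `selected` reduced to the plausible candidates.
#' @export
select_plausible_components <- function(model,
                                        channels = sensorimotor_channels(),
                                        min_concentration = 0.5) {
  conc <- vapply(model$selected, function(j) {
    weight_concentration(model$patterns[, j], model$channels, channels)
  }, numeric(1))
  keep <- conc >= min_concentration
  if (!any(keep)) keep[which.max(conc)] <- TRUE
  model$selected <- model$selected[keep]
  model$concentration <- setNames(conc[keep], model$selected)
  model
}
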