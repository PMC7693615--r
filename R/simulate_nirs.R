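#' Simulation configuration for fNIRS recordings
#'
#' Bundles the generative parameters of the optical forward model. Evoked
#' concentration amplitudes are expressed in molar x 1e-8 (so a value of 1
#' means 1e-8 M); the defaults give a parietal-dominant activation pattern
#' that is constant over groups and time points. Physiological noise is
#' injected in the concentration domain as narrow-band oscillations
#' (cardiac ~1 Hz, respiratory ~0.3 Hz, Mayer waves ~0.1 Hz, very-low
#' frequency drift) plus white noise; motion artifacts (one-sample spikes
#' and persistent baseline shifts) are injected in the optical-density
#' domain.
#'
#' @param fs sampling rate, Hz
#' @param wavelengths the two acquisition wavelengths, nm
#' @param amp_frontal,amp_parietal evoked O2Hb peak amplitude (molar x 1e-8)
#' @param hhb_ratio evoked HHb / O2Hb amplitude ratio (negative)
#' @param condition_weights relative evoked amplitude per load condition
#' @param channel_sdlog log-normal SD of per-channel amplitude gains
#' @param roi_sdlog log-normal SD of per-participant sub-ROI amplitude effects
#' @param roi_correlation between sub-ROI correlation of those effects
#' @param cardiac,respiratory,mayer,drift,white noise amplitudes (molar x 1e-8)
#' @param cardiac_freq,respiratory_freq,mayer_freq,drift_freq centre
#'   frequencies, Hz
#' @param hhb_noise_scale noise amplitude scale for the HHb chromophore
#' @param spike_rate spikes per second; `spike_amp` spike amplitude in OD units
#' @param shift_rate baseline shifts per second; `shift_amp` step size in OD
#' @param pre_roll,post_roll recording padding before/after the task, seconds
#' @param baseline per-channel raw-intensity baseline (arbitrary units)
#' @return list of class `sim_config`
#' @export
sim_config <- function(fs = 3.47, wavelengths = c(760, 850),
                       amp_frontal = 1.1, amp_parietal = 2.0,
                       hhb_ratio = -1 / 3,
                       condition_weights = c("0-back" = 0.4, "1-back" = 0.7,
                                             "2-back" = 1.0),
                       channel_sdlog = 0.4, roi_sdlog = 0.3,
                       roi_correlation = 0.8,
                       cardiac = 0.75, cardiac_freq = 1.0,
                       respiratory = 0.3, respiratory_freq = 0.3,
                       mayer = 0.4, mayer_freq = 0.1,
                       drift = 1.0, drift_freq = 0.004,
                       white = 0.2, hhb_noise_scale = 0.3,
                       spike_rate = 0.005, spike_amp = 0.01,
                       shift_rate = 0.002, shift_amp = 0.005,
                       pre_roll = 15, post_roll = 15, baseline = 1.0) {
  stopifnot(fs > 0, all(c(cardiac, respiratory, mayer, drift, white) >= 0),
            spike_rate >= 0, shift_rate >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

.sub_rois <- c("DLPFC.left", "DLPFC.right", "VLPFC.left", "VLPFC.right",
               "IPL.left", "IPL.right", "SPL.left", "SPL.right")

#' Generate one dual-wavelength fNIRS recording
#'
#' Builds per-channel O2Hb/HHb concentration time series (task-evoked
#' component plus physiological noise), converts them to optical density at
#' both wavelengths through the forward Beer-Lambert relation with the
#' participant's age-dependent pathlength factor, maps optical density to
#' raw intensity about a constant baseline, and injects motion artifacts.
#' All generating quantities are returned as ground truth for testing; the
#' analysis stages never see them.
#'
#' @param config a [sim_config()]
#' @param montage montage data.frame (see [default_montage()])
#' @param participant_id identifier
#' @param group,time_point design cell (carried into metadata)
#' @param age participant age, years (sets the pathlength factor)
#' @param noise,artifacts logical master switches
#' @param seed integer seed; identical seeds give identical recordings
#' @return list with `recording` (class `nirs_recording`: `fs`,
#'   `wavelengths`, `time`, `intensity` array samples x channels x 2,
#'   `events`, `montage`, `age`, metadata) and `truth` (per-channel evoked
#'   amplitudes in molar x 1e-8, clean concentration matrices, artifact
#'   sample indices, the evoked regressor)
#' @export
generate_nirs_recording <- function(config = sim_config(),
                                    montage = default_montage(),
                                    participant_id = "P01",
                                    group = "experimental",
                                    time_point = "pre",
                                    age = 69, noise = TRUE, artifacts = TRUE,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$fs
  schedule <- nback_schedule(randomize = TRUE)
  schedule$onset <- schedule$onset + config$pre_roll
  dur <- config$pre_roll + 405 + config$post_roll
  time <- seq(0, dur - 1 / fs, by = 1 / fs)
  nt <- length(time)
  nch <- nrow(montage)

  regressor <- hrf_regressor(time, schedule, weights = config$condition_weights,
                             fs = fs)

  # participant-level correlated sub-ROI amplitude effects
  R <- matrix(config$roi_correlation, 8, 8)
  diag(R) <- 1
  roi_eff <- exp(MASS::mvrnorm(1, rep(0, 8),
                               config$roi_sdlog^2 * R))
  names(roi_eff) <- .sub_rois

  dpf <- compute_dpf(age)
  ext <- extinction_coefficients()
  d_cm <- montage$distance * 100

  # channel gains spread amplitude within a sub-ROI but keep its mean at
  # the sub-ROI effect, so the configured ROI correlation is recoverable
  amp <- numeric(nch)
  for (sr in .sub_rois) {
    parts <- strsplit(sr, ".", fixed = TRUE)[[1]]
    chs <- which(montage$roi == parts[1] & montage$hemisphere == parts[2])
    if (length(chs) == 0) next
    base_amp <- if (parts[1] %in% c("DLPFC", "VLPFC")) config$amp_frontal
                else config$amp_parietal
    gains <- stats::rlnorm(length(chs), 0, config$channel_sdlog)
    gains <- gains / mean(gains)
    amp[chs] <- base_amp * roi_eff[[sr]] * gains
  }
  hbo <- matrix(0, nt, nch)
  hhb <- matrix(0, nt, nch)
  od <- array(0, dim = c(nt, nch, 2))
  spike_idx <- vector("list", nch)
  shift_idx <- vector("list", nch)

  for (ch in seq_len(nch)) {
    hbo_ch <- amp[ch] * regressor
    hhb_ch <- config$hhb_ratio * hbo_ch
    if (noise) {
      osc <- function(a, f) {
        a * sin(2 * pi * f * (1 + stats::rnorm(1, 0, 0.03)) * time +
                  stats::runif(1, 0, 2 * pi))
      }
      n_hbo <- osc(config$cardiac, config$cardiac_freq) +
        osc(config$respiratory, config$respiratory_freq) +
        osc(config$mayer, config$mayer_freq) +
        osc(config$drift, config$drift_freq) +
        stats::rnorm(nt, 0, config$white)
      n_hhb <- config$hhb_noise_scale *
        (osc(config$cardiac, config$cardiac_freq) +
           osc(config$respiratory, config$respiratory_freq) +
           osc(config$mayer, config$mayer_freq) +
           osc(config$drift, config$drift_freq) +
           stats::rnorm(nt, 0, config$white))
      hbo_ch <- hbo_ch + n_hbo
      hhb_ch <- hhb_ch + n_hhb
    }
    hbo[, ch] <- hbo_ch
    hhb[, ch] <- hhb_ch
    # forward modified Beer-Lambert: concentrations are molar x 1e-8
    for (w in 1:2) {
      od[, ch, w] <- (ext[w, "HbO2"] * hbo_ch + ext[w, "HHb"] * hhb_ch) *
        1e-8 * d_cm[ch] * dpf
    }
    if (artifacts) {
      ns <- stats::rpois(1, config$spike_rate * dur)
      if (ns > 0) {
        idx <- sample(nt, ns)
        spike_idx[[ch]] <- sort(idx)
        a <- config$spike_amp * stats::runif(ns, 0.5, 1.5) *
          sample(c(-1, 1), ns, replace = TRUE)
        for (w in 1:2) od[idx, ch, w] <- od[idx, ch, w] + a
      }
      nb <- stats::rpois(1, config$shift_rate * dur)
      if (nb > 0) {
        idx <- sort(sample(nt, nb))
        shift_idx[[ch]] <- idx
        a <- config$shift_amp * stats::runif(nb, 0.5, 1.5) *
          sample(c(-1, 1), nb, replace = TRUE)
        for (k in seq_len(nb)) {
          for (w in 1:2) {
            od[idx[k]:nt, ch, w] <- od[idx[k]:nt, ch, w] + a[k]
          }
        }
      }
    }
  }

  intensity <- array(config$baseline, dim = dim(od)) * exp(-od)
  dimnames(intensity) <- list(NULL, montage$label,
                              paste0("wl", config$wavelengths))

  recording <- structure(list(
    fs = fs, wavelengths = config$wavelengths, time = time,
    intensity = intensity, events = schedule, montage = montage,
    age = age, participant_id = participant_id, group = group,
    time_point = time_point
  ), class = "nirs_recording")

  truth <- list(amplitude = amp, roi_effects = roi_eff,
                hbo = hbo, hhb = hhb, regressor = regressor,
                spikes = spike_idx, shifts = shift_idx)
  list(recording = recording, truth = truth)
}
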