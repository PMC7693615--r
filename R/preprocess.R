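#' Convert raw intensity to optical-density change
#'
#' Computes the optical-density change of every channel x wavelength series
#' relative to its own temporal mean: `dOD(t) = -ln(I(t) / mean(I))`. A
#' channel's overall intensity scale therefore cancels out.
#'
#' @param rec a `nirs_recording`
#' @return list of class `od_series`: `od` (array samples x channels x 2),
#'   plus sampling metadata and provenance flags
#' @export
intensity_to_od <- function(rec) {
  I <- rec$intensity
  if (any(!is.finite(I)) || any(I <= 0)) {
    bad <- which(I <= 0 | !is.finite(I), arr.ind = TRUE)[1, ]
    stop(sprintf("intensity_to_od: non-positive intensity at sample %d, channel %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  od <- I
  for (ch in seq_len(dim(I)[2])) {
    for (w in 1:2) {
      od[, ch, w] <- -log(I[, ch, w] / mean(I[, ch, w]))
    }
  }
  structure(list(od = od, fs = rec$fs, time = rec$time,
                 wavelengths = rec$wavelengths, events = rec$events,
                 montage = rec$montage, age = rec$age,
                 participant_id = rec$participant_id, group = rec$group,
                 time_point = rec$time_point,
                 qc_passed = NULL, motion_corrected = FALSE, filtered = FALSE),
            class = "od_series")
}

# Welch power spectral density: Hann-windowed overlapping segments
welch_psd <- function(x, fs, n_segments = 8) {
  n <- length(x)
  seg_len <- max(32, floor(2 * n / (n_segments + 1)))
  seg_len <- seg_len - seg_len %% 2
  step <- seg_len %/% 2
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  starts <- seq(1, n - seg_len + 1, by = step)
  acc <- numeric(seg_len %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg))^2 / (fs * sum(win^2))
    acc <- acc + sp[seq_len(seg_len %/% 2 + 1)]
  }
  list(freq = (seq_len(seg_len %/% 2 + 1) - 1) * fs / seg_len,
       power = acc / length(starts))
}

#' Cardiac-peak channel quality check
#'
#' A channel passes when the Welch power spectrum of its 850 nm (O2Hb
#' dominant) optical-density series shows a cardiac peak: the maximum power
#' inside the cardiac band must exceed `factor` times the median broadband
#' power. Channels without such a peak indicate poor optode-scalp contact
#' and are dropped from all later stages.
#'
#' @param od an `od_series`
#' @param band cardiac search band, Hz
#' @param factor required peak-to-median power ratio
#' @return the `od_series` with a logical `qc_passed` vector attached
#' @export
cardiac_quality_check <- function(od, band = c(0.5, 1.6), factor = 3) {
  if (isTRUE(od$motion_corrected) || isTRUE(od$filtered))
    stop("cardiac_quality_check: must run before motion correction and filtering",
         call. = FALSE)
  n <- dim(od$od)[1]
  if (n / od$fs < 60)
    stop("cardiac_quality_check: recording shorter than 60 s, QC not evaluable",
         call. = FALSE)
  w850 <- which.min(abs(od$wavelengths - 850))
  nch <- dim(od$od)[2]
  pass <- logical(nch)
  for (ch in seq_len(nch)) {
    x <- od$od[, ch, w850]
    if (stats::sd(x) == 0) {
      pass[ch] <- FALSE
      next
    }
    p <- welch_psd(x, od$fs)
    in_band <- p$freq >= band[1] & p$freq <= band[2]
    pass[ch] <- max(p$power[in_band]) > factor * stats::median(p$power[p$freq > 0])
  }
  od$qc_passed <- pass
  od
}

#' Wavelet motion-artifact correction
#'
#' Per channel and wavelength, decomposes the optical-density series with a
#' Daubechies-2 discrete wavelet transform, zeroes detail coefficients that
#' fall outside `[Q1 - f*IQR, Q3 + f*IQR]` of their level's coefficient
#' distribution (those coefficients are attributed to motion), and inverts
#' the transform. The decomposition depth is chosen so the approximation
#' band still contains the haemodynamic response (approximation cut-off
#' kept above `protect_hz`), which leaves slow evoked activity untouched
#' while transient artifacts land in the detail levels.
#'
#' @param od an `od_series`
#' @param iqr_factor the interquartile-range multiplier `f` (0.1 default)
#' @param protect_hz lowest frequency to protect in the approximation band
#' @return the corrected `od_series` (`motion_corrected = TRUE`)
#' @export
wavelet_motion_correct <- function(od, iqr_factor = 0.1, protect_hz = 0.1) {
  if (isTRUE(od$filtered))
    stop("wavelet_motion_correct: must run before band-pass filtering",
         call. = FALSE)
  levels <- max(1, floor(log2(od$fs / protect_hz)) - 1)
  for (ch in seq_len(dim(od$od)[2])) {
    for (w in 1:2) {
      x <- od$od[, ch, w]
      if (stats::sd(x) == 0) next
      dec <- dwt_db2(x, levels)
      for (l in seq_along(dec$details)) {
        d <- dec$details[[l]]
        q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
        iqr <- q[2] - q[1]
        out <- d < q[1] - iqr_factor * iqr | d > q[2] + iqr_factor * iqr
        d[out] <- 0
        dec$details[[l]] <- d
      }
      od$od[, ch, w] <- idwt_db2(dec)
    }
  }
  od$motion_corrected <- TRUE
  od
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a fifth-order high-pass at `low` Hz and a third-order low-pass at
#' `high` Hz, each run forward and backward (zero phase) over every channel
#' x wavelength optical-density series. The band isolates the haemodynamic
#' response and removes cardiac, respiratory, Mayer-wave and very-low
#' frequency components.
#'
#' @param od an `od_series`
#' @param low,high cut-off frequencies, Hz
#' @param lp_order,hp_order Butterworth orders of the low-/high-pass stages
#' @return the filtered `od_series` (`filtered = TRUE`)
#' @export
bandpass_filter <- function(od, low = 0.01, high = 0.08,
                            lp_order = 3, hp_order = 5) {
  nyq <- od$fs / 2
  if (high >= nyq || low >= nyq)
    stop("bandpass_filter: cut-off at or above Nyquist frequency", call. = FALSE)
  if (low >= high)
    stop("bandpass_filter: low cut-off must be below high cut-off", call. = FALSE)
  hp <- signal::butter(hp_order, low / nyq, type = "high")
  lp <- signal::butter(lp_order, high / nyq, type = "low")
  n <- dim(od$od)[1]
  # mean removal plus odd-reflection padding suppresses the start-up
  # transients of the forward-backward passes at the very low cut-off
  pad <- min(n - 1, ceiling(3 * od$fs / low))
  for (ch in seq_len(dim(od$od)[2])) {
    for (w in 1:2) {
      x <- od$od[, ch, w]
      mu <- mean(x)
      x <- x - mu
      xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
      xp <- signal::filtfilt(hp, xp)
      xp <- signal::filtfilt(lp, xp)
      od$od[, ch, w] <- xp[(pad + 1):(pad + n)]
    }
  }
  od$filtered <- TRUE
  od
}

#' Age-dependent differential pathlength factor
#'
#' `DPF = 4.99 + 0.067 * age^0.814`, the differential pathlength factor at
#' the 807 nm reference wavelength as a function of age in years. The same
#' factor is applied to both acquisition wavelengths by default.
#'
#' @param age age in years (`>= 0`)
#' @param a,b,c model coefficients
#' @return unitless pathlength factor
#' @examples compute_dpf(25) # ~5.91
#' @export
compute_dpf <- function(age, a = 4.99, b = 0.067, c = 0.814) {
  if (any(age < 0)) stop("compute_dpf: age must be >= 0", call. = FALSE)
  a + b * age^c
}

#' Molar extinction coefficients of haemoglobin
#'
#' Literature values (Gratzer/Prahl compilation, as shipped with standard
#' fNIRS toolboxes) of the molar extinction coefficients of oxygenated and
#' deoxygenated haemoglobin at the two acquisition wavelengths, in
#' 1/(M x cm).
#'
#' @param wavelengths the two wavelengths, nm (only 760/850 shipped)
#' @return 2 x 2 matrix, rows = wavelengths, columns = `HbO2`, `HHb`
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  tab <- rbind(
    "760" = c(HbO2 = 1486.5865, HHb = 3843.707),
    "850" = c(HbO2 = 2526.391, HHb = 1798.643)
  )
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab)))
    stop("extinction_coefficients: no shipped values for requested wavelengths",
         call. = FALSE)
  tab[key, , drop = FALSE]
}

#' Modified Beer-Lambert inversion
#'
#' Converts optical-density changes at the two wavelengths into
#' concentration changes of oxygenated and deoxygenated haemoglobin by
#' solving, per channel and sample, the 2 x 2 linear system
#' `dOD(lambda) = (eps_HbO2(lambda) dHbO + eps_HHb(lambda) dHHb) * d * DPF`,
#' where `d` is the source-detector distance in cm and `DPF` the
#' participant's differential pathlength factor. Output concentrations are
#' expressed in molar x 1e-8. Total haemoglobin and the haemoglobin
#' difference are computed alongside.
#'
#' @param od an `od_series`
#' @param ext extinction table from [extinction_coefficients()]
#' @param dpf differential pathlength factor; defaults to
#'   [compute_dpf()] of the recording's age
#' @return list of class `hb_series` with matrices `hbo`, `hhb`, `hbt`,
#'   `hbdiff` (samples x channels, molar x 1e-8) and carried metadata
#' @export
mbll_invert <- function(od, ext = extinction_coefficients(od$wavelengths),
                        dpf = compute_dpf(od$age)) {
  E <- unname(ext[, c("HbO2", "HHb")])
  if (abs(det(E)) < 1e-6 * prod(sqrt(rowSums(E^2))))
    stop("mbll_invert: extinction matrix is (near) singular", call. = FALSE)
  Einv <- solve(E)
  nch <- dim(od$od)[2]
  nt <- dim(od$od)[1]
  d_cm <- od$montage$distance * 100
  hbo <- matrix(NA_real_, nt, nch)
  hhb <- matrix(NA_real_, nt, nch)
  for (ch in seq_len(nch)) {
    odl <- cbind(od$od[, ch, 1], od$od[, ch, 2]) / (d_cm[ch] * dpf)
    conc <- odl %*% t(Einv) # columns: HbO2, HHb in molar
    hbo[, ch] <- conc[, 1] * 1e8
    hhb[, ch] <- conc[, 2] * 1e8
  }
  colnames(hbo) <- colnames(hhb) <- od$montage$label
  structure(list(hbo = hbo, hhb = hhb, hbt = hbo + hhb, hbdiff = hbo - hhb,
                 fs = od$fs, time = od$time, events = od$events,
                 montage = od$montage, qc_passed = od$qc_passed,
                 participant_id = od$participant_id, group = od$group,
                 time_point = od$time_point),
            class = "hb_series")
}

#' Pointwise haemoglobin difference
#'
#' `HBdiff = O2Hb - HHb`, the composite activation index contrasting oxygen
#' supply and extraction.
#'
#' @param hbo,hhb aligned numeric arrays (molar x 1e-8)
#' @return array of the same shape
#' @export
hemoglobin_difference <- function(hbo, hhb) {
  stopifnot(length(hbo) == length(hhb))
  hbo - hhb
}

#' Block-average epochs around task events
#'
#' Extracts, per channel and condition, epochs in a window around each block
#' onset, subtracts each epoch's pre-stimulus baseline mean (window start to
#' 0 s), and averages epochs of the same condition. Epochs whose window
#' exceeds the recording are dropped with a warning.
#'
#' @param hb an `hb_series`
#' @param window epoch window relative to block onset, seconds (closed on
#'   the left, open on the right in samples)
#' @param measures which concentration series to average
#' @return list of class `block_average`: for each measure a 3-d array
#'   (window samples x channels x conditions), plus `time` (epoch time axis),
#'   `n_epochs` per condition and metadata
#' @export
block_average <- function(hb, window = c(-2, 45),
                          measures = c("hbo", "hhb", "hbt", "hbdiff")) {
  fs <- hb$fs
  pre <- round(-window[1] * fs)
  len <- round((window[2] - window[1]) * fs)
  conds <- sort(unique(hb$events$condition))
  nch <- ncol(hb$hbo)
  nt <- nrow(hb$hbo)
  epoch_time <- (seq_len(len) - 1) / fs + window[1]
  out <- list()
  n_epochs <- stats::setNames(integer(length(conds)), conds)
  for (m in measures) out[[m]] <- array(NA_real_, dim = c(len, nch, length(conds)),
                                        dimnames = list(NULL, colnames(hb$hbo), conds))
  for (ci in seq_along(conds)) {
    ev <- hb$events[hb$events$condition == conds[ci], ]
    for (m in measures) {
      acc <- matrix(0, len, nch)
      used <- 0
      for (k in seq_len(nrow(ev))) {
        onset_idx <- round(ev$onset[k] * fs) + 1
        i0 <- onset_idx - pre
        i1 <- i0 + len - 1
        if (i0 < 1 || i1 > nt) {
          warning(sprintf("block_average: epoch at %.1f s outside recording, dropped",
                          ev$onset[k]))
          next
        }
        ep <- hb[[m]][i0:i1, , drop = FALSE]
        bl <- colMeans(ep[seq_len(pre), , drop = FALSE])
        acc <- acc + sweep(ep, 2, bl)
        used <- used + 1
      }
      if (used == 0) next
      out[[m]][, , ci] <- acc / used
      n_epochs[ci] <- used
    }
  }
  structure(c(out, list(time = epoch_time, conditions = conds,
                        n_epochs = n_epochs, window = window,
                        montage = hb$montage, qc_passed = hb$qc_passed,
                        participant_id = hb$participant_id, group = hb$group,
                        time_point = hb$time_point)),
            class = "block_average")
}

#' Scalar channel summaries of a block average
#'
#' Reduces a block-averaged time course to one scalar per channel x
#' condition: the mean (default) or peak of the baseline-corrected response
#' over the task window (0 s to window end).
#'
#' @param ba a `block_average`
#' @param measure which concentration series to summarise
#' @param stat `"mean"` or `"peak"`
#' @param span summary window in seconds, default 0 to the window end
#' @return matrix channels x conditions
#' @export
channel_summary <- function(ba, measure = "hbdiff", stat = c("mean", "peak"),
                            span = c(0, ba$window[2])) {
  stat <- match.arg(stat)
  sel <- ba$time >= span[1] & ba$time < span[2]
  x <- ba[[measure]][sel, , , drop = FALSE]
  apply(x, c(2, 3), function(v) {
    if (all(is.na(v))) return(NA_real_)
    if (stat == "mean") mean(v) else v[which.max(abs(v))]
  })
}

#' z-score channel outlier filter
#'
#' Standardises scalar channel summaries across channels (within one
#' condition x time point cell) and flags channels whose |z| exceeds the
#' cut-off (3.29, the 99.95% standard-normal quantile, by default). Flagged
#' channels are excluded from ROI pooling.
#'
#' @param values numeric vector of per-channel summaries (NAs allowed)
#' @param cutoff z cut-off
#' @return logical vector, `TRUE` = outlier
#' @export
channel_outlier_filter <- function(values, cutoff = 3.29) {
  ok <- !is.na(values)
  if (sum(ok) < 3)
    stop("channel_outlier_filter: need at least 3 channels", call. = FALSE)
  s <- stats::sd(values[ok])
  if (s == 0) {
    warning("channel_outlier_filter: zero variance across channels, no exclusions")
    return(rep(FALSE, length(values)))
  }
  z <- (values - mean(values[ok])) / s
  out <- abs(z) > cutoff
  out[!ok] <- FALSE
  out
}

#' Run the full preprocessing chain on one recording
#'
#' Executes the fixed stage order: optical density, cardiac quality check,
#' wavelet motion correction, band-pass filter, Beer-Lambert inversion,
#' block averaging. Stages insist on this order; the returned object also
#' carries the per-channel scalar summaries used by the ROI stage.
#'
#' @param rec a `nirs_recording`
#' @param qc,motion_correction,bandpass stage toggles
#' @param iqr_factor wavelet outlier threshold (x IQR)
#' @param low,high band-pass cut-offs, Hz
#' @param window block-average window, seconds
#' @param summary_stat scalar summary statistic (`"mean"` or `"peak"`)
#' @return list with the `block_average`, the `hb_series`, per-channel
#'   `summary` (channels x conditions, QC-dropped channels set `NA`),
#'   `qc_passed`, and the fraction of channels dropped by QC
#' @export
preprocess_recording <- function(rec, qc = TRUE, motion_correction = TRUE,
                                 bandpass = TRUE, iqr_factor = 0.1,
                                 low = 0.01, high = 0.08, window = c(-2, 45),
                                 summary_stat = "mean") {
  od <- intensity_to_od(rec)
  if (qc) od <- cardiac_quality_check(od)
  if (motion_correction) od <- wavelet_motion_correct(od, iqr_factor = iqr_factor)
  if (bandpass) od <- bandpass_filter(od, low = low, high = high)
  hb <- mbll_invert(od)
  ba <- block_average(hb, window = window)
  smry <- channel_summary(ba, stat = summary_stat)
  if (!is.null(od$qc_passed)) smry[!od$qc_passed, ] <- NA_real_
  list(block_average = ba, hb = hb, summary = smry,
       qc_passed = od$qc_passed,
       qc_drop_rate = if (is.null(od$qc_passed)) NA_real_
                      else mean(!od$qc_passed))
}
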