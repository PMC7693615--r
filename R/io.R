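#' Write / read a recording as a SNIRF-style JSON container
#'
#' Serialises a `nirs_recording` to a JSON file whose structure mirrors the
#' SNIRF field hierarchy (`nirs/data`, `nirs/stim`, `nirs/probe`,
#' `metaDataTags`): intensity time series with per-column source/detector/
#' wavelength indices, stimulus blocks with onset/duration/condition, and
#' participant metadata. The round trip is lossless for every field the
#' pipeline consumes.
#'
#' @param rec a `nirs_recording`
#' @param path output path (`.json`)
#' @return `read_snirf` returns the reconstructed `nirs_recording`
#' @export
write_snirf <- function(rec, path) {
  nch <- dim(rec$intensity)[2]
  ml <- do.call(rbind, lapply(seq_len(nch), function(ch) {
    data.frame(channel = ch, source = rec$montage$source[ch],
               detector = rec$montage$detector[ch],
               label = rec$montage$label[ch],
               stringsAsFactors = FALSE)
  }))
  obj <- list(
    formatVersion = "1.0-json",
    nirs = list(
      metaDataTags = list(
        participant_id = rec$participant_id, age = rec$age,
        group = rec$group, time_point = rec$time_point,
        SamplingRate = rec$fs
      ),
      data = list(
        time = rec$time,
        measurementList = ml,
        wavelengths = rec$wavelengths,
        # samples x channels, one block per wavelength
        dataTimeSeries = lapply(1:2, function(w) rec$intensity[, , w])
      ),
      stim = rec$events,
      probe = rec$montage
    )
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_snirf
#' @export
read_snirf <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$nirs$data$dataTimeSeries))
    stop("read_snirf: not a SNIRF-style container (missing dataTimeSeries): ",
         path, call. = FALSE)
  dts <- obj$nirs$data$dataTimeSeries
  # jsonlite may simplify the two equally-shaped blocks into one 3-d array
  if (is.array(dts) && length(dim(dts)) == 3) {
    dts <- lapply(seq_len(dim(dts)[1]), function(w) dts[w, , ])
  }
  if (!is.list(dts) || length(dts) != 2)
    stop("read_snirf: expected two wavelength blocks in ", path, call. = FALSE)
  montage <- as.data.frame(obj$nirs$probe)
  nt <- length(obj$nirs$data$time)
  nch <- nrow(montage)
  intensity <- array(NA_real_, dim = c(nt, nch, 2),
                     dimnames = list(NULL, montage$label,
                                     paste0("wl", obj$nirs$data$wavelengths)))
  for (w in 1:2) {
    m <- as.matrix(dts[[w]])
    if (!all(dim(m) == c(nt, nch)))
      stop("read_snirf: wavelength block ", w, " has wrong shape in ", path,
           call. = FALSE)
    intensity[, , w] <- m
  }
  md <- obj$nirs$metaDataTags
  structure(list(
    fs = md$SamplingRate, wavelengths = obj$nirs$data$wavelengths,
    time = obj$nirs$data$time, intensity = intensity,
    events = as.data.frame(obj$nirs$stim), montage = montage,
    age = md$age, participant_id = md$participant_id,
    group = md$group, time_point = md$time_point
  ), class = "nirs_recording")
}

#' Write / read behavioral trial tables
#'
#' Delimited (tab-separated) trial tables, one row per trial. On reading,
#' the condition labels are validated against the known set.
#'
#' @param trials trial table
#' @param path file path
#' @return `read_trials` returns the trial table
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  t <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("participant_id", "time_point", "condition", "block", "trial",
            "is_target", "response", "rt")
  miss <- setdiff(need, names(t))
  if (length(miss) > 0)
    stop("read_trials: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  known <- c("0-back", "1-back", "2-back")
  bad <- which(!t$condition %in% known)
  if (length(bad) > 0)
    stop("read_trials: unknown condition label '", t$condition[bad[1]],
         "' in row ", bad[1], call. = FALSE)
  t
}

#' Serialise ground truth next to a dataset
#' @param truth ground-truth list from [generate_nirs_recording()]
#' @param path output path (`.json`)
#' @export
write_ground_truth <- function(truth, path) {
  slim <- list(amplitude = truth$amplitude, roi_effects = as.list(truth$roi_effects),
               spikes = truth$spikes, shifts = truth$shifts)
  jsonlite::write_json(slim, path, digits = NA, auto_unbox = TRUE, null = "list")
  invisible(path)
}
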