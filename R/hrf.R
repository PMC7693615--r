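#' Canonical double-gamma hemodynamic response function
#'
#' Evaluates the canonical haemodynamic impulse response used throughout the
#' simulator: a positive gamma density peaking at \code{peak_time} minus a
#' scaled gamma density peaking at \code{undershoot_time}. Both gamma terms
#' use a dispersion of 1 s, so the shape parameter equals the peak time + 1.
#' The curve is normalised so that its maximum over \code{t >= 0} is 1.
#'
#' @param t time in seconds (vector, all `>= 0`)
#' @param peak_time time-to-peak of the positive lobe, seconds
#' @param undershoot_time time-to-peak of the undershoot lobe, seconds
#' @param undershoot_ratio ratio of undershoot to peak amplitude (`1/6` is
#'   the usual convention; `0` disables the undershoot)
#' @return numeric vector of unitless amplitudes, peak value 1
#' @examples
#' tt <- seq(0, 30, by = 0.1)
#' h <- canonical_hrf(tt)
#' tt[which.max(h)] # ~6 s
#' @export
canonical_hrf <- function(t, peak_time = 6, undershoot_time = 16,
                          undershoot_ratio = 1 / 6) {
  if (any(t < 0)) stop("canonical_hrf: t must be >= 0", call. = FALSE)
  if (peak_time <= 0 || undershoot_time <= 0 || undershoot_ratio < 0)
    stop("canonical_hrf: shape parameters must be positive", call. = FALSE)
  if (peak_time >= undershoot_time)
    stop("canonical_hrf: peak_time must precede undershoot_time", call. = FALSE)
  # gamma density with rate 1 peaks at shape - 1, so shape = peak + 1
  h <- function(x) {
    stats::dgamma(x, shape = peak_time + 1, rate = 1) -
      undershoot_ratio * stats::dgamma(x, shape = undershoot_time + 1, rate = 1)
  }
  pk <- stats::optimize(h, c(0, undershoot_time), maximum = TRUE)$objective
  h(t) / pk
}

#' n-back task block schedule
#'
#' Builds the timing of one n-back session: 6 task blocks of 45 s (two per
#' load condition), separated by 27 s rests between consecutive blocks, for
#' a total task duration of 6 x 45 + 5 x 27 = 405 s (6:45 min). Condition
#' order is randomised when a seed is given; with `randomize = FALSE` the
#' fixed order 0-back, 1-back, 2-back, 0-back, 1-back, 2-back is used.
#'
#' @param randomize randomise the order of the six blocks
#' @param seed optional integer seed used only for the block order
#' @return data.frame with columns `block` (1-6), `condition`
#'   (`"0-back"`, `"1-back"`, `"2-back"`), `onset` and `duration` in seconds
#' @export
nback_schedule <- function(randomize = TRUE, seed = NULL) {
  conditions <- rep(c("0-back", "1-back", "2-back"), times = 2)
  if (randomize) {
    if (!is.null(seed)) {
      conditions <- withr_seed(seed, sample(conditions))
    } else {
      conditions <- sample(conditions)
    }
  }
  block_dur <- 45
  rest_dur <- 27
  onsets <- (seq_along(conditions) - 1) * (block_dur + rest_dur)
  data.frame(
    block = seq_along(conditions),
    condition = conditions,
    onset = onsets,
    duration = block_dur,
    stringsAsFactors = FALSE
  )
}

#' Total duration of the n-back task in seconds
#' @param schedule a schedule from [nback_schedule()]
#' @return scalar seconds (405 for the default schedule)
#' @export
task_duration <- function(schedule = nback_schedule(randomize = FALSE)) {
  max(schedule$onset + schedule$duration)
}

#' Evoked concentration regressor for a schedule
#'
#' Convolves the boxcar of the selected blocks with the canonical HRF and
#' rescales so the maximum equals 1 (an amplitude parameter then maps the
#' regressor to molar concentration change).
#'
#' @param time sample times in seconds
#' @param schedule block schedule (see [nback_schedule()])
#' @param conditions which conditions contribute; default all
#' @param weights named condition weights applied to the boxcar
#' @param fs sampling rate in Hz, used for the convolution grid
#' @param ... passed to [canonical_hrf()]
#' @return numeric vector aligned with `time`, max 1 (if any block selected)
#' @export
hrf_regressor <- function(time, schedule, conditions = unique(schedule$condition),
                          weights = NULL, fs = 3.47, ...) {
  box <- numeric(length(time))
  for (i in seq_len(nrow(schedule))) {
    if (!schedule$condition[i] %in% conditions) next
    w <- 1
    if (!is.null(weights) && schedule$condition[i] %in% names(weights))
      w <- weights[[schedule$condition[i]]]
    idx <- time >= schedule$onset[i] & time < schedule$onset[i] + schedule$duration[i]
    box[idx] <- box[idx] + w
  }
  kern <- canonical_hrf(seq(0, 32, by = 1 / fs), ...)
  r <- stats::convolve(box, rev(kern), type = "open")[seq_along(box)] / fs
  m <- max(r)
  if (m > 0) r / m else r
}

# Evaluate an expression under a temporary RNG state restored afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
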