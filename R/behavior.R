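#' Apply trial filters to a raw trial table
#'
#' Marks the first two trials of every 15-trial block as discarded (in the
#' 2-back condition they are necessarily non-match trials), classifies
#' responses with RT < 200 ms as premature and trials without a response
#' inside the 2000 ms window as omissions (both count as errors), and
#' classifies the remaining trials as correct or wrong-key. After filtering,
#' 26 analysable trials remain per condition and time point. The operation
#' is idempotent.
#'
#' @param trials trial table (see [generate_behavioral_session()])
#' @param rt_min,rt_max premature/omission RT bounds, ms
#' @return the table with added `discarded` and `error_class` columns
#' @export
filter_trials <- function(trials, rt_min = 200, rt_max = 2000) {
  counts <- table(trials$participant_id, trials$time_point,
                  trials$condition, trials$block)
  if (any(counts[counts > 0] != 15))
    stop("filter_trials: malformed block (expected 15 trials per block)",
         call. = FALSE)
  trials$discarded <- trials$trial %in% c(1, 2)
  responded <- trials$response != "none" & !is.na(trials$rt)
  cls <- rep("omission", nrow(trials))
  cls[responded & trials$rt < rt_min] <- "premature"
  cls[responded & trials$rt >= rt_min & trials$rt <= rt_max &
        trials$correct] <- "correct"
  cls[responded & trials$rt >= rt_min & trials$rt <= rt_max &
        !trials$correct] <- "wrong-key"
  cls[responded & trials$rt > rt_max] <- "omission"
  trials$correct[cls != "correct"] <- FALSE
  trials$error_class <- cls
  trials
}

#' Binomial inclusion threshold
#'
#' Smallest number of correct responses `k` such that the
#' `Binomial(n_trials, p)` distribution function at `k` reaches the given
#' quantile. Participants scoring below this threshold in the low-load
#' condition at pretest perform indistinguishably from guessing and are
#' excluded. With the defaults (26 trials, p = 0.5, 99% quantile) the
#' threshold is 19 correct responses (73%).
#'
#' @param n_trials number of analysable trials
#' @param p guessing probability
#' @param quantile required CDF level
#' @return integer threshold
#' @export
inclusion_threshold <- function(n_trials = 26, p = 0.5, quantile = 0.99) {
  stopifnot(n_trials >= 1, p > 0, p < 1, quantile > 0, quantile < 1)
  as.integer(stats::qbinom(quantile, n_trials, p))
}

#' Rate-correct score of one filtered trial set
#'
#' `RCS = n_correct / sum(RT)` over all responded trials (correct and
#' incorrect), with RTs in seconds: the number of correct responses per
#' second of responding. Omissions contribute to neither numerator nor
#' denominator; premature keypresses are responses and enter the
#' denominator (and count as errors).
#'
#' @param trials a filtered trial table (one participant, condition and
#'   time point; discarded trials are ignored)
#' @return list: `rcs`, `n_valid`, `n_correct`, `n_responded`, `accuracy`
#'   (over the non-discarded trials), `mean_rt` (ms, correct trials),
#'   `defined` (`FALSE` when no trial carries an RT)
#' @export
compute_rcs <- function(trials) {
  if (is.null(trials$error_class))
    stop("compute_rcs: trials must be filtered first (see filter_trials)",
         call. = FALSE)
  t <- trials[!trials$discarded, , drop = FALSE]
  responded <- t$error_class %in% c("correct", "wrong-key", "premature")
  n_correct <- sum(t$error_class == "correct")
  rt_sum_s <- sum(t$rt[responded]) / 1000
  defined <- sum(responded) > 0
  list(
    rcs = if (defined) n_correct / rt_sum_s else NA_real_,
    n_valid = nrow(t),
    n_correct = n_correct,
    n_responded = sum(responded),
    accuracy = n_correct / nrow(t),
    mean_rt = if (n_correct > 0) mean(t$rt[t$error_class == "correct"]) else NA_real_,
    defined = defined
  )
}

#' Score a session table into per-cell records
#'
#' Applies [filter_trials()] (if not already applied) and [compute_rcs()]
#' for every participant x time point x condition cell.
#'
#' @param trials raw or filtered trial table
#' @return data.frame of score records
#' @export
score_trials <- function(trials) {
  if (is.null(trials$error_class)) trials <- filter_trials(trials)
  cells <- unique(trials[, c("participant_id", "time_point", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- trials$participant_id == cells$participant_id[i] &
      trials$time_point == cells$time_point[i] &
      trials$condition == cells$condition[i]
    s <- compute_rcs(trials[sel, ])
    data.frame(cells[i, ], n_valid = s$n_valid, n_correct = s$n_correct,
               accuracy = s$accuracy, mean_rt = s$mean_rt, rcs = s$rcs,
               defined = s$defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' z-score outlier exclusion across participants
#'
#' Standardises a vector of scores (one condition x time point cell across
#' participants) and flags values with |z| above the cut-off. The default
#' cut-off 3.29 is the two-sided 99.95% standard-normal quantile.
#'
#' @param values numeric scores
#' @param cutoff z cut-off
#' @return logical exclusion mask
#' @export
zscore_exclude <- function(values, cutoff = 3.29) {
  ok <- !is.na(values)
  if (sum(ok) < 3)
    stop("zscore_exclude: need at least 3 values", call. = FALSE)
  s <- stats::sd(values[ok])
  if (s == 0) {
    warning("zscore_exclude: zero variance, no exclusions")
    return(rep(FALSE, length(values)))
  }
  z <- (values - mean(values[ok])) / s
  out <- abs(z) > cutoff
  out[!ok] <- FALSE
  out
}

#' Apply the study's participant- and cell-level exclusion rules
#'
#' Flags (a) participants whose pretest 1-back correct count falls below the
#' binomial inclusion threshold (participant-level exclusion from all
#' analyses) and (b) individual score cells whose rate-correct score is a
#' z-outlier within its condition x time point cell.
#'
#' @param scores score table from [score_trials()]
#' @param threshold correct-response threshold (see [inclusion_threshold()])
#' @param z_cutoff outlier cut-off
#' @return the score table with `included` and `excluded_reason` columns
#' @export
apply_exclusions <- function(scores, threshold = inclusion_threshold(),
                             z_cutoff = 3.29) {
  scores$included <- TRUE
  scores$excluded_reason <- "none"
  pre1 <- scores[scores$time_point == "pre" & scores$condition == "1-back", ]
  bad_pp <- pre1$participant_id[pre1$n_correct < threshold]
  sel <- scores$participant_id %in% bad_pp
  scores$included[sel] <- FALSE
  scores$excluded_reason[sel] <- "inclusion-criterion"
  for (tp in unique(scores$time_point)) {
    for (cond in unique(scores$condition)) {
      cell <- scores$time_point == tp & scores$condition == cond &
        scores$included
      if (sum(cell) < 3) next
      out <- zscore_exclude(scores$rcs[cell], cutoff = z_cutoff)
      idx <- which(cell)[out]
      scores$included[idx] <- FALSE
      scores$excluded_reason[idx] <- "z-outlier"
    }
  }
  scores
}
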