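#' Default behavioral specification
#'
#' Per (group x time x condition) generative parameters for the n-back
#' simulator. The 2-back accuracy and mean reaction-time cells reproduce the
#' reported sample means of a pre/post exercise cohort (experimental and
#' control groups at pre, post 15, post 30 and post 45 min); the 0-back and
#' 1-back cells use realistic near-ceiling values. Between-subject spread is
#' expressed through `acc_sd` (on the logit scale) and `rt_sd` (ms, SD of
#' per-subject mean RT); trial-level RT variability is log-normal with
#' coefficient of variation `rt_cv`.
#'
#' @return data.frame with columns `group`, `time_point`, `condition`,
#'   `accuracy`, `rt_mean` (ms), `omission_p`, `premature_p`
#' @export
default_behavior_spec <- function() {
  tp <- c("pre", "post15", "post30", "post45")
  acc2 <- list(
    experimental = c(0.8462, 0.9170, 0.8887, 0.9170),
    control = c(0.8662, 0.8846, 0.8880, 0.8930)
  )
  rt2 <- list(
    experimental = c(837.34, 788.38, 809.00, 796.57),
    control = c(885.07, 857.52, 847.58, 846.37)
  )
  rows <- list()
  for (g in c("experimental", "control")) {
    for (i in seq_along(tp)) {
      rows[[length(rows) + 1]] <- data.frame(
        group = g, time_point = tp[i],
        condition = c("0-back", "1-back", "2-back"),
        accuracy = c(0.97, 0.94, acc2[[g]][i]),
        rt_mean = c(600, 700, rt2[[g]][i]),
        omission_p = c(0.01, 0.015, 0.02),
        premature_p = c(0.005, 0.005, 0.005),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Generate one n-back behavioral session
#'
#' Simulates the trial table of a single session: 3 load conditions x 2
#' blocks x 15 trials (exactly 5 targets per block), with stimulus onsets
#' built from a 500 ms stimulus, a 1500 ms response interval and a uniform
#' 800-1200 ms onset jitter. Responses are drawn from the behavioral
#' specification cell for (`group`, `time_point`, condition): a trial is an
#' omission with probability `omission_p`, a premature keypress (RT < 200
#' ms) with probability `premature_p`, and otherwise correct with the cell's
#' accuracy. Response times are log-normal around the cell mean (truncated
#' at the 2000 ms response window).
#'
#' @param group `"experimental"` or `"control"`
#' @param time_point one of `"pre"`, `"post15"`, `"post30"`, `"post45"`
#' @param participant_id identifier copied into the table
#' @param behavior_spec see [default_behavior_spec()]
#' @param acc_shift per-subject accuracy offset on the logit scale
#' @param rt_shift per-subject multiplicative RT offset (log scale)
#' @param rt_cv trial-level RT coefficient of variation
#' @param seed integer seed; identical seeds give identical tables
#' @return a trial table: `participant_id`, `time_point`, `condition`,
#'   `block`, `trial`, `onset` (s), `is_target`, `response`
#'   (`"match"`/`"non-match"`/`"none"`), `rt` (ms, `NA` for omissions),
#'   `correct`
#' @export
generate_behavioral_session <- function(group, time_point, participant_id = "P01",
                                        behavior_spec = default_behavior_spec(),
                                        acc_shift = 0, rt_shift = 0,
                                        rt_cv = 0.25, seed = NULL) {
  tps <- unique(behavior_spec$time_point)
  if (!time_point %in% tps)
    stop("generate_behavioral_session: unknown time_point '", time_point, "'",
         call. = FALSE)
  if (!group %in% unique(behavior_spec$group))
    stop("generate_behavioral_session: unknown group '", group, "'",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  schedule <- nback_schedule(randomize = TRUE)
  out <- list()
  block_within <- stats::setNames(rep(0, 3), c("0-back", "1-back", "2-back"))
  for (b in seq_len(nrow(schedule))) {
    cond <- schedule$condition[b]
    block_within[cond] <- block_within[cond] + 1
    spec <- behavior_spec[behavior_spec$group == group &
                            behavior_spec$time_point == time_point &
                            behavior_spec$condition == cond, ]
    stopifnot(nrow(spec) == 1)
    acc <- stats::plogis(stats::qlogis(spec$accuracy) + acc_shift)

    n_tr <- 15
    # n-back targets need n preceding trials; keep targets off the first two
    target_pos <- sort(sample(3:n_tr, 5))
    is_target <- seq_len(n_tr) %in% target_pos

    jitter <- stats::runif(n_tr, 0.8, 1.2)
    trial_dur <- 0.5 + 1.5 + jitter
    onsets <- schedule$onset[b] + c(0, cumsum(trial_dur[-n_tr]))

    omit <- stats::runif(n_tr) < spec$omission_p
    premature <- !omit & stats::runif(n_tr) < spec$premature_p
    correct <- !omit & !premature & stats::runif(n_tr) < acc

    mu <- spec$rt_mean * exp(rt_shift)
    sdlog <- sqrt(log(1 + rt_cv^2))
    meanlog <- log(mu) - sdlog^2 / 2
    rt <- stats::rlnorm(n_tr, meanlog, sdlog)
    rt <- pmin(rt, 1999) # truncate at the response window
    rt <- pmax(rt, 200)
    rt[premature] <- stats::runif(sum(premature), 50, 199)
    rt[omit] <- NA_real_

    response <- ifelse(omit, "none",
                       ifelse(correct == is_target, "match", "non-match"))
    # a premature keypress is a guess: random key
    guess <- stats::runif(n_tr) < 0.5
    response[premature] <- ifelse(guess[premature], "match", "non-match")
    correct[premature] <- (response[premature] == "match") == is_target[premature]

    out[[b]] <- data.frame(
      participant_id = participant_id,
      time_point = time_point,
      condition = cond,
      block = block_within[[cond]],
      trial = seq_len(n_tr),
      onset = onsets,
      is_target = is_target,
      response = response,
      rt = rt,
      correct = correct & !omit,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Simulate a cohort of rate-correct scores
#'
#' Draws per-participant rate-correct scores (RCS) for the 2 x 4
#' group-by-time design directly from cell means and standard errors, with a
#' compound-symmetric within-subject correlation across the four time
#' points. This is the generator used to study the inference stage under
#' the published summary statistics.
#'
#' @param means matrix 2 x 4 (rows `experimental`, `control`; columns `pre`,
#'   `post15`, `post30`, `post45`) of cell means
#' @param ses matrix of the same shape holding standard errors of the mean
#' @param n named vector of simulated group sizes,
#'   e.g. `c(experimental = 19, control = 23)`
#' @param n_ref group sizes the standard errors refer to; the between-subject
#'   SD is `se * sqrt(n_ref)` regardless of how many subjects are simulated
#' @param rho within-subject correlation between time points (default 0.8)
#' @param seed integer seed
#' @return long data.frame: `participant`, `group`, `time_point`, `rcs`
#' @export
simulate_rcs_cohort <- function(means = rcs_table_means(),
                                ses = rcs_table_ses(),
                                n = c(experimental = 19, control = 23),
                                n_ref = c(experimental = 19, control = 23),
                                rho = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tp <- colnames(means)
  rows <- list()
  pid <- 0
  for (g in rownames(means)) {
    sds <- ses[g, ] * sqrt(n_ref[[g]])
    R <- matrix(rho, 4, 4)
    diag(R) <- 1
    S <- diag(sds) %*% R %*% diag(sds)
    y <- MASS::mvrnorm(n[[g]], mu = as.numeric(means[g, ]), Sigma = S)
    for (i in seq_len(n[[g]])) {
      pid <- pid + 1
      rows[[pid]] <- data.frame(
        participant = sprintf("P%03d", pid), group = g,
        time_point = tp, rcs = as.numeric(y[i, ]),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  tab$group <- factor(tab$group, levels = rownames(means))
  tab$time_point <- factor(tab$time_point, levels = tp)
  rownames(tab) <- NULL
  tab
}

#' Published 2-back rate-correct score cell means and standard errors
#'
#' Cell means (and, via [rcs_table_ses()], standard errors) of the
#' 2 (group) x 4 (time) design for the 2-back rate-correct score, used as
#' the default generating values of [simulate_rcs_cohort()].
#' @return 2 x 4 numeric matrix
#' @export
rcs_table_means <- function() {
  matrix(c(1.05, 1.24, 1.15, 1.22,
           1.05, 1.12, 1.13, 1.13),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("experimental", "control"),
                         c("pre", "post15", "post30", "post45")))
}

#' @rdname rcs_table_means
#' @export
rcs_table_ses <- function() {
  matrix(c(0.05, 0.08, 0.06, 0.07,
           0.07, 0.07, 0.07, 0.07),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("experimental", "control"),
                         c("pre", "post15", "post30", "post45")))
}
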