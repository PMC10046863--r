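#' Default single-trial phase schedule of the gambling paradigm
#'
#' Durations in seconds of the five phases of one trial: door choice, gaze
#' point, feedback arrow, cumulative-score display, inter-trial break.
#' The choice window is 4 s so that 80 trials of 14 s fill the 18 min 40 s
#' task block exactly.
#'
#' @return Named numeric vector of phase durations (seconds).
#' @export
default_trial_schedule <- function() {
  c(choice = 4, gaze = 2, feedback = 2, score = 2, rest = 4)
}

#' Generate a binary stimulus timecourse at fMRI volume resolution
#'
#' Builds the paradigm regressor used by the similarity indicator: a volume
#' is marked 1 when its acquisition interval `[t, t + TR)` overlaps the
#' feedback-arrow phase of a trial whose outcome matches `condition`, and 0
#' otherwise. Trial outcomes (win/lose) are drawn independently with
#' probability `p_win`.
#'
#' @param n_trials Number of trials (80 in the emulated paradigm).
#' @param schedule Named numeric vector of phase durations in seconds; must
#'   contain a `feedback` phase. See [default_trial_schedule()].
#' @param TR fMRI repetition time in seconds.
#' @param condition Which trials mark the timecourse: `"win"`, `"lose"` or
#'   `"both"`.
#' @param p_win Probability that a trial is a win.
#' @param seed Integer seed; outcomes are reproducible for a fixed seed.
#' @return An object of class `stimulus_timecourse`: list with `values`
#'   (binary vector, one entry per volume), `condition`, `TR`, `wins`
#'   (logical per trial), `schedule`, `seed`.
#' @export
generate_stimulus_timecourse <- function(n_trials,
                                         schedule = default_trial_schedule(),
                                         TR = 2,
                                         condition = c("both", "win", "lose"),
                                         p_win = 0.5,
                                         seed = 1L) {
  condition <- match.arg(condition)
  if (!is.numeric(n_trials) || n_trials <= 0 || n_trials != round(n_trials)) {
    stop("n_trials must be a positive integer")
  }
  if (!is.numeric(TR) || TR <= 0) stop("TR must be positive")
  if (!("feedback" %in% names(schedule))) {
    stop("schedule must contain a 'feedback' phase")
  }
  if (any(schedule < 0)) stop("phase durations must be nonnegative")
  trial_len <- sum(schedule)
  total <- n_trials * trial_len
  n_vol <- total / TR
  if (abs(n_vol - round(n_vol)) > 1e-9) {
    stop("task length must be an integer number of volumes (n_trials * trial length / TR)")
  }
  n_vol <- as.integer(round(n_vol))

  wins <- with_seed(seed, stats::runif(n_trials) < p_win)
  phase_start <- cumsum(c(0, schedule))[seq_along(schedule)]
  names(phase_start) <- names(schedule)
  fb_off <- phase_start[["feedback"]]
  fb_dur <- schedule[["feedback"]]

  values <- integer(n_vol)
  for (i in seq_len(n_trials)) {
    keep <- switch(condition,
      both = TRUE,
      win  = wins[i],
      lose = !wins[i]
    )
    if (!keep) next
    a <- (i - 1) * trial_len + fb_off      # feedback phase [a, b)
    b <- a + fb_dur
    # volumes whose window [t, t + TR) overlaps [a, b)
    v <- which(seq_len(n_vol) * TR > a & (seq_len(n_vol) - 1L) * TR < b)
    values[v] <- 1L
  }
  structure(
    list(values = values, condition = condition, TR = TR, wins = wins,
         schedule = schedule, n_trials = as.integer(n_trials), seed = seed),
    class = "stimulus_timecourse"
  )
}

#' @export
print.stimulus_timecourse <- function(x, ...) {
  cat(sprintf(
    "<stimulus_timecourse> %d volumes (TR = %g s), %d trials, condition '%s', %d marked\n",
    length(x$values), x$TR, x$n_trials, x$condition, sum(x$values)
  ))
  invisible(x)
}

# Validate that an object is a usable binary stimulus of length n.
check_stimulus <- function(stim, n = NULL) {
  if (!inherits(stim, "stimulus_timecourse")) stop("not a stimulus_timecourse")
  if (!all(stim$values %in% c(0L, 1L))) stop("stimulus values must be binary")
  if (!is.null(n) && length(stim$values) != n) {
    stop(sprintf("stimulus length %d does not match %d time points",
                 length(stim$values), n))
  }
  invisible(stim)
}
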