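#' Degree-of-freedom labels
#'
#' The eight hand/wrist degrees of freedom (DOFs) tracked throughout:
#' flexion/extension of digits D1-D5, abduction/adduction of D1, wrist
#' flexion/extension and wrist pronation/supination. Positive normalized
#' values denote flexion/pronation/abduction, negative values
#' extension/supination/adduction.
#'
#' @return Character vector of length 8 naming the DOFs in canonical order.
#' @export
dof_names <- function() {
  c("d1_flex", "d2_flex", "d3_flex", "d4_flex", "d5_flex",
    "d1_abad", "wrist_flex", "wrist_rot")
}

N_DOF <- 8L

movement_spec <- function(id, target_dofs, direction, is_combination = FALSE) {
  stopifnot(length(target_dofs) >= 1L,
            length(direction) == length(target_dofs),
            all(direction %in% c(-1, 1)))
  if (is_combination && length(target_dofs) < 2L)
    stop("combination movements need at least 2 target DOFs")
  if (!is_combination && length(target_dofs) != 1L)
    stop("individuated movements have exactly 1 target DOF")
  structure(list(id = id, target_dofs = as.integer(target_dofs),
                 direction = as.numeric(direction),
                 is_combination = isTRUE(is_combination)),
            class = "movement_spec")
}

#' Movement sets for the two collection protocols
#'
#' `"biomech"` is the 18-movement set used for the biomechanical analysis:
#' individuated flexion and extension of D1-D5, wrist flexion/extension,
#' wrist pronation/supination, D1 abduction/adduction, plus two combination
#' movements (power grasp = simultaneous D1-D5 flexion; hand open =
#' simultaneous D1-D5 extension). `"ml"` is the 14-movement individuated set
#' used for the offline machine-learning sessions (no combination movements).
#'
#' @param protocol `"biomech"` or `"ml"`.
#' @return A named list of movement specifications.
#' @export
movement_set <- function(protocol = c("biomech", "ml")) {
  protocol <- match.arg(protocol)
  digits <- 1:5
  mk_digit <- function(d, dir) {
    suf <- if (dir > 0) "flex" else "ext"
    movement_spec(sprintf("d%d_%s", d, suf), d, dir)
  }
  base <- list()
  n_digits <- if (protocol == "biomech") 5L else 4L
  for (d in seq_len(n_digits)) {
    base[[length(base) + 1L]] <- mk_digit(d, +1)
    base[[length(base) + 1L]] <- mk_digit(d, -1)
  }
  base[[length(base) + 1L]] <- movement_spec("wrist_flex", 7L, +1)
  base[[length(base) + 1L]] <- movement_spec("wrist_ext", 7L, -1)
  base[[length(base) + 1L]] <- movement_spec("wrist_pro", 8L, +1)
  base[[length(base) + 1L]] <- movement_spec("wrist_sup", 8L, -1)
  base[[length(base) + 1L]] <- movement_spec("d1_ab", 6L, +1)
  base[[length(base) + 1L]] <- movement_spec("d1_ad", 6L, -1)
  if (protocol == "biomech") {
    base[[length(base) + 1L]] <-
      movement_spec("power_grasp", digits, rep(+1, 5), is_combination = TRUE)
    base[[length(base) + 1L]] <-
      movement_spec("hand_open", digits, rep(-1, 5), is_combination = TRUE)
  }
  names(base) <- vapply(base, `[[`, "", "id")
  base
}

#' Trial timing parameters
#'
#' @param ramp_s Ramp duration away from (and back to) rest, seconds.
#' @param hold_s Hold time at maximum deviation, seconds.
#' @param intertrial_s Rest between successive trials, seconds.
#' @param kinematic_rate_hz Kinematic sampling rate, samples/s.
#' @param emg_rate_hz Raw EMG sampling rate, samples/s.
#' @return A `trial_timing` object.
#' @export
trial_timing <- function(ramp_s = 0.7, hold_s = 0.1, intertrial_s = 1.0,
                         kinematic_rate_hz = 30, emg_rate_hz = 1000) {
  vals <- c(ramp_s, hold_s, intertrial_s, kinematic_rate_hz, emg_rate_hz)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all timing parameters must be positive and finite")
  structure(list(ramp_s = ramp_s, hold_s = hold_s, intertrial_s = intertrial_s,
                 kinematic_rate_hz = kinematic_rate_hz,
                 emg_rate_hz = emg_rate_hz),
            class = "trial_timing")
}

trial_duration_s <- function(timing) {
  2 * timing$ramp_s + timing$hold_s + timing$intertrial_s
}

#' Build a trial schedule for one training session
#'
#' Enumerates the protocol's movement set and repeats each movement `reps`
#' times consecutively before progressing to the next movement.
#'
#' @param protocol `"biomech"` (18 movements) or `"ml"` (14 movements).
#' @param reps Repetitions per movement (>= 1).
#' @param timing A [trial_timing()] object.
#' @param session_id Label attached to the session.
#' @return A `trial_schedule` with `movements`, a `trials` data frame
#'   (`trial`, `movement_id`, `rep`), and `timing`.
#' @export
build_schedule <- function(protocol = c("biomech", "ml"), reps = 10,
                           timing = trial_timing(), session_id = "s1") {
  protocol <- match.arg(protocol)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1 || reps != round(reps))
    stop("reps must be a single integer >= 1")
  reps <- as.integer(reps)
  movements <- movement_set(protocol)
  trials <- data.frame(
    trial = seq_len(length(movements) * reps),
    movement_id = rep(names(movements), each = reps),
    rep = rep(seq_len(reps), times = length(movements)),
    stringsAsFactors = FALSE
  )
  structure(list(protocol = protocol, movements = movements, trials = trials,
                 timing = timing, session_id = session_id),
            class = "trial_schedule")
}

n_trials <- function(schedule) nrow(schedule$trials)

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule '%s'> protocol=%s: %d movements x %d reps = %d trials (%.1f s)\n",
              x$session_id, x$protocol, length(x$movements),
              max(x$trials$rep), n_trials(x),
              n_trials(x) * trial_duration_s(x$timing)))
  invisible(x)
}
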