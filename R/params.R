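#' Construct a surrogate muscle-synergy gain pattern
#'
#' Maps rectified joint angles to per-channel EMG envelope. Each DOF drives a
#' contiguous band of electrodes for flexion and a shifted band for
#' extension, with a small crosstalk gain on the neighbouring channels --
#' a deterministic stand-in for the spatially localized (but overlapping)
#' muscle activity seen under a multi-electrode sleeve.
#'
#' @param n_channels Number of EMG channels (default 32).
#' @param gain Peak envelope gain of a driven channel.
#' @param crosstalk Gain on channels adjacent to a driven band.
#' @return List with nonnegative `pos` and `neg` matrices (n_channels x 8).
#' @export
make_synergy <- function(n_channels = 32, gain = 1, crosstalk = 0.1) {
  stopifnot(n_channels >= N_DOF, gain >= 0, crosstalk >= 0)
  band <- function(offset) {
    g <- matrix(0, n_channels, N_DOF)
    w <- max(1L, n_channels %/% N_DOF)
    for (d in seq_len(N_DOF)) {
      ch <- ((d - 1L) * w + offset + seq_len(w) - 1L) %% n_channels + 1L
      g[ch, d] <- gain
      nb <- (range(ch) + c(-1L, 1L) - 1L) %% n_channels + 1L
      g[nb, d] <- pmax(g[nb, d], crosstalk)
    }
    g
  }
  list(pos = band(0L), neg = band(max(1L, n_channels %/% (2L * N_DOF))))
}

#' Participant-level generative parameters
#'
#' Bundles everything that makes a simulated participant deviate from the
#' preprogrammed virtual hand: biomechanical coupling leakage, resting-
#' position drift, mimic reaction lag (always positive), mirror timing
#' jitter (zero-mean, two-sided), magnitude errors, and the surrogate
#' EMG synergy model.
#'
#' @param preset Optional preset name (`"paper_healthy"`, `"noise_free"`) or
#'   path to a YAML preset file; explicit arguments override preset values.
#' @param coupling_matrix 8 x 8 matrix of leakage fractions in [0, 1) with a
#'   zero diagonal: entry (j, k) is the fraction of target DOF k's profile
#'   leaked into non-target DOF j.
#' @param drift_step_sd SD of the per-rest-interval random-walk increment of
#'   the resting offset, normalized-angle units per interval.
#' @param drift_max Offsets are clipped to +/- this value.
#' @param mimic_lag_mean_s,mimic_lag_sd_s Mean/SD of the per-trial reaction
#'   lag of the ground-truth hand behind the virtual hand, seconds. The lag
#'   distribution is a normal truncated at 0 (the hand always lags).
#' @param mirror_jitter_sd_s SD of the zero-mean per-trial lag of the mirror
#'   hand relative to the ground-truth hand, seconds.
#' @param mimic_mag_err_mean,mimic_mag_err_sd Mean/SD of the per-trial peak-
#'   amplitude error of the ground-truth hand relative to the preprogrammed
#'   full deviation (fraction; -0.1 means reaching only 90%).
#' @param mirror_mag_err_sd SD of the zero-mean per-trial amplitude error of
#'   the mirror hand relative to the ground-truth hand (fraction).
#' @param synergy_gain_pos,synergy_gain_neg Nonnegative n_channels x 8
#'   matrices mapping rectified flexion / extension angle to EMG envelope.
#' @param emg_baseline Per-channel resting envelope (scalar or vector).
#' @param n_emg_channels Number of EMG channels when synergy matrices are
#'   generated by default.
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   simulated sessions.
#' @return A validated `participant_params` object.
#' @export
participant_params <- function(preset = NULL,
                               coupling_matrix = NULL,
                               drift_step_sd = 0,
                               drift_max = 0.25,
                               mimic_lag_mean_s = 0,
                               mimic_lag_sd_s = 0,
                               mirror_jitter_sd_s = 0,
                               mimic_mag_err_mean = 0,
                               mimic_mag_err_sd = 0,
                               mirror_mag_err_sd = 0,
                               synergy_gain_pos = NULL,
                               synergy_gain_neg = NULL,
                               emg_baseline = 0.05,
                               n_emg_channels = 32,
                               seed = 1L) {
  supplied <- names(match.call())[-1]
  p <- list(coupling_matrix = coupling_matrix, drift_step_sd = drift_step_sd,
            drift_max = drift_max, mimic_lag_mean_s = mimic_lag_mean_s,
            mimic_lag_sd_s = mimic_lag_sd_s,
            mirror_jitter_sd_s = mirror_jitter_sd_s,
            mimic_mag_err_mean = mimic_mag_err_mean,
            mimic_mag_err_sd = mimic_mag_err_sd,
            mirror_mag_err_sd = mirror_mag_err_sd,
            synergy_gain_pos = synergy_gain_pos,
            synergy_gain_neg = synergy_gain_neg,
            emg_baseline = emg_baseline, n_emg_channels = n_emg_channels,
            seed = seed)
  if (!is.null(preset)) {
    pre <- load_preset(preset)
    for (nm in names(pre))
      if (!nm %in% supplied) p[[nm]] <- pre[[nm]]
  }
  if (is.null(p$coupling_matrix)) p$coupling_matrix <- matrix(0, N_DOF, N_DOF)
  p$coupling_matrix <- as.matrix(p$coupling_matrix)
  if (is.null(p$synergy_gain_pos) || is.null(p$synergy_gain_neg)) {
    syn <- make_synergy(p$n_emg_channels)
    if (is.null(p$synergy_gain_pos)) p$synergy_gain_pos <- syn$pos
    if (is.null(p$synergy_gain_neg)) p$synergy_gain_neg <- syn$neg
  }
  p$synergy_gain_pos <- as.matrix(p$synergy_gain_pos)
  p$synergy_gain_neg <- as.matrix(p$synergy_gain_neg)
  p$n_emg_channels <- nrow(p$synergy_gain_pos)
  if (length(p$emg_baseline) == 1L)
    p$emg_baseline <- rep(p$emg_baseline, p$n_emg_channels)
  p$seed <- as.integer(p$seed)
  validate_participant_params(p)
  structure(p, class = "participant_params")
}

validate_participant_params <- function(p) {
  sds <- c(p$drift_step_sd, p$mimic_lag_sd_s, p$mirror_jitter_sd_s,
           p$mimic_mag_err_sd, p$mirror_mag_err_sd)
  if (any(sds < 0)) stop("all SD parameters must be >= 0")
  cm <- p$coupling_matrix
  if (!all(dim(cm) == c(N_DOF, N_DOF)))
    stop("coupling_matrix must be 8 x 8")
  if (any(diag(cm) != 0)) stop("coupling_matrix diagonal must be zero")
  if (any(cm < 0) || any(cm >= 1)) stop("coupling entries must be in [0, 1)")
  if (any(p$synergy_gain_pos < 0) || any(p$synergy_gain_neg < 0))
    stop("synergy matrices must be nonnegative")
  if (!all(dim(p$synergy_gain_pos) == dim(p$synergy_gain_neg)) ||
      ncol(p$synergy_gain_pos) != N_DOF)
    stop("synergy matrices must be n_channels x 8 and congruent")
  if (any(p$emg_baseline < 0)) stop("emg_baseline must be nonnegative")
  if (p$mimic_lag_mean_s < 0) stop("mimic_lag_mean_s must be >= 0")
  invisible(p)
}

#' Uniform off-diagonal coupling matrix
#'
#' @param value Leakage fraction applied from every target DOF into every
#'   non-target DOF.
#' @return 8 x 8 matrix with zero diagonal.
#' @export
uniform_coupling <- function(value) {
  m <- matrix(value, N_DOF, N_DOF)
  diag(m) <- 0
  m
}

load_preset <- function(preset) {
  path <- if (file.exists(preset)) preset else
    system.file("presets", paste0(preset, ".yaml"), package = "myolabel")
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("unknown preset '%s'", preset))
  y <- yaml::read_yaml(path)
  out <- y[setdiff(names(y), c("coupling", "synergy", "name", "description"))]
  if (!is.null(y$coupling)) {
    if (!identical(y$coupling$type, "uniform"))
      stop("unsupported coupling type in preset")
    out$coupling_matrix <- uniform_coupling(y$coupling$value)
  }
  if (!is.null(y$synergy)) {
    if (!identical(y$synergy$type, "banded"))
      stop("unsupported synergy type in preset")
    syn <- make_synergy(y$synergy$n_channels %||% 32,
                        y$synergy$gain %||% 1,
                        y$synergy$crosstalk %||% 0.1)
    out$synergy_gain_pos <- syn$pos
    out$synergy_gain_neg <- syn$neg
    out$emg_baseline <- y$synergy$baseline %||% 0.05
    out$n_emg_channels <- nrow(syn$pos)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.participant_params <- function(x, ...) {
  cat(sprintf(paste0("<participant_params> coupling=%.3f drift_sd=%.4f ",
                     "lag=%.0f+/-%.0f ms jitter_sd=%.0f ms ",
                     "mag_err=%.3f+/-%.3f mirror_mag_sd=%.3f seed=%d\n"),
              max(x$coupling_matrix), x$drift_step_sd,
              1000 * x$mimic_lag_mean_s, 1000 * x$mimic_lag_sd_s,
              1000 * x$mirror_jitter_sd_s, x$mimic_mag_err_mean,
              x$mimic_mag_err_sd, x$mirror_mag_err_sd, x$seed))
  invisible(x)
}
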