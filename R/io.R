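SESSION_FORMAT_VERSION <- "1.0"

# full-precision numeric formatting so text round trips are bit-exact
fmt_num <- function(x) sprintf("%.17g", x)

write_num_tsv <- function(mat, path) {
  mat <- as.matrix(mat)
  txt <- apply(mat, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  header <- paste(colnames(mat) %||% paste0("V", seq_len(ncol(mat))),
                  collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, txt), con)
}

read_num_tsv <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a session archive
#'
#' Serializes a `session_data` to a directory of plain-text files:
#' `session.json` (format version, schedule, timing, boundaries and
#' participant parameters), one TSV per kinematic trace (full precision, so
#' `read_session(write_session(x))` is bit-exact), and gzip-compressed TSV
#' for the raw EMG when present.
#'
#' @param session A `session_data`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sc <- session$schedule
  p <- session$params
  meta <- list(
    format_version = SESSION_FORMAT_VERSION,
    session_id = sc$session_id,
    protocol = sc$protocol,
    timing = unclass(sc$timing),
    trials = sc$trials,
    boundaries = as.data.frame(session$truth$boundaries),
    kinematic_rate_hz = session$truth$rate,
    emg_rate_hz = if (is.null(session$emg)) NULL else session$emg$rate,
    has_emg = !is.null(session$emg),
    params = lapply(unclass(p), function(x)
      if (is.matrix(x)) list(matrix = TRUE, nrow = nrow(x),
                             data = fmt_num(as.vector(x)))
      else if (is.numeric(x)) fmt_num(x) else x)
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_num_tsv(session$virtual$values, file.path(path, "virtual.tsv"))
  write_num_tsv(session$truth$values, file.path(path, "truth.tsv"))
  write_num_tsv(session$mirror$values, file.path(path, "mirror.tsv"))
  if (!is.null(session$emg)) {
    con <- gzfile(file.path(path, "emg.tsv.gz"), "w")
    mat <- session$emg$values
    writeLines(c(paste(paste0("ch", seq_len(ncol(mat))), collapse = "\t"),
                 apply(mat, 1, function(r) paste(fmt_num(r), collapse = "\t"))),
               con)
    close(con)
  }
  invisible(path)
}

schema_fail <- function(field, msg)
  stop(sprintf("session archive schema violation in field '%s': %s",
               field, msg), call. = FALSE)

#' Read a session archive
#'
#' Validates the format version and internal consistency (trace lengths,
#' rates, EMG duration) before returning; a truncated or inconsistent
#' archive raises a field-level error and no partial object.
#'
#' @param path Directory written by [write_session()].
#' @return A `session_data`.
#' @export
read_session <- function(path) {
  jf <- file.path(path, "session.json")
  if (!file.exists(jf)) schema_fail("session.json", "missing")
  meta <- tryCatch(jsonlite::read_json(jf, simplifyVector = TRUE),
                   error = function(e) schema_fail("session.json",
                                                   "unparseable (truncated?)"))
  if (!identical(meta$format_version, SESSION_FORMAT_VERSION))
    stop(sprintf("session archive version '%s' is not supported (expected %s)",
                 meta$format_version, SESSION_FORMAT_VERSION), call. = FALSE)
  for (f in c("virtual.tsv", "truth.tsv", "mirror.tsv"))
    if (!file.exists(file.path(path, f))) schema_fail(f, "missing trace file")
  pr <- meta$params
  pr <- lapply(pr, function(x) {
    if (is.list(x) && isTRUE(x$matrix))
      matrix(as.numeric(x$data), nrow = x$nrow)
    else if (is.character(x) && all(grepl("^[-+0-9.eEinfa]+$", x)))
      as.numeric(x)
    else x
  })
  params <- participant_params(
    coupling_matrix = pr$coupling_matrix, drift_step_sd = pr$drift_step_sd,
    drift_max = pr$drift_max, mimic_lag_mean_s = pr$mimic_lag_mean_s,
    mimic_lag_sd_s = pr$mimic_lag_sd_s,
    mirror_jitter_sd_s = pr$mirror_jitter_sd_s,
    mimic_mag_err_mean = pr$mimic_mag_err_mean,
    mimic_mag_err_sd = pr$mimic_mag_err_sd,
    mirror_mag_err_sd = pr$mirror_mag_err_sd,
    synergy_gain_pos = pr$synergy_gain_pos,
    synergy_gain_neg = pr$synergy_gain_neg,
    emg_baseline = pr$emg_baseline, seed = pr$seed)
  timing <- do.call(trial_timing, meta$timing)
  schedule <- build_schedule(meta$protocol,
                             reps = max(meta$trials$rep),
                             timing = timing, session_id = meta$session_id)
  if (!identical(schedule$trials$movement_id, meta$trials$movement_id))
    schema_fail("trials", "movement sequence does not match the protocol")
  bounds <- as.matrix(meta$boundaries)
  rate <- meta$kinematic_rate_hz
  if (!identical(as.numeric(rate), as.numeric(timing$kinematic_rate_hz)))
    schema_fail("kinematic_rate_hz", "does not match declared timing")
  traces <- lapply(c("virtual", "truth", "mirror"), function(nm) {
    v <- read_num_tsv(file.path(path, paste0(nm, ".tsv")))
    if (nrow(v) < max(bounds[, "end"]) - 1L)
      schema_fail(paste0(nm, ".tsv"), "trace shorter than trial boundaries")
    kinematic_trace(v, rate, bounds)
  })
  names(traces) <- c("virtual", "truth", "mirror")
  emg <- NULL
  if (isTRUE(meta$has_emg)) {
    ef <- file.path(path, "emg.tsv.gz")
    if (!file.exists(ef)) schema_fail("emg.tsv.gz", "missing EMG file")
    v <- as.matrix(utils::read.delim(gzfile(ef), check.names = FALSE))
    expect_n <- round(nrow(traces$truth$values) / rate * meta$emg_rate_hz)
    if (abs(nrow(v) - expect_n) > 1)
      schema_fail("emg_rate_hz", sprintf(
        "EMG sample count %d does not match declared rate (expected %d)",
        nrow(v), expect_n))
    if (!identical(as.numeric(meta$emg_rate_hz),
                   as.numeric(timing$emg_rate_hz)))
      schema_fail("emg_rate_hz", "does not match declared timing")
    emg <- raw_emg(v, meta$emg_rate_hz)
  }
  structure(list(schedule = schedule, virtual = traces$virtual,
                 truth = traces$truth, mirror = traces$mirror,
                 emg = emg, params = params),
            class = "session_data")
}

config_defaults <- function() {
  list(preset = "paper_healthy", cohort_size = 7L, seed = 1L,
       protocol = "biomech", reps = 10L, run_sweep = FALSE,
       ml_reps = 20L, ml_sessions = 3L,
       sizes = seq(10L, 55L, by = 5L), algorithms = c("kf", "cnn"),
       k_folds = 10L, feature_channels = 64L, agg = "median_abs",
       out_dir = "results")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills defaults, and rejects unknown keys
#' (with a closest-match suggestion) and type mismatches. The resolved
#' configuration is what [run_full_experiment()] echoes to the manifest.
#'
#' @param path YAML file path.
#' @return A validated named list.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  defs <- config_defaults()
  unknown <- setdiff(names(y), names(defs))
  if (length(unknown) > 0) {
    d <- utils::adist(unknown[1], names(defs))
    hint <- names(defs)[which.min(d)]
    stop(sprintf("unknown config key '%s'%s", unknown[1],
                 if (min(d) <= 3) sprintf("; did you mean '%s'?", hint) else ""),
         call. = FALSE)
  }
  cfg <- defs
  cfg[names(y)] <- y
  num_keys <- c("cohort_size", "seed", "reps", "ml_reps", "ml_sessions",
                "sizes", "k_folds", "feature_channels")
  for (k in num_keys)
    if (!is.numeric(cfg[[k]]))
      stop(sprintf("config key '%s' must be numeric", k), call. = FALSE)
  if (!cfg$protocol %in% c("biomech", "ml"))
    stop("config key 'protocol' must be 'biomech' or 'ml'", call. = FALSE)
  # resolve the preset now so a missing preset fails before any computation
  invisible(participant_params(preset = cfg$preset))
  cfg
}

#' Write a run manifest
#'
#' Records the resolved configuration, seeds, format versions and package
#' version -- enough to reproduce the run.
#'
#' @param config Resolved configuration list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  man <- list(
    package = "myolabel",
    package_version = as.character(utils::packageVersion("myolabel")),
    r_version = as.character(getRversion()),
    session_format_version = SESSION_FORMAT_VERSION,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = lapply(config, function(x) if (is.numeric(x)) as.vector(x) else x)
  )
  yaml::write_yaml(man, path)
  invisible(path)
}
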