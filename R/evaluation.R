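#' Assemble a training dataset from one or more sessions
#'
#' Computes (or accepts) MAV features per session, derives the paradigm's
#' labels -- mimic: the preprogrammed virtual trace, lag-corrected against
#' that session's features by cross-correlation; mirror: the contralateral
#' trace as-is -- and concatenates sessions into aligned per-sample
#' matrices. Trials are renumbered globally; every sample carries its trial,
#' session and movement id.
#'
#' @param sessions A `session_data` or list of them (e.g.
#'   [simulate_ml_participant()]).
#' @param paradigm `"mimic"` or `"mirror"`.
#' @param feature_channels Number of feature columns kept, in canonical
#'   order (32 single-ended, then differential pairs); default 64, the
#'   desk-scale mode. `NULL` keeps all 528.
#' @param features Optional list of precomputed [feature_matrix()] per
#'   session (reused across paradigms).
#' @param align Lag-correct mimic labels (default TRUE).
#' @return A `training_dataset`: matrices `features` (T x C), `labels`
#'   (T x 8) and `truth` (T x 8, the ground-truth trace used as the scoring
#'   reference), vectors `trial`, `session`, `movement`, a per-trial
#'   `trials` table, and `paradigm`.
#' @export
build_training_dataset <- function(sessions, paradigm = c("mimic", "mirror"),
                                   feature_channels = 64, features = NULL,
                                   align = TRUE) {
  paradigm <- match.arg(paradigm)
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  feat_l <- lab_l <- truth_l <- trial_l <- sess_l <- mov_l <- list()
  trial_rows <- list()
  offset <- 0L
  for (s in seq_along(sessions)) {
    ses <- sessions[[s]]
    fm <- if (!is.null(features)) features[[s]] else {
      if (is.null(ses$emg)) stop("session has no EMG; supply `features`")
      compute_mav_features(ses$emg, max_channels = feature_channels)
    }
    labels <- if (paradigm == "mirror") ses$mirror else {
      if (align) {
        al <- align_labels_crosscorr(ses$virtual, fm)
        shift_trace_zero(ses$virtual, al$lag_samples)
      } else ses$virtual
    }
    b <- ses$truth$boundaries
    nt <- nrow(b)
    spt <- b[1, "end"] - b[1, "start"]
    Tn <- min(nrow(fm$values), nrow(labels$values))
    feat_l[[s]] <- fm$values[seq_len(Tn), , drop = FALSE]
    lab_l[[s]] <- labels$values[seq_len(Tn), , drop = FALSE]
    truth_l[[s]] <- ses$truth$values[seq_len(Tn), , drop = FALSE]
    tid <- rep(seq_len(nt), each = spt)[seq_len(Tn)] + offset
    trial_l[[s]] <- tid
    sess_l[[s]] <- rep(s, Tn)
    mov_l[[s]] <- rep(ses$schedule$trials$movement_id, each = spt)[seq_len(Tn)]
    trial_rows[[s]] <- data.frame(
      trial = seq_len(nt) + offset, session = s,
      movement_id = ses$schedule$trials$movement_id,
      rep = ses$schedule$trials$rep, stringsAsFactors = FALSE)
    offset <- offset + nt
  }
  structure(list(features = do.call(rbind, feat_l),
                 labels = do.call(rbind, lab_l),
                 truth = do.call(rbind, truth_l),
                 trial = unlist(trial_l), session = unlist(sess_l),
                 movement = unlist(mov_l),
                 trials = do.call(rbind, trial_rows),
                 paradigm = paradigm,
                 rate = sessions[[1]]$truth$rate),
            class = "training_dataset")
}

#' @export
print.training_dataset <- function(x, ...) {
  cat(sprintf("<training_dataset %s> %d samples, %d features, %d trials, %d session(s)\n",
              x$paradigm, nrow(x$features), ncol(x$features),
              nrow(x$trials), length(unique(x$trials$session))))
  invisible(x)
}

#' Shuffled train/test fold assignments at trial granularity
#'
#' Each fold reserves `n_train_trials` trials per movement for training,
#' drawn equally from each session (remainders go to the lowest-numbered
#' sessions), and leaves the remaining trials of that movement for testing.
#' `val_trials` training trials (total) are additionally re-reserved for
#' validation of the convolutional regressor. Trials are never split.
#'
#' @param dataset A [build_training_dataset()] result (either paradigm --
#'   the trial structure is shared).
#' @param n_train_trials Training trials per movement.
#' @param k Number of folds (default 10); each fold re-draws the split.
#' @param seed Seed; identical seeds give identical folds.
#' @param val_trials Validation trials re-reserved from training (default 5).
#' @return List of `k` folds, each `list(train, test, val)` of global trial
#'   ids (with `val` a subset of `train`).
#' @export
make_folds <- function(dataset, n_train_trials, k = 10, seed = 1,
                       val_trials = 5) {
  tt <- dataset$trials
  sessions <- sort(unique(tt$session))
  movements <- unique(tt$movement_id)
  per_sess <- vapply(split(tt$trial, paste(tt$movement_id, tt$session)),
                     length, integer(1))
  avail <- min(tapply(tt$trial, tt$movement_id, length))
  if (n_train_trials >= avail)
    stop("n_train_trials must be below the available trials per movement")
  ns <- length(sessions)
  base <- n_train_trials %/% ns
  extra <- n_train_trials %% ns
  take <- rep(base, ns) + c(rep(1L, extra), rep(0L, ns - extra))
  set.seed(seed)
  lapply(seq_len(k), function(f) {
    train <- integer(0)
    for (m in movements) {
      for (si in seq_along(sessions)) {
        pool <- tt$trial[tt$movement_id == m & tt$session == sessions[si]]
        if (take[si] > length(pool))
          stop("not enough trials in a session to balance the fold")
        train <- c(train, sample(pool, take[si]))
      }
    }
    test <- setdiff(tt$trial, train)
    val <- if (val_trials > 0) sample(train, min(val_trials, length(train)))
           else integer(0)
    list(train = sort(train), test = sort(test), val = sort(val))
  })
}

decoder_backends <- function(algorithm, kf_lambda, kf_channels, cnn_spec) {
  if (is.function(algorithm)) return(algorithm)
  switch(algorithm,
    kf = function(train, fold, seed) {
      model <- fit_kalman(train, ridge_lambda = kf_lambda,
                          n_channels = min(kf_channels,
                                           ncol(train$features)))
      function(feat, trial) {
        out <- matrix(0, nrow(feat), model$n_dof)
        for (tr in unique(trial)) {
          idx <- which(trial == tr)
          out[idx, ] <- kalman_predict(model,
                                       feat[idx, , drop = FALSE])$values
        }
        out
      }
    },
    cnn = function(train, fold, seed) {
      spec <- cnn_spec
      spec$seed <- as.integer(seed)
      model <- fit_conv_regressor(train, spec,
                                  val_trials = fold$val)
      function(feat, trial) conv_predict(model, feat, trial)$values
    },
    stop(sprintf("unknown algorithm '%s'", algorithm))
  )
}

subset_dataset <- function(dataset, trials) {
  idx <- dataset$trial %in% trials
  list(features = dataset$features[idx, , drop = FALSE],
       labels = dataset$labels[idx, , drop = FALSE],
       truth = if (is.null(dataset$truth)) NULL else
         dataset$truth[idx, , drop = FALSE],
       trial = dataset$trial[idx])
}

#' Evaluate one paradigm x algorithm x dataset-size condition
#'
#' Per fold, the decoder is trained on the paradigm's labels over the
#' fold's training trials and run over the held-out test trials; its
#' predictions are compared against the ground-truth hand kinematics (the
#' point of recording a ground-truth hand: both paradigms are scored on the
#' same reference). The error is aggregated per DOF over time, the median
#' across the 8 DOFs is the fold value, and the condition summary is the
#' median over folds.
#'
#' @param dataset A [build_training_dataset()] result.
#' @param algorithm `"kf"`, `"cnn"`, or a function
#'   `f(train, fold, seed)` returning a predictor `g(features, trial)`
#'   (testing hook).
#' @param n_train_trials Training trials per movement.
#' @param k Number of folds.
#' @param seed Seed for fold construction and decoder initialization.
#' @param folds Optional precomputed [make_folds()] result (for paired
#'   comparisons across paradigms).
#' @param agg Per-DOF error aggregation over time: `"median_abs"` (median
#'   absolute error per time point, default, following the evaluation's
#'   sentence order) or `"rmse"` (plain per-DOF RMSE).
#' @param eval_against `"truth"` (default: score predictions against the
#'   ground-truth trace) or `"labels"` (score against the paradigm's own
#'   labels).
#' @param kf_lambda,kf_channels Kalman hyperparameters.
#' @param cnn_spec A [conv_spec()] for the convolutional regressor.
#' @return An `eval_result`: `fold_rmse`, `summary_rmse` (median of folds),
#'   `per_dof_medians`, plus the condition descriptors.
#' @export
evaluate_condition <- function(dataset, algorithm = "kf", n_train_trials = 10,
                               k = 10, seed = 1, folds = NULL,
                               agg = c("median_abs", "rmse"),
                               eval_against = c("truth", "labels"),
                               kf_lambda = 1e-3, kf_channels = 48,
                               cnn_spec = conv_spec_small()) {
  agg <- match.arg(agg)
  eval_against <- match.arg(eval_against)
  if (eval_against == "truth" && is.null(dataset$truth))
    stop("dataset carries no ground-truth trace; use eval_against = 'labels'")
  if (is.null(folds))
    folds <- make_folds(dataset, n_train_trials, k = k, seed = seed)
  backend <- decoder_backends(algorithm, kf_lambda, kf_channels, cnn_spec)
  fold_vals <- numeric(length(folds))
  dof_vals <- matrix(NA_real_, length(folds), ncol(dataset$labels))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    train <- subset_dataset(dataset, fold$train)
    test <- subset_dataset(dataset, fold$test)
    predictor <- tryCatch(backend(train, fold, seed + f),
                          error = function(e)
                            stop(sprintf("decoder training failed in fold %d: %s",
                                         f, conditionMessage(e))))
    pred <- predictor(test$features, test$trial)
    ref <- if (eval_against == "truth") test$truth else test$labels
    err <- pred - ref
    per_dof <- if (agg == "median_abs")
      apply(abs(err), 2, stats::median) else sqrt(colMeans(err^2))
    dof_vals[f, ] <- per_dof
    fold_vals[f] <- stats::median(per_dof)
  }
  structure(list(paradigm = dataset$paradigm,
                 algorithm = if (is.function(algorithm)) "custom" else algorithm,
                 n_train_trials = n_train_trials, k = length(folds),
                 agg = agg, fold_rmse = fold_vals,
                 summary_rmse = stats::median(fold_vals),
                 per_dof_medians = apply(dof_vals, 2, stats::median),
                 seed = seed),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s/%s n_train=%d: summary %s = %.4f (%d folds)\n",
              x$paradigm, x$algorithm, x$n_train_trials, x$agg,
              x$summary_rmse, x$k))
  invisible(x)
}

#' Dataset-size sweep across paradigms and algorithms
#'
#' Runs the full factorial paradigm x algorithm x size. At a fixed size and
#' seed the same folds are reused across paradigms and algorithms, so every
#' comparison is paired (identical train/test trials).
#'
#' @param datasets Named list of [build_training_dataset()] results, one
#'   per paradigm (e.g. `list(mimic = ..., mirror = ...)`).
#' @param algorithms Character vector of algorithms.
#' @param sizes Training-trials-per-movement grid (default 10..55 by 5).
#' @param k,seed,... Passed to [evaluate_condition()].
#' @return Long data frame with one row per condition x fold, plus the
#'   condition summaries (column `summary_rmse` repeated within condition).
#' @export
dataset_size_sweep <- function(datasets, algorithms = c("kf", "cnn"),
                               sizes = seq(10, 55, by = 5), k = 10,
                               seed = 1, ...) {
  alg_names <- names(algorithms)
  if (is.null(alg_names)) alg_names <- as.character(algorithms)
  rows <- list()
  for (size in sizes) {
    folds <- make_folds(datasets[[1]], size, k = k, seed = seed + size)
    for (ai in seq_along(algorithms)) {
      for (par in names(datasets)) {
        res <- evaluate_condition(datasets[[par]], algorithms[[ai]], size,
                                  k = k, seed = seed + size, folds = folds,
                                  ...)
        rows[[length(rows) + 1L]] <- data.frame(
          paradigm = par, algorithm = alg_names[ai], n_train_trials = size,
          fold = seq_along(res$fold_rmse), rmse = res$fold_rmse,
          summary_rmse = res$summary_rmse, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cohort-level statistics
#'
#' One-sample t-tests of coupling and drift against zero, paired t-tests of
#' mirror vs mimic for every label-quality metric, a three-way ANOVA of
#' decoder error on paradigm, algorithm and dataset size, and post-hoc
#' paired t-tests at the extreme dataset sizes (uncorrected p-values, with a
#' Holm-adjusted column).
#'
#' @param label_metrics Optional [cohort_label_quality()] data frame.
#' @param eval_results Optional data frame of per-participant condition
#'   summaries with columns `participant`, `paradigm`, `algorithm`,
#'   `n_train_trials`, `summary_rmse`.
#' @return Data frame with columns `test`, `term`, `estimate`, `statistic`,
#'   `df`, `p`, `p_holm`.
#' @export
cohort_stats <- function(label_metrics = NULL, eval_results = NULL) {
  rows <- list()
  add <- function(test, term, estimate, statistic, df, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, term = term, estimate = estimate, statistic = statistic,
      df = df, p = p, stringsAsFactors = FALSE)
  safe_t <- function(x, y = NULL, paired = FALSE) {
    tryCatch({
      tt <- if (is.null(y)) stats::t.test(x) else
        stats::t.test(x, y, paired = paired)
      list(est = unname(tt$estimate[1]), stat = unname(tt$statistic),
           df = unname(tt$parameter), p = tt$p.value)
    }, error = function(e) list(est = mean(x - if (is.null(y)) 0 else y),
                                stat = NA_real_, df = NA_real_, p = NA_real_))
  }
  if (!is.null(label_metrics)) {
    m <- label_metrics
    if (length(unique(m$participant)) < 2)
      stop("cohort statistics need at least 2 participants")
    one <- m[m$paradigm == m$paradigm[1], ]
    for (v in c("coupling_pct", "drift_pct")) {
      r <- safe_t(one[[v]])
      add("one_sample_t_vs_0", v, r$est, r$stat, r$df, r$p)
    }
    mim <- m[m$paradigm == "mimic", ]
    mir <- m[m$paradigm == "mirror", ]
    mim <- mim[order(mim$participant), ]
    mir <- mir[order(mir$participant), ]
    for (v in c("mag_err_mean_pct", "mag_err_disp_pct",
                "timing_err_abs_mean_ms", "timing_err_disp_ms", "rmse")) {
      r <- safe_t(mir[[v]], mim[[v]], paired = TRUE)
      add("paired_t_mirror_vs_mimic", v, r$est, r$stat, r$df, r$p)
    }
  }
  if (!is.null(eval_results)) {
    e <- eval_results
    e$size_f <- factor(e$n_train_trials)
    fit <- stats::aov(summary_rmse ~ paradigm * algorithm * size_f, data = e)
    an <- summary(fit)[[1]]
    terms <- trimws(rownames(an))
    for (i in seq_len(nrow(an) - 1))
      add("anova_3way", terms[i], an[i, "Mean Sq"], an[i, "F value"],
          an[i, "Df"], an[i, "Pr(>F)"])
    lo <- min(e$n_train_trials)
    hi <- max(e$n_train_trials)
    for (alg in unique(e$algorithm)) {
      wide <- function(size, par)
        e$summary_rmse[e$algorithm == alg & e$n_train_trials == size &
                         e$paradigm == par][order(e$participant[
                           e$algorithm == alg & e$n_train_trials == size &
                             e$paradigm == par])]
      for (par in unique(e$paradigm)) {
        r <- safe_t(wide(hi, par), wide(lo, par), paired = TRUE)
        add("posthoc_size_extremes", sprintf("%s_%s_%dvs%d", alg, par, hi, lo),
            r$est, r$stat, r$df, r$p)
      }
      r <- safe_t(wide(hi, "mirror"), wide(hi, "mimic"), paired = TRUE)
      add("posthoc_paradigm_at_max_size", sprintf("%s_%d", alg, hi),
          r$est, r$stat, r$df, r$p)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("nothing to test: supply metrics and/or results")
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Run the full simulated experiment end-to-end
#'
#' Simulates the cohort, computes the label-quality table and cohort
#' statistics, optionally runs the dataset-size sweep on a simulated
#' participant, and writes tab-delimited outputs plus a run manifest.
#'
#' @param config A [load_config()] result (or compatible list).
#' @return Invisibly, a list with `metrics`, `stats`, `results` (or NULL)
#'   and the output paths.
#' @export
run_full_experiment <- function(config) {
  cfg <- config
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cohort <- stage("simulate", simulate_cohort(
    cfg$cohort_size, preset = cfg$preset, protocol = cfg$protocol,
    reps = cfg$reps, seed = cfg$seed, with_emg = TRUE))
  metrics <- stage("metrics", cohort_label_quality(cohort))
  results <- NULL
  if (isTRUE(cfg$run_sweep)) {
    results <- stage("sweep", {
      sessions <- simulate_ml_participant(preset = cfg$preset,
                                          seed = cfg$seed + 1,
                                          reps = cfg$ml_reps,
                                          n_sessions = cfg$ml_sessions)
      feats <- lapply(sessions, function(s)
        compute_mav_features(s$emg, max_channels = cfg$feature_channels))
      datasets <- list(
        mimic = build_training_dataset(sessions, "mimic",
                                       features = feats),
        mirror = build_training_dataset(sessions, "mirror",
                                        features = feats))
      sw <- dataset_size_sweep(datasets, algorithms = cfg$algorithms,
                               sizes = cfg$sizes, k = cfg$k_folds,
                               seed = cfg$seed)
      sw$participant <- "ml1"
      sw
    })
  }
  stats_tab <- stage("stats", cohort_stats(
    label_metrics = metrics,
    eval_results = if (!is.null(results))
      unique(results[, c("participant", "paradigm", "algorithm",
                         "n_train_trials", "summary_rmse")]) else NULL))
  write_tsv(metrics, file.path(out_dir, "metrics.tsv"))
  write_tsv(stats_tab, file.path(out_dir, "stats.tsv"))
  if (!is.null(results)) write_tsv(results, file.path(out_dir, "results.tsv"))
  write_manifest(cfg, file.path(out_dir, "manifest.yaml"))
  invisible(list(metrics = metrics, stats = stats_tab, results = results,
                 out_dir = out_dir))
}
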