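# End-to-end orchestration: per-space and joint-model accuracies, unique
# contributions with permutation nulls, attended-vs-unattended contrasts,
# optional lag-windowed analysis, and a Table-1-style statistical report.

#' Study-level analysis configuration
#'
#' Validated bundle of analysis parameters for [run_study()].
#'
#' @param sim a [sim_config()] (synthetic mode) or `NULL` when `study` is
#'   supplied directly to [run_study()].
#' @param lag_min,lag_max analysis lag window in ms.
#' @param lambda_joint ridge grid for the joint-model comparisons.
#' @param lambda_partial ridge grid for the partial-correlation path.
#' @param channels channel-label subset for averaging (`NULL` = all).
#' @param window_ms lag-window width for the windowed analysis; `NULL`
#'   disables it.
#' @param run_vc include the vowel/consonant control comparison.
#' @param n_perm permutations per subject (default 1000).
#' @param n_group group-level resamples (default 1000).
#' @param seed seed for the statistics layer's resampling.
#' @return A `study_config` list.
#' @export
study_config <- function(sim = sim_config(), lag_min = 0, lag_max = 300,
                         lambda_joint = lambda_grid_decades(),
                         lambda_partial = lambda_grid_powers2(),
                         channels = NULL, window_ms = 50, run_vc = TRUE,
                         n_perm = 1000, n_group = 1000, seed = 1) {
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    abort_bad_arg("`sim` must be a sim_config() or NULL.")
  }
  if (lag_min >= lag_max) abort_bad_arg("`lag_min` must be below `lag_max`.")
  if (!is.null(window_ms) && !is_whole((lag_max - lag_min) / window_ms)) {
    abort_bad_arg("`window_ms` must divide the lag range.")
  }
  if (!is.null(sim) && sim$duration * 1000 <= lag_max) {
    abort_bad_arg("lag window longer than a trial.")
  }
  stopifnot_scalar_number(n_perm, "n_perm", min = 1)
  stopifnot_scalar_number(n_group, "n_group", min = 1)
  structure(
    list(
      sim = sim, lag_min = lag_min, lag_max = lag_max,
      lambda_joint = lambda_joint, lambda_partial = lambda_partial,
      channels = channels, window_ms = window_ms, run_vc = run_vc,
      n_perm = as.integer(n_perm), n_group = as.integer(n_group),
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

# Wilcoxon + BF rows for a set of paired comparisons. `pairs` is a list of
# lists with fields label, condition, a, b.
paired_comparison_rows <- function(pairs) {
  rows <- lapply(pairs, function(p) {
    wt <- wilcoxon_two_tailed(p$a, p$b)
    tibble::tibble(
      comparison = p$label, condition = p$condition,
      observed = mean(p$a - p$b),
      p_perm = NA_real_,
      p_wilcoxon = wt$p, z = wt$z,
      bf10 = jzs_bf_paired(p$a, p$b)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- fdr_bh(out$p_wilcoxon)
  out[c("comparison", "condition", "observed", "p_perm", "p_wilcoxon",
    "z", "p_fdr", "bf10")]
}

# Joint-model comparison set: every non-baseline model against its
# nested baseline.
joint_comparison_pairs <- function() {
  list(
    list(model = "s+f", baseline = "s"),
    list(model = "s+sD", baseline = "s"),
    list(model = "s+fo", baseline = "s"),
    list(model = "s+sD+f", baseline = "s+sD"),
    list(model = "s+fo+f", baseline = "s+fo"),
    list(model = "s+fo+sD", baseline = "s+sD"),
    list(model = "s+fo+sD+f", baseline = "s+fo+sD")
  )
}

#' Run the complete two-stage analysis
#'
#' Stage one compares joint encoding models (does adding a feature space
#' improve EEG prediction?); stage two isolates each space's unique
#' predictive power by partial correlation, tests it against trial-
#' derangement permutation nulls, contrasts attended vs unattended, and
#' optionally repeats the analysis in lag sub-windows and with the
#' vowel/consonant control. All randomness is governed by the config
#' seeds, so a rerun is bit-identical.
#'
#' @param config a [study_config()].
#' @param study optional pre-built study tibble; by default the synthetic
#'   study described by `config$sim` is generated.
#' @return A `trf_study_results` list with tibbles `per_space`, `joint`,
#'   `unique`, `windowed` (or NULL), `stat_report`, plus `config` and a
#'   stage `log`.
#' @export
run_study <- function(config = study_config(), study = NULL) {
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }
  if (is.null(study)) {
    if (is.null(config$sim)) abort_bad_arg("no study and no sim config.")
    say("simulate: %d subjects x %d trials x %g s @ %g Hz",
      config$sim$n_subjects, config$sim$n_trials, config$sim$duration,
      config$sim$fs)
    study <- make_study(config$sim)
  }
  conds <- c("attended", "unattended")

  say("fit: per-space cross-validated models (lambda grid n=%d, lags %g-%g ms)",
    length(config$lambda_partial), config$lag_min, config$lag_max)
  spaces <- c("s", "sD", "f", "fo")
  if (isTRUE(config$run_vc)) spaces <- c(spaces, "vc")
  preds <- predictions_per_space(study, tags = spaces, conditions = conds,
    lambda = config$lambda_partial,
    lag_min = config$lag_min, lag_max = config$lag_max)
  per_space <- preds[c("subject", "condition", "space", "lambda", "mean_r")]

  say("partition: unique contributions + permutation nulls (n_perm=%d, n_group=%d)",
    config$n_perm, config$n_group)
  core <- c("s", "sD", "f", "fo")
  uniq <- dplyr::bind_rows(lapply(core, function(tg) {
    unique_contribution(preds, tg, setdiff(core, tg), config$channels)
  }))
  if (isTRUE(config$run_vc)) {
    uniq <- dplyr::bind_rows(uniq,
      unique_contribution(preds, "vc", c("s", "sD", "fo"), config$channels))
  }
  uniq$by_channel <- NULL
  # group-level permutation p per space x condition
  perm_rows <- list()
  for (tg in unique(uniq$feature_space)) {
    ctrls <- if (tg == "vc") c("s", "sD", "fo") else setdiff(core, tg)
    for (cond in conds) {
      subj <- unique(study$subject)
      nulls <- lapply(seq_along(subj), function(i) {
        cv_t <- pick_cv(preds, subj[i], cond, tg)
        cv_c <- lapply(ctrls, pick_cv, preds = preds, subj = subj[i],
          cond = cond)
        permutation_null_partial(cv_t, cv_c, n_perm = config$n_perm,
          channels = config$channels,
          seed = derive_seed(config$seed, i, match(cond, conds),
            match(tg, c(core, "vc"))))
      })
      obs <- mean(uniq$partial_r[uniq$feature_space == tg &
        uniq$condition == cond])
      gp <- group_null_and_p(nulls, obs, n_group = config$n_group,
        seed = derive_seed(config$seed, 999, match(cond, conds),
          match(tg, c(core, "vc"))))
      perm_rows[[length(perm_rows) + 1L]] <- tibble::tibble(
        feature_space = tg, condition = cond, p_perm = gp$p
      )
    }
  }
  uniq <- dplyr::left_join(uniq, dplyr::bind_rows(perm_rows),
    by = c("feature_space", "condition"))

  say("fit: joint models (%d combinations, lambda grid n=%d)",
    length(joint_model_set()), length(config$lambda_joint))
  joint <- joint_model_accuracy(study, joint_model_set(),
    conditions = conds, lambda = config$lambda_joint,
    lag_min = config$lag_min, lag_max = config$lag_max,
    channels = config$channels)

  say("stats: Wilcoxon/FDR/BF report")
  pairs <- list()
  for (cond in conds) {
    j <- joint[joint$condition == cond, ]
    for (cp in joint_comparison_pairs()) {
      a <- j$mean_r[j$model == cp$model][order(j$subject[j$model == cp$model])]
      b <- j$mean_r[j$model == cp$baseline][order(j$subject[j$model == cp$baseline])]
      pairs[[length(pairs) + 1L]] <- list(
        label = sprintf("%s > %s", cp$model, cp$baseline),
        condition = cond, a = a, b = b
      )
    }
  }
  joint_report <- paired_comparison_rows(pairs)
  att_pairs <- lapply(unique(uniq$feature_space), function(tg) {
    u <- uniq[uniq$feature_space == tg, ]
    a <- u$partial_r[u$condition == "attended"][order(u$subject[u$condition == "attended"])]
    b <- u$partial_r[u$condition == "unattended"][order(u$subject[u$condition == "unattended"])]
    list(label = sprintf("%s: attended > unattended", tg),
      condition = "contrast", a = a, b = b)
  })
  if (isTRUE(config$run_vc)) {
    ua <- uniq[uniq$condition == "attended", ]
    att_pairs <- c(att_pairs, list(list(
      label = "f > vc (attended)", condition = "attended",
      a = ua$partial_r[ua$feature_space == "f"][order(ua$subject[ua$feature_space == "f"])],
      b = ua$partial_r[ua$feature_space == "vc"][order(ua$subject[ua$feature_space == "vc"])]
    )))
  }
  contrast_report <- paired_comparison_rows(att_pairs)
  stat_report <- dplyr::bind_rows(joint_report, contrast_report)

  windowed <- NULL
  if (!is.null(config$window_ms)) {
    say("partition: lag-windowed analysis (%g ms windows)", config$window_ms)
    windowed <- windowed_unique_contribution(study, "f",
      c("s", "sD", "fo"), width_ms = config$window_ms,
      lag_min = config$lag_min, lag_max = config$lag_max,
      conditions = conds, lambda = config$lambda_partial,
      channels = config$channels)
  } else {
    say("partition: windowed analysis disabled")
  }

  structure(
    list(
      per_space = per_space, joint = joint, unique = uniq,
      windowed = windowed, stat_report = stat_report,
      config = config, log = log
    ),
    class = "trf_study_results"
  )
}

# Permutation null for the channel-averaged partial correlation of one
# target cv against its controls: the target's held-out predictions are
# deranged across trials, actual EEG and controls stay in place.
permutation_null_partial <- function(cv_target, cv_controls, n_perm = 1000,
                                     channels = NULL, seed = NULL) {
  n <- length(cv_target$predictions)
  nchan <- nrow(cv_target$actual[[1]])
  keep <- if (is.null(channels)) seq_len(nchan) else
    match(channels, cv_target$channels)
  qz <- vector("list", length(keep))
  rx <- vector("list", length(keep))
  for (ki in seq_along(keep)) {
    ch <- keep[ki]
    x <- concat_channel(cv_target$actual, ch)
    z <- if (length(cv_controls) == 0L) matrix(1, length(x), 1) else
      cbind(1, vapply(cv_controls, function(cv) {
        concat_channel(cv$predictions, ch)
      }, numeric(length(x))))
    qz[[ki]] <- qr(z)
    rx[[ki]] <- qr.resid(qz[[ki]], x)
  }
  lens <- vapply(cv_target$predictions, ncol, integer(1))
  stat_for <- function(perm) {
    mean(vapply(seq_along(keep), function(ki) {
      ch <- keep[ki]
      y <- unlist(lapply(perm, function(j) {
        cv_target$predictions[[j]][ch, ]
      }), use.names = FALSE)
      ry <- qr.resid(qz[[ki]], y)
      stats::cor(rx[[ki]], ry)
    }, numeric(1)))
  }
  with_seed_maybe(seed, {
    null <- vapply(seq_len(n_perm), function(k) {
      stat_for(sample_derangement(n))
    }, numeric(1))
    structure(
      list(null = null, observed = stat_for(seq_len(n)),
        statistic = "channel-mean partial correlation"),
      class = "null_distribution"
    )
  })
}

#' Write a results bundle to disk
#'
#' Writes the result tibbles as CSV with a stable column order, the run
#' log, and a JSON manifest embedding the configuration, seed and package
#' version. A disabled windowed analysis is noted in the log rather than
#' producing an empty table.
#'
#' @param results a `trf_study_results` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(results, dir) {
  stopifnot(inherits(results, "trf_study_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(results$per_space, "per_space_accuracy.csv")
  wr(results$joint, "joint_models.csv")
  wr(results$unique, "unique_contributions.csv")
  log <- results$log
  if (!is.null(results$windowed)) {
    wr(results$windowed, "windowed_contributions.csv")
  } else {
    log <- c(log, "report: windowed table omitted (analysis disabled)")
  }
  wr(results$stat_report, "stat_report.csv")
  cfg <- results$config
  manifest <- list(
    package = "speechtrf",
    version = as.character(utils::packageVersion("speechtrf")),
    seed = cfg$seed,
    lag_ms = c(cfg$lag_min, cfg$lag_max),
    lambda_joint = cfg$lambda_joint,
    lambda_partial = cfg$lambda_partial,
    n_perm = cfg$n_perm, n_group = cfg$n_group,
    window_ms = cfg$window_ms,
    sim = if (is.null(cfg$sim)) NULL else unclass(cfg$sim),
    tables = list.files(dir, pattern = "\\.csv$")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @rdname write_report
#' @param dir directory written by [write_report()].
#' @export
read_report <- function(dir) {
  rd <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    tibble::as_tibble(utils::read.csv(p))
  }
  list(
    per_space = rd("per_space_accuracy.csv"),
    joint = rd("joint_models.csv"),
    unique = rd("unique_contributions.csv"),
    windowed = rd("windowed_contributions.csv"),
    stat_report = rd("stat_report.csv"),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"))
  )
}
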