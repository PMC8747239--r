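# End-to-end evaluation: per fold, fit normalisation and feature selection
# on the training cycles only, train the LSTM, predict the held-out cycles
# and score per joint. Reports mirror the scheme x feature-set tables.

normalize_cycles <- function(cycles, stats, features) {
  lapply(cycles, function(cy) {
    cy$features <- apply_minmax(cy$features[, features, drop = FALSE],
                                stats)
    cy
  })
}

windows_from_cycles <- function(cycles, seq_len) {
  combine_windows(lapply(cycles, build_windows, seq_len = seq_len))
}

#' Evaluate one train/test fold
#'
#' Runs the full modelling pipeline on one fold: optional
#' Pearson-correlation feature selection on the training cycles, min-max
#' normalisation fitted on the training cycles, window construction, LSTM
#' training and prediction, and per-joint scoring. Nothing from the test
#' cycles influences feature selection, normalisation or training.
#'
#' @param train_cycles,test_cycles Lists of `gait_cycle` objects.
#' @param hp An [lstm_hyperparams()].
#' @param feature_set `"all"` (all nine channels) or `"selected"`.
#' @param sel_threshold Relative-importance threshold for selection.
#' @param nrmse_denominator Passed to [nrmse_cycle()].
#' @return List with `metrics` (data frame joint x {r2, rmse_deg,
#'   nrmse_pct}), `per_cycle` (per-test-cycle RMSE/NRMSE), `features`
#'   (channels used) and `model`.
#' @export
evaluate_fold <- function(train_cycles, test_cycles,
                          hp = lstm_hyperparams(),
                          feature_set = c("all", "selected"),
                          sel_threshold = 0.30,
                          nrmse_denominator = "prediction") {
  feature_set <- match.arg(feature_set)
  feats <- imu_channels()
  if (feature_set == "selected") {
    tables <- lapply(joint_names(), function(j) {
      joint_importance(train_cycles, j)
    })
    feats <- select_features(tables, threshold = sel_threshold)
  }
  stats <- fit_minmax(lapply(train_cycles, function(cy) {
    list(features = cy$features[, feats, drop = FALSE])
  }))
  tr <- normalize_cycles(train_cycles, stats, feats)
  te <- normalize_cycles(test_cycles, stats, feats)
  model <- train_lstm(windows_from_cycles(tr, hp$seq_len), hp)

  per_cycle <- data.frame()
  pooled_y <- vector("list", length(te))
  pooled_p <- vector("list", length(te))
  for (ci in seq_along(te)) {
    wb <- build_windows(te[[ci]], seq_len = hp$seq_len)
    pred <- predict_lstm(model, wb)
    pooled_y[[ci]] <- wb$y
    pooled_p[[ci]] <- pred
    for (j in joint_names()) {
      per_cycle <- rbind(per_cycle, data.frame(
        subject_id = te[[ci]]$subject_id, cycle_id = te[[ci]]$cycle_id,
        joint = j,
        rmse_deg = rmse(wb$y[, j], pred[, j]),
        nrmse_pct = nrmse_cycle(wb$y[, j], pred[, j],
                                denominator = nrmse_denominator)))
    }
  }
  Y <- do.call(rbind, pooled_y)
  P <- do.call(rbind, pooled_p)
  metrics <- do.call(rbind, lapply(joint_names(), function(j) {
    nr <- per_cycle$nrmse_pct[per_cycle$joint == j]
    data.frame(joint = j,
               r2 = r2(Y[, j], P[, j]),
               rmse_deg = rmse(Y[, j], P[, j]),
               nrmse_pct = mean(nr, na.rm = TRUE))
  }))
  list(metrics = metrics, per_cycle = per_cycle, features = feats,
       model = model)
}

fold_mean <- function(fold_metrics) {
  # average per-joint metrics over folds
  all <- do.call(rbind, fold_metrics)
  out <- do.call(rbind, lapply(joint_names(), function(j) {
    sub <- all[all$joint == j, ]
    data.frame(joint = j, r2 = mean(sub$r2),
               rmse_deg = mean(sub$rmse_deg),
               nrmse_pct = mean(sub$nrmse_pct),
               r2_sd = stats::sd(sub$r2), rmse_sd = stats::sd(sub$rmse_deg),
               nrmse_sd = stats::sd(sub$nrmse_pct))
  }))
  rownames(out) <- NULL
  out
}

#' Run the full scheme x feature-set evaluation grid
#'
#' For each requested split scheme and feature set, runs k-fold
#' cross-validation over the cohort's preprocessed cycles and collects
#' per-fold and cross-fold per-joint metrics. Under the within-one-subject
#' scheme a separate model is trained per subject and fold; per-subject
#' 5-fold means are aggregated across subjects by unweighted mean.
#'
#' @param cycles List of `gait_cycle` objects (e.g. from [build_cycles()]
#'   over a cohort's trials).
#' @param schemes Character vector of schemes to run.
#' @param feature_sets Subset of `c("all", "selected")`.
#' @param hp An [lstm_hyperparams()] (model seed lives here).
#' @param k Folds (default 5).
#' @param split_seed Seed for fold construction, independent of the model
#'   seed.
#' @param sel_threshold Feature-selection threshold.
#' @return A `metrics_report`: named list (one entry per
#'   `scheme.feature_set`) with `summary` (cross-fold per-joint means and
#'   SDs), `folds` (per-fold metrics), `features` (selection per fold) and
#'   `failed` (folds that errored). Attribute `config_hash` identifies the
#'   run.
#' @export
run_experiment <- function(cycles,
                           schemes = c("within_one_subject",
                                       "intra_subject", "inter_subject"),
                           feature_sets = c("all", "selected"),
                           hp = lstm_hyperparams(), k = 5,
                           split_seed = 1L, sel_threshold = 0.30) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  feature_sets <- match.arg(feature_sets, c("all", "selected"),
                            several.ok = TRUE)
  report <- list()
  for (scheme in schemes) {
    plan <- make_splits(cycles, scheme, k = k, seed = split_seed)
    for (fs in feature_sets) {
      run_one_fold <- function(fold) {
        tryCatch(
          evaluate_fold(cycles[fold$train], cycles[fold$test], hp = hp,
                        feature_set = fs, sel_threshold = sel_threshold),
          error = function(e) structure(list(message = conditionMessage(e)),
                                        class = "fold_failure"))
      }
      if (scheme == "within_one_subject") {
        subj_means <- list()
        folds <- list()
        feats <- list()
        failed <- character(0)
        for (s in names(plan)) {
          res <- lapply(plan[[s]], run_one_fold)
          ok <- !vapply(res, inherits, logical(1), "fold_failure")
          failed <- c(failed, vapply(res[!ok], function(r) {
            sprintf("subject %s: %s", s, r$message)
          }, character(1)))
          if (any(ok)) {
            subj_means[[s]] <- fold_mean(lapply(res[ok], function(r) {
              r$metrics
            }))
            folds[[s]] <- lapply(res[ok], `[[`, "metrics")
            feats[[s]] <- lapply(res[ok], `[[`, "features")
          }
        }
        # unweighted mean across subjects of the per-subject fold means
        summary <- do.call(rbind, lapply(joint_names(), function(j) {
          vals <- do.call(rbind, lapply(subj_means, function(m) {
            m[m$joint == j, c("r2", "rmse_deg", "nrmse_pct")]
          }))
          data.frame(joint = j, r2 = mean(vals$r2),
                     rmse_deg = mean(vals$rmse_deg),
                     nrmse_pct = mean(vals$nrmse_pct),
                     r2_sd = stats::sd(vals$r2),
                     rmse_sd = stats::sd(vals$rmse_deg),
                     nrmse_sd = stats::sd(vals$nrmse_pct))
        }))
        rownames(summary) <- NULL
        entry <- list(summary = summary, per_subject = subj_means,
                      folds = folds, features = feats, failed = failed)
      } else {
        res <- lapply(plan, run_one_fold)
        ok <- !vapply(res, inherits, logical(1), "fold_failure")
        entry <- list(
          summary = if (any(ok)) fold_mean(lapply(res[ok], `[[`,
                                                  "metrics")) else NULL,
          folds = lapply(res[ok], `[[`, "metrics"),
          per_cycle = lapply(res[ok], `[[`, "per_cycle"),
          features = lapply(res[ok], `[[`, "features"),
          failed = vapply(res[!ok], `[[`, character(1), "message"))
      }
      report[[paste(scheme, fs, sep = ".")]] <- entry
    }
  }
  attr(report, "config_hash") <- rlang::hash(list(
    schemes = schemes, feature_sets = feature_sets, hp = unclass(hp),
    k = k, split_seed = split_seed, sel_threshold = sel_threshold))
  class(report) <- "metrics_report"
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    if (!is.null(x[[nm]]$summary)) {
      print(x[[nm]]$summary, digits = 3)
    }
    if (length(x[[nm]]$failed)) {
      cat("failed folds:", length(x[[nm]]$failed), "\n")
    }
  }
  invisible(x)
}

#' Scheme summary as a joint-by-metric table
#'
#' Reshapes one report entry into the conventional layout: rows
#' {R2, RMSE, NRMSE} and columns {ankle, knee, hip}.
#'
#' @param report A [run_experiment()] result.
#' @param entry Entry name, e.g. `"inter_subject.selected"`.
#' @return Data frame with one row per metric.
#' @export
report_table <- function(report, entry) {
  s <- report[[entry]]$summary
  stopifnot(!is.null(s))
  tab <- data.frame(metric = c("R2", "RMSE (deg)", "NRMSE (%)"))
  for (j in c("ankle", "knee", "hip")) {
    row <- s[s$joint == j, ]
    tab[[j]] <- c(row$r2, row$rmse_deg, row$nrmse_pct)
  }
  tab
}
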