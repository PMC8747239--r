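# Metrics, split schemes, leakage guards and the experiment runner.

test_that("RMSE matches hand arithmetic and a brute-force loop", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(1)
  y <- rnorm(1000); yhat <- rnorm(1000)
  acc <- 0
  for (i in 1:1000) acc <- acc + (yhat[i] - y[i])^2
  expect_equal(rmse(y, yhat), sqrt(acc / 1000), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "lengths differ")
})

test_that("per-cycle NRMSE normalises by the predicted range", {
  y <- c(0, 10); yhat <- c(1, 11)
  expect_equal(nrmse_cycle(y, yhat), 10)          # RMSE 1 / range 10
  expect_equal(nrmse_cycle(y, y + 0), 0)
  # reference-range variant
  expect_equal(nrmse_cycle(c(0, 20), c(5, 15), denominator = "reference"),
               100 * sqrt(25) / 20)
  expect_warning(out <- nrmse_cycle(c(0, 1, 2), c(5, 5, 5)), "constant")
  expect_true(is.na(out))
})

test_that("R2 equals its definition on trivial and random inputs", {
  set.seed(2)
  y <- rnorm(1000); yhat <- y + rnorm(1000, 0, 0.5)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 1000)), 0, tolerance = 1e-12)
  ss_res <- 0; ss_tot <- 0
  for (i in 1:1000) {
    ss_res <- ss_res + (y[i] - yhat[i])^2
    ss_tot <- ss_tot + (y[i] - mean(y))^2
  }
  expect_equal(r2(y, yhat), 1 - ss_res / ss_tot, tolerance = 1e-12)
  expect_warning(expect_true(is.na(r2(rep(1, 5), rnorm(5)))), "constant")
})

make_labelled_cycles <- function(n_subjects, cycles_each, n = 8,
                                 seed = 1) {
  set.seed(seed)
  out <- list()
  for (s in seq_len(n_subjects)) {
    for (k in seq_len(cycles_each)) {
      out[[length(out) + 1]] <- toy_cycle(
        matrix(rnorm(n * 9), n, 9), matrix(rnorm(n * 3), n, 3),
        subject_id = s, cycle_id = k)
    }
  }
  out
}

test_that("fold test sets partition the units for every scheme", {
  cycles <- make_labelled_cycles(10, 10)
  for (scheme in c("intra_subject", "inter_subject")) {
    plan <- make_splits(cycles, scheme, k = 5, seed = 3)
    test_sets <- lapply(plan, `[[`, "test")
    # disjoint and exhaustive
    expect_equal(sort(unlist(test_sets)), seq_along(cycles))
    for (f in plan) {
      expect_length(intersect(f$train, f$test), 0)
      expect_equal(sort(c(f$train, f$test)), seq_along(cycles))
    }
  }
  plan_w <- make_splits(cycles, "within_one_subject", k = 5, seed = 3)
  for (s in names(plan_w)) {
    idx <- which(vapply(cycles, `[[`, integer(1), "subject_id") ==
                   as.integer(s))
    expect_equal(sort(unlist(lapply(plan_w[[s]], `[[`, "test"))), idx)
  }
})

test_that("inter-subject folds hold out exactly n_subjects / k people", {
  cycles <- make_labelled_cycles(30, 2, n = 4)
  plan <- make_splits(cycles, "inter_subject", k = 5, seed = 7)
  subj <- vapply(cycles, `[[`, integer(1), "subject_id")
  for (f in plan) {
    expect_length(unique(subj[f$test]), 6)
    expect_length(intersect(unique(subj[f$train]), unique(subj[f$test])),
                  0)
  }
  expect_error(make_splits(make_labelled_cycles(7, 2), "inter_subject",
                           k = 5, seed = 1), "divisible")
})

test_that("within-one-subject folds follow the 16/4 cycle split", {
  cycles <- make_labelled_cycles(1, 20)
  plan <- make_splits(cycles, "within_one_subject", k = 5, seed = 2)
  for (f in plan[["1"]]) {
    expect_length(f$test, 4)
    expect_length(f$train, 16)
  }
  expect_error(make_splits(make_labelled_cycles(1, 3),
                           "within_one_subject", k = 5, seed = 1),
               "fewer than")
})

test_that("splits are deterministic in the seed and differ across seeds", {
  cycles <- make_labelled_cycles(10, 5)
  a <- make_splits(cycles, "intra_subject", k = 5, seed = 9)
  b <- make_splits(cycles, "intra_subject", k = 5, seed = 9)
  c <- make_splits(cycles, "intra_subject", k = 5, seed = 10)
  expect_identical(a, b)
  expect_false(identical(unclass(a), unclass(c)))
})

test_that("normalisation and selection never see test data", {
  trl <- quiet_trial(n_cycles = 8, seed = 4)
  cycles <- build_cycles(trl)
  train <- cycles[1:6]; test <- cycles[7:8]

  feats_of <- function(test_cycles) {
    tabs <- lapply(joint_names(), function(j) joint_importance(train, j))
    sel <- select_features(tabs)
    st <- fit_minmax(train)
    list(sel = as.character(sel), st = st)
  }
  base <- suppressWarnings(feats_of(test))
  perturbed <- lapply(test, function(cy) {
    cy$labels <- cy$labels + 1000
    cy$features <- cy$features * 5
    cy
  })
  after <- suppressWarnings(feats_of(perturbed))
  expect_identical(base, after)
})

test_that("evaluate_fold scores a learnable subject accurately", {
  trl <- quiet_trial(n_cycles = 10, seed = 6)
  cycles <- build_cycles(trl)
  res <- suppressWarnings(evaluate_fold(
    cycles[1:8], cycles[9:10],
    hp = lstm_hyperparams(epochs = 40, seed = 2), feature_set = "all"))
  expect_identical(res$metrics$joint, joint_names())
  expect_true(all(res$metrics$r2 > 0.9))
  expect_true(all(res$metrics$rmse_deg >= 0))
  expect_true(all(res$metrics$nrmse_pct >= 0))
  expect_lte(max(res$metrics$r2), 1)
  # selected feature set never exceeds the nine channels, excludes yaw
  res_sel <- suppressWarnings(evaluate_fold(
    cycles[1:8], cycles[9:10],
    hp = lstm_hyperparams(epochs = 10, seed = 2),
    feature_set = "selected"))
  expect_lte(length(res_sel$features), 9)
  expect_false("yaw" %in% res_sel$features)
})

test_that("run_experiment emits the full grid and is seed-reproducible", {
  cohort <- make_cohort(cohort_config(n_subjects = 5, n_cycles = 6,
                                      seed = 13))
  cycles <- unlist(lapply(cohort$trials, build_cycles), recursive = FALSE)
  hp <- lstm_hyperparams(epochs = 3, hidden_size = 8, seed = 4)
  rep1 <- suppressWarnings(run_experiment(
    cycles, schemes = c("intra_subject", "inter_subject"),
    feature_sets = c("all", "selected"), hp = hp, k = 5, split_seed = 6))
  expect_setequal(names(rep1),
                  c("intra_subject.all", "intra_subject.selected",
                    "inter_subject.all", "inter_subject.selected"))
  for (nm in names(rep1)) {
    s <- rep1[[nm]]$summary
    expect_identical(s$joint, joint_names())
    expect_length(rep1[[nm]]$folds, 5)
    expect_length(rep1[[nm]]$failed, 0)
  }
  tab <- report_table(rep1, "intra_subject.all")
  expect_identical(tab$metric, c("R2", "RMSE (deg)", "NRMSE (%)"))
  expect_identical(names(tab), c("metric", "ankle", "knee", "hip"))

  rep2 <- suppressWarnings(run_experiment(
    cycles, schemes = c("intra_subject", "inter_subject"),
    feature_sets = c("all", "selected"), hp = hp, k = 5, split_seed = 6))
  expect_identical(rep1, rep2)
})

test_that("a failing fold is flagged without aborting the run", {
  cycles <- make_labelled_cycles(5, 5, n = 8)
  # poison one subject's labels so its folds fail inside evaluate_fold
  cycles[[3]]$labels[] <- NA_real_
  hp <- lstm_hyperparams(epochs = 1, hidden_size = 4, seed = 1)
  rep <- suppressWarnings(run_experiment(
    cycles, schemes = "intra_subject", feature_sets = "all", hp = hp,
    k = 5, split_seed = 2))
  entry <- rep[["intra_subject.all"]]
  expect_gt(length(entry$failed), 0)
  expect_lt(length(entry$folds), 5)
})
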