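# End-to-end experiments: generate a synthetic cohort, segment and
# featurize, reduce with PCA, train the level classifier (and optional
# per-level force regressors), evaluate on held-out groups, and
# aggregate per-level accuracy with between-subject SD.

#' Experiment configuration
#'
#' Defaults reproduce the reference protocol: 15 subjects, 8 levels over
#' 0-40 N, 50/25 ms windows, all four TD features on 8 channels (32-dim
#' rows), PCA to 8 dimensions, and per level a pool of 400 training +
#' 400 testing groups from which 200 + 200 are sampled.
#'
#' @param n_subjects cohort size.
#' @param seed master seed; every random choice derives from it.
#' @param acquisition an [acquisition_config()].
#' @param window a [window_spec()].
#' @param scheme a [level_scheme()] (must match the acquisition levels).
#' @param features TD features used (subset of MAV, RMS, SD, WL).
#' @param channels sEMG channels used.
#' @param pca_k PCA output dimension; `NA` disables PCA (raw features).
#' @param standardize_pca z-score features before PCA.
#' @param hyper an [sae_hyperparams()].
#' @param train_pool,test_pool per-level group pool sizes.
#' @param train_groups,test_groups groups sampled from each pool.
#' @param eval_regression also train per-level force regressors and
#'   report the held-out force MAE (slower; default FALSE).
#' @param verbose print per-stage progress.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 15, seed = 1L,
                              acquisition = acquisition_config(),
                              window = window_spec(),
                              scheme = level_scheme(),
                              features = c("MAV", "RMS", "SD", "WL"),
                              channels = 1:8,
                              pca_k = 8, standardize_pca = TRUE,
                              hyper = sae_hyperparams(),
                              train_pool = 400, test_pool = 400,
                              train_groups = 200, test_groups = 200,
                              eval_regression = FALSE, verbose = FALSE) {
  if (scheme$n_levels != acquisition$n_levels)
    stop_validation("scheme and acquisition disagree on n_levels")
  if (train_groups > train_pool || test_groups > test_pool)
    stop_validation("group counts cannot exceed their pools")
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 acquisition = acquisition, window = window, scheme = scheme,
                 features = features, channels = channels,
                 pca_k = pca_k, standardize_pca = standardize_pca,
                 hyper = hyper,
                 train_pool = as.integer(train_pool),
                 test_pool = as.integer(test_pool),
                 train_groups = as.integer(train_groups),
                 test_groups = as.integer(test_groups),
                 eval_regression = eval_regression, verbose = verbose),
            class = "experiment_config")
}

# Featurize all sessions of one subject into a single feature table.
subject_feature_table <- function(subject, config) {
  tables <- lapply(subject$sessions, function(rec)
    build_feature_table(rec, config$window, config$scheme,
                        features = config$features,
                        channels = config$channels))
  bind_feature_tables(tables)
}

# Per-level disjoint train/test group indices: windows of each level are
# shuffled (seeded); the first `train_pool` form the training pool, the
# next `test_pool` the testing pool; groups are then sampled from each.
split_groups <- function(table, config, subject_seed) {
  train_idx <- integer(0); test_idx <- integer(0)
  for (lv in seq_len(config$scheme$n_levels)) {
    idx <- which(table$level == lv)
    need <- config$train_pool + config$test_pool
    if (length(idx) < need)
      stop("subject ", table$subject_id, ", level ", lv, ": only ",
           length(idx), " feature groups, need ", need)
    shuffled <- with_seed(split_seed(subject_seed, 500L + lv), sample(idx))
    pool_train <- shuffled[seq_len(config$train_pool)]
    pool_test <- shuffled[config$train_pool + seq_len(config$test_pool)]
    picked <- with_seed(split_seed(subject_seed, 600L + lv), list(
      train = sample(pool_train, config$train_groups),
      test = sample(pool_test, config$test_groups)))
    train_idx <- c(train_idx, picked$train)
    test_idx <- c(test_idx, picked$test)
  }
  list(train = train_idx, test = test_idx)
}

# Train and evaluate one subject; returns per-level accuracy (%), the
# confusion matrix, and (optionally) the force MAE per level.
evaluate_subject <- function(subject_index, config) {
  sseed <- split_seed(config$seed, subject_index)
  subject <- generate_subject(subject_index, config$acquisition, config$seed)
  table <- subject_feature_table(subject, config)
  split <- split_groups(table, config, sseed)
  x_train <- table$features[split$train, , drop = FALSE]
  x_test <- table$features[split$test, , drop = FALSE]
  y_train <- table$level[split$train]
  y_test <- table$level[split$test]
  f_train <- table$force[split$train]
  f_test <- table$force[split$test]
  pca <- NULL
  if (!is.na(config$pca_k)) {
    pca <- fit_pca(x_train, k = config$pca_k,
                   standardize = config$standardize_pca)
    x_train <- pca_transform(pca, x_train)
    x_test <- pca_transform(pca, x_test)
  }
  hyper <- config$hyper
  predictor <- train_force_predictor(
    x_train, y_train, forces = if (config$eval_regression) f_train,
    hyper = hyper, scheme = config$scheme,
    seed = split_seed(sseed, 900L),
    train_regressors = config$eval_regression)
  pred <- predict_level(predictor, x_test)
  k <- config$scheme$n_levels
  confusion <- matrix(0L, k, k,
                      dimnames = list(true = seq_len(k), pred = seq_len(k)))
  for (i in seq_along(y_test))
    confusion[y_test[i], pred$level[i]] <- confusion[y_test[i], pred$level[i]] + 1L
  acc <- vapply(seq_len(k), function(lv)
    100 * mean(pred$level[y_test == lv] == lv), numeric(1))
  mae <- rep(NA_real_, k)
  if (config$eval_regression) {
    pf <- predict_force(predictor, x_test)
    mae <- vapply(seq_len(k), function(lv)
      mean(abs(pf$force[y_test == lv] - f_test[y_test == lv])), numeric(1))
  }
  list(accuracy = acc, confusion = confusion, force_mae = mae,
       subject_id = subject$profile$subject_id, predictor = predictor,
       pca = pca)
}

#' Run the full evaluation experiment
#'
#' For each subject: generate the synthetic sessions, featurize, fit PCA
#' and the classifier (plus regressors when `eval_regression`) on the
#' training groups, and evaluate on the held-out testing groups. The
#' report aggregates per-level accuracy across subjects; the
#' between-subject SD is the sample SD of the per-subject accuracies and
#' the mean recognition rate is the mean over subjects of each subject's
#' mean accuracy over levels.
#'
#' @param config an [experiment_config()].
#' @return an object of class `evaluation_report`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  k <- config$scheme$n_levels
  acc <- matrix(NA_real_, config$n_subjects, k)
  mae <- matrix(NA_real_, config$n_subjects, k)
  confusion <- matrix(0L, k, k,
                      dimnames = list(true = seq_len(k), pred = seq_len(k)))
  subject_ids <- character(config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    t0 <- Sys.time()
    res <- evaluate_subject(s, config)
    acc[s, ] <- res$accuracy
    mae[s, ] <- res$force_mae
    confusion <- confusion + res$confusion
    subject_ids[s] <- res$subject_id
    if (config$verbose)
      message(sprintf("subject %s: mean accuracy %.1f%% (%.1f s)",
                      res$subject_id, mean(res$accuracy),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  rownames(acc) <- rownames(mae) <- subject_ids
  structure(list(
    accuracy = acc,
    level_mean = colMeans(acc),
    level_sd = apply(acc, 2, stats::sd),
    mean_accuracy = mean(rowMeans(acc)),
    confusion = confusion,
    force_mae = if (config$eval_regression) mae else NULL,
    mean_force_mae = if (config$eval_regression) mean(rowMeans(mae)) else NULL,
    groups_per_subject = k * (config$train_pool + config$test_pool),
    config = config),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  k <- length(x$level_mean)
  cat(sprintf("<evaluation_report> %d subjects x %d levels, %d groups/subject\n",
              nrow(x$accuracy), k, x$groups_per_subject))
  tab <- rbind(`mean accuracy (%)` = round(x$level_mean, 2),
               `between-subject SD (%)` = round(x$level_sd, 2))
  colnames(tab) <- paste0("L", seq_len(k))
  print(tab)
  cat(sprintf("mean recognition rate: %.2f%%\n", x$mean_accuracy))
  if (!is.null(x$mean_force_mae))
    cat(sprintf("mean force MAE: %.2f N\n", x$mean_force_mae))
  invisible(x)
}

#' Read an experiment configuration from a JSON file
#'
#' The file may set any argument of [experiment_config()]; the nested
#' objects `acquisition`, `window`, `scheme` and `hyper` are given as
#' objects whose fields are the arguments of [acquisition_config()],
#' [window_spec()], [level_scheme()] and [sae_hyperparams()]. Unset
#' fields keep their defaults.
#'
#' @param path JSON file path.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(fn, args) do.call(fn, as.list(args %||% list()))
  args <- raw[setdiff(names(raw), c("acquisition", "window", "scheme",
                                    "hyper"))]
  args$acquisition <- build(acquisition_config, raw$acquisition)
  args$window <- build(window_spec, raw$window)
  args$scheme <- build(level_scheme, raw$scheme)
  args$hyper <- build(sae_hyperparams, raw$hyper)
  do.call(experiment_config, args)
}

#' Compare experiment configurations on a paired cohort
#'
#' Runs each configuration (all must share the generator seed and the
#' level scheme, so the synthetic subjects are identical) and tabulates
#' per-level mean accuracy and between-subject SD.
#'
#' @param configs named list of [experiment_config()] objects.
#' @return data frame with columns `config`, `level`, `mean_accuracy`,
#'   `sd_accuracy`; the full reports are attached as attribute
#'   `"reports"`.
#' @export
compare_configs <- function(configs) {
  stopifnot(length(configs) >= 1L)
  if (is.null(names(configs)))
    names(configs) <- paste0("config", seq_along(configs))
  ref <- configs[[1L]]
  for (cfg in configs) {
    if (!identical(cfg$scheme, ref$scheme))
      stop_validation("all configs must share the level scheme")
    if (!identical(cfg$seed, ref$seed))
      stop_validation("all configs must share the generator seed")
  }
  reports <- lapply(configs, run_experiment)
  rows <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(config = nm, level = seq_along(r$level_mean),
               mean_accuracy = r$level_mean, sd_accuracy = r$level_sd)
  }))
  rownames(rows) <- NULL
  attr(rows, "reports") <- reports
  rows
}
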