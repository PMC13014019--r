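#' Default experiment configuration
#'
#' One place for every pipeline threshold and setting, with the study
#' defaults: CV threshold 15%, 0.1 Hz third-order zero-phase low-pass,
#' FDR 0.05, 8:2 split, 200-step diffusion schedule. The `cohort` block is
#' desk-scale by default (10 subjects per group x gender cell) so a full
#' run completes in minutes on one CPU; set the cell sizes to the study
#' cohort (57/28/54/28) for a paper-scale run. `diffusion$epochs` likewise
#' defaults to a reduced profile; the reference setting is 500.
#'
#' @param master_seed Master seed; every stochastic stage derives its own
#'   seed from it through a named substream.
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function(master_seed = 1) {
  structure(list(
    master_seed = master_seed,
    cohort = list(
      n_per_group = list(
        normal = c(female = 10, male = 10),
        ICPP = c(female = 10, male = 10)
      ),
      between_sd = 0.15
    ),
    preprocess = list(cv_threshold = 15, detrend_order = 1, cutoff = 0.1,
                      filter_order = 3, tddr = TRUE),
    glm = list(species = "hbo"),
    features = list(set_id = "A", n_pc = 3, n_imf = 3),
    split = list(train_frac = 0.8, unit = "subject"),
    classifier = list(family = "tree", n_folds = 10),
    diffusion = list(
      enabled = FALSE, n_steps = 200, beta_start = 0.001, beta_end = 0.02,
      epochs = 80, batch_size = 64, lr = 0.001, weight_decay = 0.01,
      hidden = c(96, 48)
    ),
    alpha = 0.05
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- default_config(usr$master_seed %||% 1)
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        merge_into(base[[nm]], upd[[nm]])
      } else {
        upd[[nm]]
      }
    }
    base
  }
  merge_into(cfg, usr)
}

#' Run the full experiment pipeline
#'
#' Executes the complete workflow on a simulated cohort: simulate raw
#' intensities, QC-screen, preprocess to hemoglobin, fit the channel-wise
#' GLM, compute paired (task vs rest) and group-contrast stat maps per
#' gender, segment trials, fit the feature state on the training split,
#' extract features, optionally train the conditional diffusion model on
#' the real training segments and augment the training set, train the
#' classifier by grid-search cross-validation, and evaluate on the
#' held-out real test set.
#'
#' @param config A `pipeline_config` (see [default_config()]).
#' @return A list of class `experiment_result` with elements `config`,
#'   `qc`, `activation` (paired/group stat maps), `features`, `split`
#'   sizes, `eval` (an `eval_report`), `eval_augmented` (when diffusion is
#'   enabled), `cddpm` (training glance), and `manifest` (seeds and stage
#'   provenance).
#' @export
run_experiment <- function(config = default_config()) {
  ms <- config$master_seed
  stage_seed <- function(stage) derive_seed(ms, stage)
  paradigm <- build_paradigm()

  cohort <- sample_cohort(
    n_per_group = config$cohort$n_per_group,
    between_sd = config$cohort$between_sd,
    paradigm = paradigm,
    seed = stage_seed("cohort")
  )
  prep <- preprocess_cohort(cohort,
    detrend_order = config$preprocess$detrend_order,
    cutoff = config$preprocess$cutoff,
    filter_order = config$preprocess$filter_order,
    tddr = config$preprocess$tddr
  )
  meta <- cohort$subjects[cohort$subjects$subject_id %in% prep$kept, ]

  species <- config$glm$species
  cg <- cohort_glm(prep$hemo, paradigm, species = species)
  maps <- list()
  for (g in unique(meta$gender)) {
    for (grp in unique(meta$group)) {
      rows <- meta$subject_id[meta$gender == g & meta$group == grp]
      if (length(rows) >= 2) {
        maps[[paste("paired", grp, g, sep = "_")]] <-
          paired_t_map(cg$beta_ma[rows, , drop = FALSE],
                       cg$beta_rest[rows, , drop = FALSE],
                       alpha = config$alpha)
      }
    }
    a <- meta$subject_id[meta$gender == g & meta$group == "normal"]
    b <- meta$subject_id[meta$gender == g & meta$group == "ICPP"]
    if (length(a) >= 2 && length(b) >= 2) {
      maps[[paste("group", g, sep = "_")]] <-
        group_t_map(cg$beta_ma[a, , drop = FALSE], cg$beta_ma[b, , drop = FALSE],
                    alpha = config$alpha)
    }
  }

  labels_by_subject <- stats::setNames(
    as.integer(meta$group == "ICPP"), meta$subject_id
  )
  segments <- purrr::list_flatten(purrr::map(prep$hemo, function(h) {
    segment_trials(h, paradigm, species = species,
                   label = labels_by_subject[[h$subject_id]])
  }))
  seg_tbl <- tibble::tibble(
    idx = seq_along(segments),
    subject_id = purrr::map_chr(segments, "subject_id"),
    label = purrr::map_dbl(segments, ~ as.numeric(.x$label))
  )
  split <- split_dataset(seg_tbl,
    train_frac = config$split$train_frac,
    unit = config$split$unit, seed = stage_seed("split")
  )
  train_segs <- segments[split$train$idx]
  test_segs <- segments[split$test$idx]

  state <- fit_feature_state(train_segs,
    sets = config$features$set_id,
    n_pc = config$features$n_pc, n_imf = config$features$n_imf
  )
  feat_train <- extract_features(train_segs, config$features$set_id, state)
  feat_test <- extract_features(test_segs, config$features$set_id, state)

  clf <- tune_and_train(feat_train,
    family = config$classifier$family,
    n_folds = config$classifier$n_folds, seed = stage_seed("classifier")
  )
  ev <- evaluate(clf, feat_test)

  ev_aug <- NULL
  dm_glance <- NULL
  if (isTRUE(config$diffusion$enabled)) {
    dcfg <- config$diffusion
    tdesign <- trial_design(ncol(train_segs[[1]]$data))
    beta_tr <- do.call(rbind, lapply(train_segs, trial_beta, design = tdesign))
    dm <- train_cddpm(train_segs,
      labels = split$train$label, beta = beta_tr,
      schedule = make_schedule(dcfg$n_steps, dcfg$beta_start, dcfg$beta_end),
      epochs = dcfg$epochs, batch_size = dcfg$batch_size, lr = dcfg$lr,
      weight_decay = dcfg$weight_decay, hidden = dcfg$hidden,
      seed = stage_seed("diffusion")
    )
    check_no_leakage(dm, test_segs)
    aug <- augment_train_set(train_segs, dm, seed = stage_seed("augment"))
    for (i in seq_along(aug$segments)) aug$segments[[i]]$label <- aug$labels[i]
    state_aug <- fit_feature_state(aug$segments, sets = config$features$set_id,
                                   n_pc = config$features$n_pc,
                                   n_imf = config$features$n_imf)
    feat_aug <- extract_features(aug$segments, config$features$set_id, state_aug)
    feat_test_aug <- extract_features(test_segs, config$features$set_id, state_aug)
    clf_aug <- tune_and_train(feat_aug,
      family = config$classifier$family,
      n_folds = config$classifier$n_folds, seed = stage_seed("classifier")
    )
    ev_aug <- evaluate(clf_aug, feat_test_aug)
    dm_glance <- glance(dm)
  }

  structure(
    list(
      config = config,
      qc = list(kept = prep$kept, discarded = prep$discarded),
      activation = maps,
      n_train = nrow(feat_train), n_test = nrow(feat_test),
      eval = ev, eval_augmented = ev_aug, cddpm = dm_glance,
      manifest = list(
        master_seed = ms,
        stage_seeds = c(
          cohort = stage_seed("cohort"), split = stage_seed("split"),
          classifier = stage_seed("classifier"),
          diffusion = stage_seed("diffusion"), augment = stage_seed("augment")
        ),
        species = species, feature_set = config$features$set_id,
        package_version = as.character(utils::packageVersion("nirsicpp"))
      )
    ),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> feature set %s, %s classifier; %d train / %d test trials\n",
    x$manifest$feature_set, x$eval$family, x$n_train, x$n_test
  ))
  cat(sprintf("  accuracy %.2f%%, specificity %.2f%%\n",
              x$eval$accuracy, x$eval$specificity))
  if (!is.null(x$eval_augmented)) {
    cat(sprintf("  augmented: accuracy %.2f%%, specificity %.2f%%\n",
                x$eval_augmented$accuracy, x$eval_augmented$specificity))
  }
  invisible(x)
}

#' Write the report bundle of an experiment
#'
#' Emits per-channel activation TSVs (one per stat map), the evaluation
#' metrics as JSON (two-decimal percent formatting in a companion TSV),
#' and the provenance manifest.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
make_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$activation)) {
    write_stat_map_tsv(result$activation[[nm]],
                       file.path(dir, paste0("activation_", nm, ".tsv")))
  }
  metrics <- dplyr::bind_rows(
    dplyr::mutate(result$eval, dataset = "real"),
    if (!is.null(result$eval_augmented)) {
      dplyr::mutate(result$eval_augmented, dataset = "real+synthetic")
    }
  )
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  fmt <- dplyr::mutate(metrics, dplyr::across(
    c("accuracy", "precision", "recall", "f1", "specificity"),
    ~ sprintf("%.2f", .x)
  ))
  readr::write_tsv(fmt, file.path(dir, "metrics.tsv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
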