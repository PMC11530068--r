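#' Experiment variants M1-M5
#'
#' M1 trains on homogeneous data only; M2 adds the mixture training set
#' unmodified; M3 adds Borderline-SMOTE synthesis (M3s the plain SMOTE
#' variant); M4 adds random oversampling; M5 runs ENN editing before
#' random oversampling.
#'
#' @param id one of `"M1"`, `"M2"`, `"M3"`, `"M3s"`, `"M4"`, `"M5"`.
#' @return list with `id`, `uses_hetero`, `resample_method`.
#' @export
experiment_variant <- function(id = c("M1", "M2", "M3", "M3s", "M4", "M5")) {
  id <- match.arg(id)
  method <- switch(id, M1 = "none", M2 = "none", M3 = "borderline_smote",
                   M3s = "smote", M4 = "random_os",
                   M5 = "enn_then_random_os")
  list(id = id, uses_hetero = id != "M1", resample_method = method)
}

#' Configuration of one full experiment run
#'
#' @param data_dir dataset directory containing `manifest.csv` (as
#'   written by [generate_dataset()]).
#' @param out_dir run directory for all artifacts.
#' @param variant an [experiment_variant()] (or its id string).
#' @param model a [model_config()].
#' @param delta_os per-ratio oversampling increments for OS variants.
#' @param knn_k KNN neighborhood size for SMOTE/ENN.
#' @param K number of cross-validation folds.
#' @param seed master seed for splitting and resampling.
#' @param embedding [feature_embedding()] for the KNN operators.
#' @return object of class `mixshape_run_config`.
#' @export
run_config <- function(data_dir, out_dir, variant = "M1",
                       model = model_config(),
                       delta_os = c("1:2" = 256, "2:1" = 128,
                                    "1:3" = 256, "3:1" = 256),
                       knn_k = 3, K = 5, seed = 1L,
                       embedding = feature_embedding()) {
  if (is.character(variant)) variant <- experiment_variant(variant)
  structure(list(data_dir = data_dir, out_dir = out_dir, variant = variant,
                 model = model, delta_os = delta_os, knn_k = knn_k,
                 K = as.integer(K), seed = as.integer(seed),
                 embedding = embedding),
            class = "mixshape_run_config")
}

preprocess_all <- function(records, input_size) {
  lapply(records, preprocess_image, target_size = input_size)
}

records_by_id <- function(records, manifest) {
  stats::setNames(records, manifest$path)
}

assert_no_leakage <- function(train_ids, test_ids, stage) {
  bad <- intersect(train_ids, test_ids)
  if (length(bad))
    stop("test-set leakage into ", stage, ": ",
         paste(utils::head(bad, 3), collapse = ", "))
  invisible(TRUE)
}

#' Run one experiment end to end
#'
#' Executes the full framework: 20% homogeneous hold-out plus K-fold
#' cross-validation, a single 64:16:20 mixture split, per-fold training
#' on the homogeneous fold training set (plus the resampled mixture
#' training set for variants that use it), per-fold validation metrics
#' (classification metrics on homogeneous data, soft-label RMSE on
#' mixtures), and test-set evaluation through the K-model bagging
#' ensemble. All artifacts (split plan, fold models, logs, metric
#' tables, resampling audit) are written under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return invisible list of run artifacts and summary metrics.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "mixshape_run_config"))
  variant <- config$variant
  manifest <- read_manifest(config$data_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$out_dir, "models"), showWarnings = FALSE)

  input_size <- config$model$input_size
  all_records <- records_by_id(
    preprocess_all(load_records(manifest, config$data_dir), input_size),
    manifest)

  homo_split <- split_homo(manifest, K = config$K, seed = config$seed)
  has_hetero <- any(vapply(manifest$tag, is_ratio_tag, logical(1)))
  if (variant$uses_hetero && !has_hetero)
    stop("variant ", variant$id,
         " requires mixture (HETERO) data but the manifest has none")
  het_split <- if (has_hetero)
    split_hetero(manifest, seed = child_seed(config$seed, 1)) else NULL
  plan_out <- homo_split
  plan_out$hetero <- het_split
  write_split_plan(plan_out, file.path(config$out_dir, "split.json"))

  test_ids <- c(homo_split$test_ids, het_split$test_ids)
  val_rows <- NULL
  audits <- NULL
  models <- vector("list", config$K)
  het_val_recs <- if (has_hetero) all_records[het_split$val_ids] else list()
  for (k in seq_len(config$K)) {
    fold <- homo_split$folds[[k]]
    train_recs <- all_records[fold$train]
    if (variant$uses_hetero) {
      het_train <- all_records[het_split$train_ids]
      pool <- c(train_recs, het_train)
      if (variant$resample_method != "none") {
        plan <- resample_plan(variant$resample_method,
                              delta_os = config$delta_os,
                              knn_k = config$knn_k,
                              seed = child_seed(config$seed, 100 + k))
        rs <- apply_plan(pool, plan, embedding = config$embedding)
        pool <- rs$records
        audits <- rbind(audits, cbind(fold = k, rs$audit))
      }
      train_recs <- pool
    }
    train_ids_used <- vapply(train_recs, function(r) r$source, character(1))
    assert_no_leakage(train_ids_used, test_ids, paste0("fold ", k, " training"))
    assert_no_leakage(train_ids_used,
                      c(fold$val, het_split$val_ids),
                      paste0("fold ", k, " training (validation ids)"))

    mcfg <- config$model
    mcfg$seed <- child_seed(config$model$seed, k)
    model <- build_model(mcfg)
    model <- train_fold(model, train_recs, all_records[fold$val],
                        fold_id = k)
    save_model(model, file.path(config$out_dir, "models",
                                sprintf("fold_%d.rds", k)))
    utils::write.csv(model$log,
                     file.path(config$out_dir, "models",
                               sprintf("fold_%d_log.csv", k)),
                     row.names = FALSE)
    models[[k]] <- model

    val_recs <- all_records[fold$val]
    vp <- predict_soft(model, val_recs)
    vt <- t(labels_to_matrix(val_recs))
    mm <- macro_metrics(confusion(vt, vp), vp, vt)
    het_rmse <- if (has_hetero && length(het_val_recs))
      rmse_soft(t(labels_to_matrix(het_val_recs)),
                predict_soft(model, het_val_recs)) else NA_real_
    val_rows <- rbind(val_rows, data.frame(
      fold = k, accuracy = mm$accuracy,
      macro_sensitivity = mm$macro_sensitivity,
      macro_precision = mm$macro_precision,
      macro_f1 = mm$macro_f1, macro_auc = mm$macro_auc,
      hetero_rmse = het_rmse))
  }
  utils::write.csv(val_rows, file.path(config$out_dir, "val_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(audits))
    utils::write.csv(audits, file.path(config$out_dir, "resample_audit.csv"),
                     row.names = FALSE)

  # --- ensemble evaluation on the held-out test sets ---
  homo_test <- all_records[homo_split$test_ids]
  ens <- ensemble_predict(models, homo_test)
  tt <- t(labels_to_matrix(homo_test))
  test_mm <- macro_metrics(confusion(tt, ens$aggregate), ens$aggregate, tt)
  test_row <- data.frame(accuracy = test_mm$accuracy,
                         macro_sensitivity = test_mm$macro_sensitivity,
                         macro_precision = test_mm$macro_precision,
                         macro_f1 = test_mm$macro_f1,
                         macro_auc = test_mm$macro_auc)
  het_summary <- NULL
  dom <- NULL
  het_test_rmse <- NA_real_
  if (has_hetero && length(het_split$test_ids)) {
    het_test <- all_records[het_split$test_ids]
    het_tags <- vapply(het_test, function(r) r$tag, character(1))
    hens <- ensemble_predict(models, het_test)
    het_test_rmse <- rmse_soft(t(labels_to_matrix(het_test)),
                               hens$aggregate)
    props <- NULL
    for (tg in intersect(RATIO_TAGS, unique(het_tags))) {
      rows <- het_tags == tg
      props <- rbind(props, data.frame(
        ratio = tg,
        parental_pct = mean(hens$aggregate[rows, "PARENTAL"]) * 100,
        resistant_pct = mean(hens$aggregate[rows, "RESISTANT"]) * 100,
        control_pct = mean(hens$aggregate[rows, "CONTROL"]) * 100))
    }
    het_summary <- props
    da <- dominant_accuracy(het_tags, hens$aggregate)
    dom <- data.frame(ratio = names(da), accuracy_pct = as.numeric(da))
    utils::write.csv(props, file.path(config$out_dir, "proportions.csv"),
                     row.names = FALSE)
    utils::write.csv(dom, file.path(config$out_dir, "dominant.csv"),
                     row.names = FALSE)
  }
  test_row$hetero_rmse <- het_test_rmse
  utils::write.csv(test_row, file.path(config$out_dir, "test_metrics.csv"),
                   row.names = FALSE)
  cfg_json <- list(variant = variant, data_dir = config$data_dir,
                   delta_os = as.list(config$delta_os),
                   knn_k = config$knn_k, K = config$K, seed = config$seed,
                   model = list(backbone = config$model$backbone,
                                input_size = config$model$input_size,
                                batch_size = config$model$batch_size,
                                epochs = config$model$epochs,
                                seed = config$model$seed))
  jsonlite::write_json(cfg_json, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(out_dir = config$out_dir, models = models,
                 val_metrics = val_rows, test_metrics = test_row,
                 proportions = het_summary, dominant = dom,
                 audit = audits, split = plan_out))
}

#' Random-search tuning of the oversampling increments
#'
#' Draws `n_draws` candidate increment maps uniformly from the grid
#' (default 64 to 384 in steps of 64, giving 6^4 = 1296 joint
#' candidates), scores each by the mean K-fold validation RMSE on the
#' mixture data, and returns the argmin with the full trace.
#'
#' @param config a [run_config()] whose variant uses oversampling.
#' @param grid candidate increment values.
#' @param n_draws number of random candidates.
#' @param seed search seed.
#' @return list `best` (named increments), `best_rmse`, `trace`
#'   (data.frame of candidates and scores).
#' @export
tune_deltas <- function(config, grid = seq(64, 384, by = 64),
                        n_draws = 30, seed = 1L) {
  stopifnot(inherits(config, "mixshape_run_config"))
  if (length(grid) == 0) stop("empty search domain")
  if (!(config$variant$resample_method %in%
        c("random_os", "smote", "borderline_smote", "enn_then_random_os")))
    stop("variant ", config$variant$id, " has no oversampling to tune")
  cands <- with_seed_ms(seed, {
    lapply(seq_len(n_draws), function(i)
      stats::setNames(sample(grid, 4, replace = TRUE), RATIO_TAGS))
  })
  trace <- NULL
  best <- NULL; best_rmse <- Inf
  for (i in seq_along(cands)) {
    ci <- config
    ci$delta_os <- cands[[i]]
    ci$out_dir <- file.path(config$out_dir, sprintf("tune_%03d", i))
    res <- run_experiment(ci)
    score <- mean(res$val_metrics$hetero_rmse)
    trace <- rbind(trace, data.frame(
      draw = i, t(cands[[i]]), mean_val_rmse = score,
      check.names = FALSE))
    if (is.finite(score) && score < best_rmse) {
      best_rmse <- score; best <- cands[[i]]
    }
  }
  list(best = best, best_rmse = best_rmse, trace = trace)
}

# red-yellow overlay of a Grad-CAM heatmap on a grayscale image
cam_overlay <- function(image, cam, alpha = 0.5) {
  gray <- if (length(dim(image)) == 3) apply(image, c(1, 2), mean) else image
  H <- nrow(gray); W <- ncol(gray)
  out <- array(0, c(H, W, 3))
  heat_r <- matrix(pmin(1, 2 * cam), H, W)
  heat_g <- matrix(pmax(0, 2 * cam - 1), H, W)
  out[, , 1] <- (1 - alpha) * gray + alpha * heat_r
  out[, , 2] <- (1 - alpha) * gray + alpha * heat_g
  out[, , 3] <- (1 - alpha) * gray
  array(pmin(1, pmax(0, out)), dim(out))
}

#' Summarize a completed run into report tables and a Grad-CAM gallery
#'
#' Validation metrics are reported as Mean(SE) across folds; test
#' metrics come from the ensemble and carry no SE. The mixture
#' proportion table is ordered 1:2, 2:1, 1:3, 3:1. The gallery holds one
#' original plus one heatmap overlay per sampled test class.
#'
#' @param run_dir directory written by [run_experiment()].
#' @param gallery_n sampled test images per class for Grad-CAM (0 to
#'   skip).
#' @param seed sampling seed for the gallery.
#' @return list of report tables (also written as CSV under
#'   `run_dir/report/`).
#' @export
report_run <- function(run_dir, gallery_n = 1, seed = 1L) {
  need <- c("val_metrics.csv", "test_metrics.csv", "split.json",
            "config.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run; missing artifacts: ",
         paste(missing, collapse = ", "))
  rep_dir <- file.path(run_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  val <- utils::read.csv(file.path(run_dir, "val_metrics.csv"))
  mets <- setdiff(names(val), "fold")
  mean_se <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return("NA")
    sprintf("%.2f (%.2f)", mean(x), stats::sd(x) / sqrt(length(x)))
  }
  val_tab <- data.frame(metric = mets,
                        mean_se = vapply(val[mets], mean_se, character(1)))
  test_tab <- utils::read.csv(file.path(run_dir, "test_metrics.csv"))
  out <- list(validation = val_tab, test = test_tab)
  pf <- file.path(run_dir, "proportions.csv")
  if (file.exists(pf)) {
    props <- utils::read.csv(pf, colClasses = c(ratio = "character"))
    props <- props[order(match(props$ratio, RATIO_TAGS)), ]
    out$proportions <- props
    dom <- utils::read.csv(file.path(run_dir, "dominant.csv"),
                           colClasses = c(ratio = "character"))
    out$dominant <- dom[order(match(dom$ratio, RATIO_TAGS)), ]
    utils::write.csv(out$proportions,
                     file.path(rep_dir, "proportions.csv"),
                     row.names = FALSE)
    utils::write.csv(out$dominant, file.path(rep_dir, "dominant.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(val_tab, file.path(rep_dir, "validation_mean_se.csv"),
                   row.names = FALSE)
  utils::write.csv(test_tab, file.path(rep_dir, "test_metrics.csv"),
                   row.names = FALSE)
  if (gallery_n > 0) {
    cfg <- jsonlite::read_json(file.path(run_dir, "config.json"),
                               simplifyVector = TRUE)
    model <- load_model(file.path(run_dir, "models", "fold_1.rds"))
    split <- read_split_plan(file.path(run_dir, "split.json"))
    data_dir <- cfg$data_dir
    manifest <- if (!is.null(data_dir) &&
                    file.exists(file.path(data_dir, "manifest.csv")))
      read_manifest(data_dir) else NULL
    if (!is.null(manifest)) {
      test_rows <- manifest[manifest$path %in% unlist(split$test_ids), ]
      with_seed_ms(seed, {
        for (cl in intersect(CLASS_NAMES, unique(test_rows$tag))) {
          ids <- test_rows$path[test_rows$tag == cl]
          pick <- sample(ids, min(gallery_n, length(ids)))
          recs <- load_records(
            manifest[manifest$path %in% pick, , drop = FALSE], data_dir)
          recs <- preprocess_all(recs, model$config$input_size)
          for (i in seq_along(recs)) {
            cam <- grad_cam(model, recs[[i]], cl)
            base <- gsub("\\.[a-z]+$", "", pick[i])
            png::writePNG(recs[[i]]$image,
                          file.path(rep_dir, paste0(base, "_orig.png")))
            png::writePNG(cam_overlay(recs[[i]]$image, cam),
                          file.path(rep_dir, paste0(base, "_cam.png")))
          }
        }
      })
    }
  }
  out
}
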