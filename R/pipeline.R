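#' Run the full analysis pipeline
#'
#' Executes the whole chain on a set of photographs and a long-format
#' rating table: feature extraction, IRCS scoring, per-photo aggregation,
#' greenery correlations, standardization, VIF pruning with the square root
#' of greenery protected, a seeded train/test split, 10-fold
#' cross-validated lasso with the one-standard-error rule for each of the
#' four outcomes, and train/test RMSE evaluation. When `out_dir` is given,
#' every intermediate is persisted (CSV/JSON) together with the resolved
#' configuration.
#'
#' @param images List of [raster_image] objects, or a directory of
#'   PNG/JPEG files. May also be a pre-computed feature tibble (the output
#'   of [extract_features_batch()]), in which case extraction is skipped.
#' @param ratings Long-format rating table (`participant_id`, `photo_id`,
#'   `item_id`, `response`) or a CSV path.
#' @param config A [feature_config].
#' @param scale An [ircs_scale()] definition.
#' @param seed Integer seed driving the split and fold assignment.
#' @param n_test Number of photos held out as test data (default 10).
#' @param vif_threshold VIF threshold for iterative pruning (default 5).
#' @param protected Features never removed by pruning.
#' @param out_dir Optional output directory for persisted intermediates.
#' @return List with `features`, `photo_scores`, `correlations`,
#'   `vif_report`, `split`, `cv` (per outcome), `models` (1-SE models per
#'   outcome), and `rmse` (train/test per outcome).
#' @export
run_full_pipeline <- function(images, ratings, config = feature_config(),
                              scale = ircs_scale(), seed = 1, n_test = 10,
                              vif_threshold = 5,
                              protected = "sqrt_greenery",
                              out_dir = NULL) {
  features <- if (is.data.frame(images)) tibble::as_tibble(images)
              else extract_features_batch(images, config)
  if (is.character(ratings)) ratings <- read_features(ratings)
  unknown <- setdiff(unique(ratings$photo_id), features$source_id)
  if (length(unknown))
    stop("ratings reference unknown photo_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))

  scores <- score_ratings(ratings, scale)
  photo_scores <- aggregate_by_photo(
    scores[, c("photo_id", "being_away", "fascination", "extent", "overall")])

  feat_tab <- dplyr::rename(features, photo_id = "source_id")
  correlations <- sqrt_greenery_correlations(feat_tab, photo_scores)

  X_raw <- as.matrix(feat_tab[, feature_names()])
  rownames(X_raw) <- feat_tab$photo_id
  keep <- apply(X_raw, 2, stats::sd) > 0
  X_raw <- X_raw[, keep, drop = FALSE]
  Z <- standardize(X_raw)
  vif_report <- vif_prune(Z, threshold = vif_threshold,
                          protected = intersect(protected, colnames(Z)))
  Zp <- Z[, vif_report$retained, drop = FALSE]
  attr(Zp, "center") <- attr(Z, "center")[vif_report$retained]
  attr(Zp, "scale") <- attr(Z, "scale")[vif_report$retained]

  split <- split_train_test(feat_tab$photo_id, n_test = n_test, seed = seed)
  tr <- rownames(Zp) %in% split$train_ids
  outcomes <- c("overall", "being_away", "fascination", "extent")
  ord <- match(rownames(Zp), photo_scores$photo_id)
  cv <- list(); models <- list(); rmse <- list()
  for (oc in outcomes) {
    y <- photo_scores[[paste0(oc, "_mean")]][ord]
    Ztr <- Zp[tr, , drop = FALSE]
    attr(Ztr, "center") <- attr(Zp, "center")
    attr(Ztr, "scale") <- attr(Zp, "scale")
    cv[[oc]] <- cv_lasso(Ztr, y[tr], seed = seed, outcome = oc)
    models[[oc]] <- cv[[oc]]$model_1se
    rmse[[oc]] <- c(
      train = evaluate_rmse(models[[oc]], Zp[tr, , drop = FALSE], y[tr]),
      test = if (n_test > 0)
        evaluate_rmse(models[[oc]], Zp[!tr, , drop = FALSE], y[!tr])
      else NA_real_)
  }

  result <- list(features = features, photo_scores = photo_scores,
                 correlations = correlations, vif_report = vif_report,
                 split = split, cv = cv, models = models, rmse = rmse,
                 seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_features(features, file.path(out_dir, "features.csv"))
    utils::write.csv(photo_scores, file.path(out_dir, "photo_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(vif_report$removal_trace,
                     file.path(out_dir, "vif_removal_trace.csv"),
                     row.names = FALSE)
    for (oc in outcomes) {
      write_model(models[[oc]], file.path(out_dir, paste0("model_", oc, ".json")))
      utils::write.csv(cv[[oc]]$cv_table,
                       file.path(out_dir, paste0("cv_curve_", oc, ".csv")),
                       row.names = FALSE)
    }
    write_config(config, file.path(out_dir, "config.json"))
    jsonlite::write_json(
      list(seed = seed, n_photos = nrow(features),
           n_ratings = nrow(ratings),
           train_ids = split$train_ids, test_ids = split$test_ids,
           retained_features = vif_report$retained),
      file.path(out_dir, "run_metadata.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
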