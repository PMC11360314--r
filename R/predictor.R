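# ddG regressor: inverse-mutation augmentation, 10-fold ensemble of
# gradient-boosted regression trees (xgboost members), grid search on mean
# validation PCC, and prediction averaging.

#' Augment a mutation table with inverse mutations
#'
#' Emits two rows per direct record: the original and its inverse partner
#' with wild-type/mutant swapped and the label negated. Partners share a
#' `pair_id`.
#'
#' @param records data.frame with `structure_id`, `position`, `wt_aa`,
#'   `mut_aa` and optionally `ddg_exp`.
#' @return data.frame with 2N rows and columns `pair_id`, `is_inverse`.
#' @export
augment_with_inverse <- function(records) {
  n <- nrow(records)
  direct <- records
  direct$pair_id <- seq_len(n)
  direct$is_inverse <- FALSE
  inverse <- records
  inverse$pair_id <- seq_len(n)
  inverse$is_inverse <- TRUE
  wt <- inverse$wt_aa
  inverse$wt_aa <- inverse$mut_aa
  inverse$mut_aa <- wt
  if ("ddg_exp" %in% names(records)) inverse$ddg_exp <- -inverse$ddg_exp
  out <- rbind(direct, inverse)
  ord <- order(out$pair_id, out$is_inverse)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hyperparameter grids for the boosted-tree members
#'
#' The full grid matches the published search space; the reduced grid is
#' the desk-scale default.
#'
#' @param reduced Use the reduced desk-scale grid.
#' @return data.frame of hyperparameter combinations.
#' @export
boost_grid <- function(reduced = TRUE) {
  if (reduced) {
    expand.grid(n_estimators = c(200L, 500L), max_depth = c(5L, 6L),
                subsample = 0.7, colsample_bytree = 0.56, learning_rate = 0.1)
  } else {
    expand.grid(n_estimators = c(10000L, 20000L, 30000L),
                max_depth = c(5L, 6L, 7L), subsample = c(0.6, 0.7, 0.8),
                colsample_bytree = c(0.55, 0.56, 0.57),
                learning_rate = c(0.02, 0.05, 0.1))
  }
}

pair_folds <- function(pair_id, nfolds, seed) {
  pairs <- unique(pair_id)
  set.seed(seed)
  shuffled <- sample(pairs)
  fold_of_pair <- stats::setNames(rep_len(seq_len(nfolds), length(pairs)),
                                  shuffled)
  as.integer(fold_of_pair[as.character(pair_id)])
}

fit_member <- function(X_tr, y_tr, X_val, y_val, hp, seed,
                       early_stopping_rounds = 20L) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X_tr, label = y_tr)
  dval <- xgboost::xgb.DMatrix(X_val, label = y_val)
  params <- list(objective = "reg:squarederror", max_depth = hp$max_depth,
                 eta = hp$learning_rate, subsample = hp$subsample,
                 colsample_bytree = hp$colsample_bytree, nthread = 1,
                 tree_method = "hist", max_bin = 128)
  xgboost::xgb.train(params, dtrain, nrounds = hp$n_estimators,
                     evals = list(val = dval),
                     early_stopping_rounds = early_stopping_rounds,
                     verbose = 0)
}

#' Train the ten-fold boosted-tree ensemble
#'
#' Rows are split into ten folds with direct/inverse partners kept in the
#' same fold. For each grid combination, ten members are trained (each on
#' nine folds, validated on the remaining one); the combination with the
#' best mean validation PCC wins and its ten members form the ensemble.
#' Standardization is fit on the full training matrix and stored with the
#' model.
#'
#' @param X Raw (unstandardized) feature matrix.
#' @param y ddG labels (kcal/mol).
#' @param pair_id Integer pair identifiers (direct/inverse partners share one).
#' @param grid Hyperparameter grid from [boost_grid()].
#' @param seed RNG seed (fold assignment and member fitting).
#' @param nfolds Number of folds/members.
#' @param metric Selection metric: "pcc" or "rmse".
#' @return An `EnsembleModel` (members stored as serialized boosters).
#' @export
train_ensemble <- function(X, y, pair_id = seq_len(nrow(X)),
                           grid = boost_grid(), seed = 1L, nfolds = 10L,
                           metric = c("pcc", "rmse")) {
  metric <- match.arg(metric)
  if (nrow(X) < 2 * nfolds) stop("need at least ", 2 * nfolds, " rows for ",
                                 nfolds, "-fold training")
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  folds <- pair_folds(pair_id, nfolds, seed)
  if (length(unique(folds)) < nfolds) stop("fewer pairs than folds")
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    hp <- grid[g, ]
    members <- vector("list", nfolds)
    scores <- numeric(nfolds)
    for (k in seq_len(nfolds)) {
      tr <- folds != k
      m <- fit_member(Xs[tr, , drop = FALSE], y[tr],
                      Xs[!tr, , drop = FALSE], y[!tr], hp,
                      seed = seed + 1000L * g + k)
      pv <- predict(m, xgboost::xgb.DMatrix(Xs[!tr, , drop = FALSE]))
      scores[k] <- if (metric == "pcc") {
        suppressWarnings(stats::cor(pv, y[!tr]))
      } else {
        -sqrt(mean((pv - y[!tr])^2))
      }
      # members are kept as serialized boosters; freeing the live handle
      # caps the memory of the grid search at one model
      members[[k]] <- xgboost::xgb.save.raw(m)
      rm(m)
      gc(verbose = FALSE)
    }
    mean_score <- mean(scores, na.rm = TRUE)
    if (is.null(best) || mean_score > best$score) {
      best <- list(score = mean_score, members = members, hp = hp,
                   fold_scores = scores)
    }
  }
  structure(list(members = best$members, scaler = scaler,
                 hyperparameters = best$hp, folds = folds,
                 validation_score = best$score, metric = metric,
                 seed = seed),
            class = "EnsembleModel")
}

#' Predict ddG with the ensemble
#'
#' Arithmetic mean of the ten members' predictions on the scaled features.
#'
#' @param model An `EnsembleModel`.
#' @param features Raw feature vector or matrix (rows = mutations).
#' @return Predicted ddG (kcal/mol), one value per row.
#' @export
predict_ddg <- function(model, features) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model$scaler$mean)) {
    stop("feature length ", ncol(features), " does not match training (",
         length(model$scaler$mean), ")")
  }
  Xs <- apply_scaler(model$scaler, features)
  dm <- xgboost::xgb.DMatrix(Xs)
  preds <- vapply(model$members, function(m) {
    booster <- xgboost::xgb.load.raw(m)
    p <- predict(booster, dm)
    rm(booster)
    p
  }, numeric(nrow(Xs)))
  gc(verbose = FALSE)
  if (nrow(Xs) == 1) mean(preds) else rowMeans(preds)
}

#' @export
print.EnsembleModel <- function(x, ...) {
  cat(sprintf("EnsembleModel: %d boosted-tree members, %s=%.3f (validation)\n",
              length(x$members), x$metric, x$validation_score))
  cat(" hyperparameters:",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}
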