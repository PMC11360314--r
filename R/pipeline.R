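# End-to-end pipeline on a labelled mutation dataset: featurize, split by
# direct/inverse pair, train the ensemble, and evaluate held-out accuracy
# and anti-symmetry bias.

#' Run the full ddG pipeline on a labelled dataset
#'
#' Featurizes every record (direct + inverse rows), holds out a fraction of
#' the pairs, trains the ten-fold ensemble on the remainder, and evaluates
#' the held-out predictions including the bias metrics.
#'
#' @param records Mutation records (direct) with `ddg_exp`.
#' @param structures Named list of wild-type structures.
#' @param encoder Trained `EncoderState`.
#' @param library Rotamer library.
#' @param holdout_fraction Fraction of pairs held out for testing.
#' @param grid Hyperparameter grid.
#' @param seed RNG seed (split, folds, members).
#' @param n_points SASA quadrature points during featurization.
#' @return List with `model`, `report` (held-out `EvalReport`),
#'   `predictions` (held-out table), `features`.
#' @export
run_ddg_pipeline <- function(records, structures, encoder,
                             library = default_rotamer_library(),
                             holdout_fraction = 0.2, grid = boost_grid(),
                             seed = 1L, n_points = 100L) {
  feats <- featurize_dataset(records, structures, encoder, library,
                             n_points = n_points)
  meta <- feats$meta
  pairs <- unique(meta$pair_id)
  set.seed(seed)
  n_test <- max(1L, floor(length(pairs) * holdout_fraction))
  test_pairs <- sample(pairs, n_test)
  te <- meta$pair_id %in% test_pairs
  model <- train_ensemble(feats$X[!te, , drop = FALSE], meta$ddg[!te],
                          pair_id = meta$pair_id[!te], grid = grid,
                          seed = seed)
  pred <- predict_ddg(model, feats$X[te, , drop = FALSE])
  predictions <- cbind(meta[te, , drop = FALSE], pred = pred)
  list(model = model, report = evaluate(predictions),
       predictions = predictions, features = feats)
}
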