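#' Fit the tree ensemble used for SHAP importances
#'
#' Gradient-boosted trees (100 estimators, depth 3, learning rate 0.1,
#' balanced class weighting via the positive-class scale factor), seeded and
#' single-threaded for reproducibility.
#'
#' @param X numeric feature matrix (samples x features, named columns).
#' @param y binary labels (0/1).
#' @param nrounds,max_depth,eta ensemble hyperparameters.
#' @param seed integer seed.
#' @return An `xgb.Booster`.
#' @export
fit_importance_model <- function(X, y, nrounds = 100L, max_depth = 3L,
                                 eta = 0.1, seed = 1L) {
  if (length(unique(y)) < 2L)
    stop("labels must contain both classes")
  X <- as.matrix(X)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1L, seed = seed,
                  scale_pos_weight = sum(y == 0) / sum(y == 1)),
    data = dtrain, nrounds = nrounds, verbose = 0L)
}

#' Local and global SHAP importances
#'
#' TreeSHAP attributions per sample (signed contributions that sum with the
#' bias to the model margin), their absolute values as local importances,
#' and the per-feature mean of local importance as global importance.
#'
#' @param model a fitted `xgb.Booster`.
#' @param X the feature matrix the model was fitted on (same columns).
#' @return List of class `soz_importance`: `contrib` (signed, incl. `BIAS`),
#'   `local` (|contrib|, samples x features), `global` (named vector),
#'   `bias` (expected model output, margin scale).
#' @export
local_global_importance <- function(model, X) {
  X <- as.matrix(X)
  contrib <- stats::predict(model, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  colnames(contrib) <- c(colnames(X), "BIAS")
  local <- abs(contrib[, colnames(X), drop = FALSE])
  structure(list(contrib = contrib, local = local,
                 global = colMeans(local), bias = contrib[1L, "BIAS"]),
            class = "soz_importance")
}

# append n_shadow permuted copies of randomly chosen real features
.add_shadows <- function(X, n_shadow) {
  n <- nrow(X)
  src <- sample(seq_len(ncol(X)), n_shadow, replace = n_shadow > ncol(X))
  S <- vapply(src, function(j) X[sample.int(n), j], numeric(n))
  colnames(S) <- paste0("shadow_", seq_len(n_shadow))
  cbind(X, S)
}

#' Shadow-feature adaptive threshold
#'
#' Appends `n_shadow` permuted copies of randomly chosen real features
#' (shadow features carry no label information by construction), refits the
#' ensemble, and sets the relevance threshold to `c_l * max(GI_shadow)` with
#' `c_l` ramping linearly from `c_start` to 1 over `L` iterations; the final
#' threshold uses `c_L = 1`, i.e. the maximum shadow global importance.
#' By default one shadow is appended per real feature: the threshold is the
#' maximum over the shadows, and a small shadow set makes that maximum a weak
#' null envelope (real but irrelevant features then beat it by chance alone).
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param n_shadow number of shadow features (>= 1); default `ncol(X)`.
#' @param L iterations of the ramp.
#' @param c_start initial ramp factor.
#' @param seed integer seed.
#' @param nrounds,max_depth,eta passed to [fit_importance_model()].
#' @return List: `threshold` (Tre), `c_trace` (threshold per iteration),
#'   `shadow_global`, `importance` (the augmented-fit `soz_importance`),
#'   `shadow_names`.
#' @export
shadow_threshold <- function(X, y, n_shadow = ncol(X),
                             L = 10L, c_start = 0.1, seed = 1L,
                             nrounds = 100L, max_depth = 3L, eta = 0.1) {
  if (n_shadow < 1L) stop("n_shadow must be >= 1")
  X <- as.matrix(X)
  set.seed(seed)
  Xa <- .add_shadows(X, n_shadow)
  model <- fit_importance_model(Xa, y, nrounds, max_depth, eta, seed)
  imp <- local_global_importance(model, Xa)
  shadow_names <- paste0("shadow_", seq_len(n_shadow))
  gi_shadow <- imp$global[shadow_names]
  c_l <- seq(c_start, 1, length.out = L)
  list(threshold = max(gi_shadow), c_trace = c_l * max(gi_shadow),
       shadow_global = gi_shadow, importance = imp,
       shadow_names = shadow_names)
}

#' ShapHT+ feature selection
#'
#' Partitions features into relevant and irrelevant: per feature, the number
#' of samples whose local SHAP importance exceeds the shadow-derived
#' threshold is compared against the shadow hit probability with a binomial
#' test ("more hits than chance" direction); features rejecting the null
#' after Benjamini-Hochberg correction at `alpha` are relevant.
#'
#' @param X feature matrix (samples x features) or a feature table data
#'   frame (non-feature columns `contact`, `patient_id`, `region`, `label`
#'   are dropped automatically).
#' @param y binary labels.
#' @param alpha significance level.
#' @param n_shadow,L,seed,nrounds,max_depth,eta see [shadow_threshold()].
#' @return An object of class `soz_selection`: `relevant`, `irrelevant`,
#'   `p_values`, `p_adjusted`, `hits`, `null_prob`, `threshold`, `c_trace`.
#' @export
select_features <- function(X, y, alpha = 0.05,
                            n_shadow = NULL, L = 10L, seed = 1L,
                            nrounds = 100L, max_depth = 3L, eta = 0.1) {
  if (is.data.frame(X)) {
    if (missing(y) && "label" %in% names(X)) y <- X$label
    X <- as.matrix(X[, setdiff(names(X), c("contact", "patient_id", "region",
                                           "label")), drop = FALSE])
  }
  if (is.null(n_shadow)) n_shadow <- ncol(X)
  st <- shadow_threshold(X, y, n_shadow, L, seed = seed, nrounds = nrounds,
                         max_depth = max_depth, eta = eta)
  feats <- setdiff(colnames(st$importance$local), st$shadow_names)
  localF <- st$importance$local[, feats, drop = FALSE]
  localS <- st$importance$local[, st$shadow_names, drop = FALSE]
  n <- nrow(localF)
  tre <- st$threshold
  hits <- colSums(localF > tre)
  # null hit probability: the most optimistic (max) per-shadow hit rate, so a
  # real feature must beat what the luckiest label-free feature achieves;
  # floored so the test is defined when no shadow sample ever crosses
  p0 <- max(colMeans(localS > tre), 1 / (2 * n * ncol(localS)))
  pv <- vapply(hits, function(h)
    stats::binom.test(h, n, p0, alternative = "greater")$p.value, numeric(1))
  padj <- stats::p.adjust(pv, method = "BH")
  relevant <- names(hits)[padj < alpha]
  structure(list(relevant = relevant,
                 irrelevant = setdiff(feats, relevant),
                 p_values = pv, p_adjusted = padj, hits = hits,
                 null_prob = p0, threshold = tre, c_trace = st$c_trace,
                 alpha = alpha, seed = seed),
            class = "soz_selection")
}

#' @export
print.soz_selection <- function(x, ...) {
  cat(sprintf("ShapHT+ selection: %d relevant / %d total features (alpha = %g)\n",
              length(x$relevant), length(x$relevant) + length(x$irrelevant),
              x$alpha))
  cat("threshold Tre =", format(x$threshold, digits = 4),
      " null hit prob =", format(x$null_prob, digits = 4), "\n")
  if (length(x$relevant) > 0L)
    cat("relevant:", paste(utils::head(x$relevant, 20L), collapse = ", "),
        if (length(x$relevant) > 20L) "..." else "", "\n")
  invisible(x)
}
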