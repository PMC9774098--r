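#' Classifier configuration
#'
#' Architecture and training settings of the SOZ contact classifier: four
#' fully connected layers (`n_features -> 128 -> 128 -> 128 -> 2`) with ReLU
#' activations, dropout 0.3 after the first and third layers, an attention
#' block over the third hidden activation, softmax output, focal loss, and
#' the NAdam optimizer (learning rate 1e-4, 20 epochs, batch size 4).
#'
#' The attention block treats the 128 hidden units as a sequence of
#' `seq_len` segments of `hidden/seq_len` units each (contact rows have no
#' time axis, so the sequence is formed over the hidden-unit axis).
#'
#' @param hidden hidden width.
#' @param seq_len attention sequence length; must divide `hidden`.
#' @param d_att attention projection dimension.
#' @param dropout dropout probability in `[0, 1)`.
#' @param epochs,batch_size,lr training schedule.
#' @param gamma focal-loss focusing exponent.
#' @param alpha focal-loss class weights `c(negative, positive)`; a scalar is
#'   applied to both classes (so `gamma = 0, alpha = 1` is plain
#'   cross-entropy).
#' @param seed integer seed.
#' @return A list of class `soz_net_config`.
#' @export
classifier_config <- function(hidden = 128L, seq_len = 8L, d_att = 16L,
                              dropout = 0.3, epochs = 20L, batch_size = 4L,
                              lr = 1e-4, gamma = 2, alpha = c(0.75, 0.25),
                              seed = 1L) {
  if (hidden %% seq_len != 0L) stop("seq_len must divide hidden")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (length(alpha) == 1L) alpha <- rep(alpha, 2L)
  structure(as.list(environment()), class = "soz_net_config")
}

#' Attention forward pass
#'
#' For a sequence of activations `e_t` (rows of `e`):
#' `u_t = tanh(W_w e_t + b_w)`, `h_t = softmax_t(u_t' u_w)`,
#' `v = sum_t h_t e_t`. The weights `h` are non-negative and sum to 1, so
#' `v` is a convex combination of the `e_t`.
#'
#' @param e numeric matrix, `T x d` (one row per sequence element).
#' @param params list with `W_w` (`d_att x d`), `b_w` (`d_att`), `u_w`
#'   (`d_att`).
#' @return List: `v` (length-`d` context vector), `weights` (length-`T`
#'   attention distribution).
#' @export
attention_forward <- function(e, params) {
  e <- as.matrix(e)
  if (ncol(params$W_w) != ncol(e))
    stop("dimension mismatch: W_w has ", ncol(params$W_w),
         " columns but e_t has length ", ncol(e))
  u <- tanh(e %*% t(params$W_w) + matrix(params$b_w, nrow(e),
                                         length(params$b_w), byrow = TRUE))
  s <- as.numeric(u %*% params$u_w)
  s <- s - max(s)
  h <- exp(s) / sum(exp(s))
  list(v = as.numeric(t(e) %*% h), weights = h)
}

#' Focal loss
#'
#' Mean over samples of `-alpha_y (1 - p_true)^gamma log(p_true)` with
#' class-dependent weight `alpha_y`. With `gamma = 0` and `alpha = 1` this
#' is exactly the cross-entropy. Probabilities at 0 or 1 are clipped to
#' machine tolerance with a warning.
#'
#' @param probabilities matrix of class probabilities (samples x 2, columns
#'   = classes 0 and 1) or a vector of positive-class probabilities.
#' @param labels binary labels (0/1).
#' @param gamma focusing exponent (>= 0).
#' @param alpha class weights `c(negative, positive)`; scalar applies to
#'   both.
#' @return Scalar loss.
#' @export
focal_loss <- function(probabilities, labels, gamma = 2,
                       alpha = c(0.75, 0.25)) {
  if (is.null(dim(probabilities)))
    probabilities <- cbind(1 - probabilities, probabilities)
  if (length(alpha) == 1L) alpha <- rep(alpha, 2L)
  pt <- probabilities[cbind(seq_along(labels), labels + 1L)]
  if (any(pt <= 0 | pt >= 1)) {
    warning("probabilities at 0/1 clipped for the focal loss")
    pt <- pmin(pmax(pt, 1e-12), 1 - 1e-12)
  }
  at <- alpha[labels + 1L]
  mean(-at * (1 - pt)^gamma * log(pt))
}

# ---- internal network machinery ------------------------------------------

.init_params <- function(n_features, cfg) {
  H <- cfg$hidden; d <- H %/% cfg$seq_len
  gl <- function(nin, nout) matrix(stats::runif(nin * nout,
                                                -sqrt(6 / (nin + nout)),
                                                sqrt(6 / (nin + nout))),
                                   nin, nout)
  list(W1 = gl(n_features, H), b1 = numeric(H),
       W2 = gl(H, H), b2 = numeric(H),
       W3 = gl(H, H), b3 = numeric(H),
       W_w = gl(cfg$d_att, d) * 1, b_w = numeric(cfg$d_att),
       u_w = stats::runif(cfg$d_att, -0.5, 0.5),
       W4 = gl(d, 2L), b4 = numeric(2L))
}

# forward pass on a batch; masks are NULL at inference
.net_forward <- function(X, par, cfg, masks = NULL) {
  Tn <- cfg$seq_len; d <- cfg$hidden %/% Tn
  relu <- function(z) pmax(z, 0)
  lin <- function(A, W, b) A %*% W + matrix(b, nrow(A), length(b), byrow = TRUE)
  A1 <- relu(lin(X, par$W1, par$b1))
  D1 <- if (is.null(masks)) A1 else A1 * masks$M1
  A2 <- relu(lin(D1, par$W2, par$b2))
  A3 <- relu(lin(A2, par$W3, par$b3))
  D3 <- if (is.null(masks)) A3 else A3 * masks$M3
  B <- nrow(X)
  V <- matrix(0, B, d); Hw <- matrix(0, B, Tn); U <- vector("list", B)
  att_par <- list(W_w = par$W_w, b_w = par$b_w, u_w = par$u_w)
  for (i in seq_len(B)) {
    e <- matrix(D3[i, ], Tn, d, byrow = TRUE)
    u <- tanh(e %*% t(par$W_w) + matrix(par$b_w, Tn, cfg$d_att, byrow = TRUE))
    s <- as.numeric(u %*% par$u_w); s <- s - max(s)
    h <- exp(s) / sum(exp(s))
    V[i, ] <- as.numeric(t(e) %*% h); Hw[i, ] <- h; U[[i]] <- u
  }
  Z4 <- lin(V, par$W4, par$b4)
  Z4s <- Z4 - apply(Z4, 1L, max)
  P <- exp(Z4s) / rowSums(exp(Z4s))
  list(A1 = A1, D1 = D1, A2 = A2, A3 = A3, D3 = D3, V = V, Hw = Hw, U = U,
       P = P)
}

.net_backward <- function(X, y, fw, par, cfg, masks) {
  B <- nrow(X); Tn <- cfg$seq_len; d <- cfg$hidden %/% Tn
  P <- fw$P
  pt <- pmin(pmax(P[cbind(seq_len(B), y + 1L)], 1e-12), 1 - 1e-12)
  at <- cfg$alpha[y + 1L]
  g <- cfg$gamma
  # dL/dp_true of the focal term, then chain through softmax
  dLdpt <- -at * (-g * (1 - pt)^(pmax(g - 1, 0)) * log(pt) *
                    (if (g > 0) 1 else 0) + (1 - pt)^g / pt)
  dZ4 <- matrix(0, B, 2L)
  for (k in 1:2) {
    ind <- as.numeric(y + 1L == k)
    dZ4[, k] <- dLdpt * pt * (ind - P[, k])
  }
  dZ4 <- dZ4 / B
  gr <- list(W4 = t(fw$V) %*% dZ4, b4 = colSums(dZ4))
  dV <- dZ4 %*% t(par$W4)
  dD3 <- matrix(0, B, cfg$hidden)
  gW_w <- matrix(0, cfg$d_att, d); gb_w <- numeric(cfg$d_att)
  gu_w <- numeric(cfg$d_att)
  for (i in seq_len(B)) {
    e <- matrix(fw$D3[i, ], Tn, d, byrow = TRUE)
    h <- fw$Hw[i, ]; u <- fw$U[[i]]
    gv <- dV[i, ]
    dh <- as.numeric(e %*% gv)
    ds <- h * (dh - sum(h * dh))
    dpre <- (ds %o% par$u_w) * (1 - u^2)
    gW_w <- gW_w + t(dpre) %*% e
    gb_w <- gb_w + colSums(dpre)
    gu_w <- gu_w + as.numeric(t(u) %*% ds)
    de <- dpre %*% par$W_w + h %o% gv
    dD3[i, ] <- as.vector(t(de))
  }
  gr$W_w <- gW_w; gr$b_w <- gb_w; gr$u_w <- gu_w
  dA3 <- if (is.null(masks)) dD3 else dD3 * masks$M3
  dZ3 <- dA3 * (fw$A3 > 0)
  gr$W3 <- t(fw$A2) %*% dZ3; gr$b3 <- colSums(dZ3)
  dA2 <- dZ3 %*% t(par$W3)
  dZ2 <- dA2 * (fw$A2 > 0)
  gr$W2 <- t(fw$D1) %*% dZ2; gr$b2 <- colSums(dZ2)
  dD1 <- dZ2 %*% t(par$W2)
  dA1 <- if (is.null(masks)) dD1 else dD1 * masks$M1
  dZ1 <- dA1 * (fw$A1 > 0)
  gr$W1 <- t(X) %*% dZ1; gr$b1 <- colSums(dZ1)
  gr
}

# NAdam step (Nesterov-accelerated adaptive moments)
.nadam_step <- function(par, gr, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  for (nm in names(gr)) {
    g <- gr[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    upd <- (beta1 * mhat + (1 - beta1) * g / (1 - beta1^t)) /
      (sqrt(vhat) + eps)
    par[[nm]] <- par[[nm]] - lr * upd
  }
  list(par = par, state = state)
}

#' Train the attention MLP SOZ classifier
#'
#' Trains the network described in [classifier_config()] with focal loss and
#' NAdam. Features are z-scored with training-set statistics (stored in the
#' model). When validation data are supplied, the epoch with the lowest
#' validation focal loss is kept; otherwise the final epoch is returned.
#' Training is reproducible for a fixed config seed.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y binary labels (0 = non-SOZ, 1 = SOZ).
#' @param config a [classifier_config()].
#' @param X_val,y_val optional validation split for epoch selection.
#' @return An object of class `soz_net` with elements `par`, `config`,
#'   `center`, `scale`, `feature_names`, `history`, `best_epoch`.
#' @export
soz_net <- function(X, y, config = classifier_config(),
                    X_val = NULL, y_val = NULL) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("no features to train on")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  center <- colMeans(X)
  scl <- apply(X, 2L, stats::sd); scl[scl <= 0 | !is.finite(scl)] <- 1
  Xs <- scale(X, center, scl)
  if (!is.null(X_val))
    Xv <- scale(as.matrix(X_val), center, scl)
  set.seed(config$seed)
  par <- .init_params(ncol(X), config)
  state <- list(m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  n <- nrow(Xs); p_drop <- config$dropout
  step <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, par = par, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      Xb <- Xs[idx, , drop = FALSE]; yb <- y[idx]
      masks <- if (p_drop > 0) list(
        M1 = matrix(stats::rbinom(length(idx) * config$hidden, 1L, 1 - p_drop),
                    length(idx)) / (1 - p_drop),
        M3 = matrix(stats::rbinom(length(idx) * config$hidden, 1L, 1 - p_drop),
                    length(idx)) / (1 - p_drop)) else NULL
      fw <- .net_forward(Xb, par, config, masks)
      ep_loss <- ep_loss + focal_loss(fw$P, yb, config$gamma, config$alpha)
      nb <- nb + 1L
      gr <- .net_backward(Xb, yb, fw, par, config, masks)
      step <- step + 1L
      upd <- .nadam_step(par, gr, state, config$lr, step)
      par <- upd$par; state <- upd$state
    }
    val_loss <- NA_real_
    if (!is.null(X_val)) {
      pv <- .net_forward(Xv, par, config)$P
      val_loss <- focal_loss(pv, y_val, config$gamma, config$alpha)
      if (val_loss < best$loss) best <- list(loss = val_loss, par = par,
                                             epoch = ep)
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                         val_loss = val_loss))
  }
  if (is.null(X_val)) best <- list(loss = NA_real_, par = par,
                                   epoch = config$epochs)
  structure(list(par = best$par, config = config, center = center,
                 scale = scl, feature_names = colnames(X),
                 history = history, best_epoch = best$epoch),
            class = "soz_net")
}

#' @export
print.soz_net <- function(x, ...) {
  cat(sprintf(paste0("attention MLP SOZ classifier: %d features -> %d-%d-%d",
                     " hidden -> attention(%d x %d) -> 2 classes\n"),
              length(x$feature_names), x$config$hidden, x$config$hidden,
              x$config$hidden, x$config$seq_len,
              x$config$hidden %/% x$config$seq_len))
  cat(sprintf("trained %d epochs (kept epoch %d), final train loss %.4g\n",
              nrow(x$history), x$best_epoch,
              x$history$train_loss[nrow(x$history)]))
  invisible(x)
}

#' Predict SOZ probabilities
#'
#' @param object a fitted [soz_net()].
#' @param newdata feature matrix with the training columns.
#' @param type `"prob"` for the SOZ probability, `"class"` for the 0/1 label
#'   at threshold 0.5.
#' @param ... unused.
#' @return Numeric vector of probabilities or integer labels.
#' @export
predict.soz_net <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X)))
    X <- X[, object$feature_names, drop = FALSE]
  Xs <- scale(X, object$center, object$scale)
  p <- .net_forward(Xs, object$par, object$config)$P[, 2L]
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Leave-one-patient-out cross-validation
#'
#' For each fold one patient is the test set, the next patient in rotation
#' is the validation set (used to pick the best epoch), and all remaining
#' patients form the training set — so with patients P1..P10, testing P1
#' trains on P2-P10. Optionally runs ShapHT+ feature selection inside each
#' fold on the training rows only. Per-patient metrics are averaged
#' unweighted across folds.
#'
#' @param features feature table data frame containing `patient_id`, `label`
#'   and feature columns (as from [build_feature_table()] or
#'   [generate_feature_table()]).
#' @param config a [classifier_config()].
#' @param select run ShapHT+ per fold (`TRUE`) or use all features.
#' @param threshold classification threshold on the SOZ probability.
#' @param selection_args list of extra arguments for [select_features()].
#' @return An object of class `soz_loocv`: `predictions` (one row per
#'   contact: `contact`, `patient_id`, `probability`, `predicted`, `label`),
#'   `per_patient` (metrics matrix), `mean_metrics`, `folds`.
#' @export
loocv <- function(features, config = classifier_config(), select = FALSE,
                  threshold = 0.5, selection_args = list()) {
  stopifnot(all(c("patient_id", "label") %in% names(features)))
  patients <- unique(features$patient_id)
  if (length(patients) < 3L) stop("leave-one-patient-out needs >= 3 patients")
  counts <- table(features$patient_id)
  empty <- names(counts)[counts == 0L]
  if (length(empty) > 0L) {
    warning("excluding patient(s) with no contacts: ",
            paste(empty, collapse = ", "))
    patients <- setdiff(patients, empty)
  }
  feat_cols <- setdiff(names(features),
                       c("contact", "patient_id", "region", "label"))
  X <- as.matrix(features[, feat_cols, drop = FALSE])
  y <- features$label
  preds <- list(); folds <- list()
  for (k in seq_along(patients)) {
    test_p <- patients[k]
    val_p <- patients[if (k == length(patients)) 1L else k + 1L]
    train_p <- setdiff(patients, c(test_p, val_p))
    tr <- features$patient_id %in% train_p
    va <- features$patient_id == val_p
    te <- features$patient_id == test_p
    folds[[k]] <- list(test = test_p, validation = val_p, train = train_p)
    cols <- feat_cols
    if (select) {
      sel <- do.call(select_features,
                     c(list(X = X[tr, , drop = FALSE], y = y[tr],
                            seed = config$seed + k), selection_args))
      if (length(sel$relevant) > 0L) cols <- sel$relevant
    }
    cfg <- config; cfg$seed <- config$seed + k
    fit <- soz_net(X[tr, cols, drop = FALSE], y[tr], cfg,
                   X_val = X[va, cols, drop = FALSE], y_val = y[va])
    p <- predict(fit, X[te, cols, drop = FALSE])
    preds[[k]] <- data.frame(
      contact = if ("contact" %in% names(features))
        features$contact[te] else which(te),
      patient_id = test_p, probability = p,
      predicted = as.integer(p >= threshold), label = y[te],
      stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  per_patient <- t(vapply(patients, function(p) {
    rows <- predictions[predictions$patient_id == p, ]
    soz_metrics(confusion(rows$probability, rows$label, threshold))
  }, numeric(5)))
  structure(list(predictions = predictions, per_patient = per_patient,
                 mean_metrics = aggregate_metrics(per_patient),
                 folds = folds, threshold = threshold),
            class = "soz_loocv")
}

#' @export
print.soz_loocv <- function(x, ...) {
  cat(sprintf("leave-one-patient-out CV over %d patients, %d contacts\n",
              length(x$folds), nrow(x$predictions)))
  m <- x$mean_metrics
  cat(sprintf("mean metrics (%%): SEN %.2f  SPE %.2f  ACC %.2f  PPV %.2f  NPV %.2f\n",
              m["SEN"], m["SPE"], m["ACC"], m["PPV"], m["NPV"]))
  invisible(x)
}

#' @export
summary.soz_loocv <- function(object, ...) {
  out <- rbind(object$per_patient, Mean = object$mean_metrics)
  round(out, 2)
}
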