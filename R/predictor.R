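# QSAR models mapping SMILES to pIC50: a recurrent (embedding + GRU) model
# plus fingerprint-based baselines (fully connected net, SVR, random forest,
# k-nearest neighbours), trained under a held-out-test / 5-fold protocol with
# label standardization and early stopping.

#' ECFP featurization for QSAR models
#'
#' Radius-3 Morgan fingerprint folded to 4096 bits, the same definition used
#' by the diversity metrics.
#'
#' @param smiles A single SMILES string or character vector.
#' @return For a single input, an integer vector of 0-based on-bit indices
#'   (class `dmg_fingerprint`); for a vector, a list of them. Unparseable
#'   SMILES raise an error.
#' @export
featurize_ecfp <- function(smiles) {
  fps <- morgan_fingerprints(smiles)
  bad <- vapply(fps, is.null, logical(1))
  if (any(bad))
    stop(sprintf("unparseable SMILES: %s",
                 paste(sprintf("'%s'", smiles[bad]), collapse = ", ")))
  fps <- lapply(fps, structure, class = "dmg_fingerprint")
  if (length(smiles) == 1L) fps[[1]] else fps
}

#' Standardize activity labels
#'
#' Centers and scales pIC50 labels to zero mean and unit variance, returning
#' the scaler so predictions can be mapped back. The scaler must be fitted on
#' training data only.
#'
#' @param y Numeric vector of labels (length >= 2, non-constant).
#' @return List with `scaler` (`mean`, `std` in pIC50 units) and `z`, the
#'   standardized labels.
#' @export
standardize_labels <- function(y) {
  stopifnot(length(y) >= 2, all(is.finite(y)))
  s <- stats::sd(y)
  if (s == 0) stop("labels are constant; cannot standardize")
  m <- mean(y)
  list(scaler = list(mean = m, std = s), z = (y - m) / s)
}

apply_scaler <- function(scaler, y) (y - scaler$mean) / scaler$std
invert_scaler <- function(scaler, z) z * scaler$std + scaler$mean

#' QSAR model configuration
#'
#' Hyperparameters for the five QSAR variants. Defaults are the full-scale
#' settings: the recurrent model uses a 128-dimensional token embedding, two
#' GRU layers of 128 units and a 128-unit dense layer; the fully connected
#' net takes the 4096-bit fingerprint through 8000/4000/2000-unit hidden
#' layers with dropout 0.25; SVR uses a polynomial kernel (C 0.125, gamma 8),
#' the random forest 500 trees with sqrt feature sampling, and kNN k = 11
#' with Euclidean distance. The protocol holds out 15% for testing and
#' cross-validates 5 folds over the rest, with an inner 15% validation split
#' for early stopping of the neural variants.
#'
#' @param model_kind One of `"smiles_rnn"`, `"fcnn_ecfp"`, `"svr_ecfp"`,
#'   `"rf_ecfp"`, `"knn_ecfp"`.
#' @param embedding_dim,gru_layers,gru_units,dense_units Recurrent variant.
#' @param max_len Padded token length for the recurrent variant.
#' @param fcnn_hidden,fcnn_dropout Fully connected variant.
#' @param svr_cost,svr_gamma Polynomial-kernel SVR.
#' @param rf_trees Random forest size (`max_features` is sqrt).
#' @param knn_k Neighbour count.
#' @param test_fraction,folds,inner_validation_fraction Protocol.
#' @param learning_rate,batch_size,max_epochs,early_stopping_patience Neural
#'   training control (patience in epochs on validation MSE).
#' @return A `dmg_qsar_config` list.
#' @export
qsar_config <- function(model_kind = c("smiles_rnn", "fcnn_ecfp", "svr_ecfp",
                                       "rf_ecfp", "knn_ecfp"),
                        embedding_dim = 128L, gru_layers = 2L,
                        gru_units = 128L, dense_units = 128L, max_len = 65L,
                        fcnn_hidden = c(8000L, 4000L, 2000L),
                        fcnn_dropout = 0.25,
                        svr_cost = 0.125, svr_gamma = 8,
                        rf_trees = 500L, knn_k = 11L,
                        test_fraction = 0.15, folds = 5L,
                        inner_validation_fraction = 0.15,
                        learning_rate = 1e-3, batch_size = 16L,
                        max_epochs = 100L, early_stopping_patience = 10L) {
  model_kind <- match.arg(model_kind)
  stopifnot(test_fraction > 0, test_fraction < 1, folds >= 2,
            inner_validation_fraction > 0, inner_validation_fraction < 1)
  structure(as.list(environment()), class = "dmg_qsar_config")
}

# Last non-pad position of each row of an integer token matrix.
.last_real <- function(X, pad_idx) {
  apply(X != pad_idx, 1, function(r) max(which(r)))
}

# Train one neural sequence-regression model with early stopping.
.fit_rnn_reg <- function(Xtr, ztr, Xval, zval, vocab, config, seed) {
  net <- rnn_new(vocab$size, layers = config$gru_layers,
                 units = config$gru_units, cell = "gru", out_dim = 1L,
                 embedding_dim = config$embedding_dim,
                 dense_units = config$dense_units,
                 seed = derive_seed(seed, "qsar-init"))
  opt <- adam_new(net$params)
  pad_idx <- vocab$index_of[[vocab$pad_token]]
  last_tr <- .last_real(Xtr, pad_idx)
  last_val <- .last_real(Xval, pad_idx)
  best <- list(params = net$params, val = Inf, epoch = 0L)
  wait <- 0L
  with_local_seed(derive_seed(seed, "qsar-shuffle"), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(nrow(Xtr))
      for (start in seq(1L, nrow(Xtr), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, nrow(Xtr))]
        xb <- Xtr[idx, , drop = FALSE]
        fwd <- rnn_forward(net, xb, train = TRUE)
        lb <- last_tr[idx]
        preds <- vapply(seq_along(idx), function(i) fwd$logits[[lb[i]]][i, 1],
                        numeric(1))
        dl <- 2 * (preds - ztr[idx]) / length(idx)
        dlog <- vector("list", ncol(xb))
        for (i in seq_along(idx)) {
          t <- lb[i]
          if (is.null(dlog[[t]])) dlog[[t]] <- matrix(0, length(idx), 1)
          dlog[[t]][i, 1] <- dl[i]
        }
        g <- rnn_backward(net, xb, fwd, dlog)
        st <- adam_step(net$params, g, opt, lr = config$learning_rate)
        net$params <- st$params; opt <- st$opt
      }
      pv <- .predict_rnn_reg(net, Xval, last_val)
      val_mse <- mean((pv - zval)^2)
      if (val_mse < best$val - 1e-6) {
        best <- list(params = net$params, val = val_mse, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stopping_patience) break
      }
    }
  })
  net$params <- best$params
  list(net = net, val_mse = best$val, stopped_epoch = best$epoch)
}

.predict_rnn_reg <- function(net, X, last) {
  fwd <- rnn_forward(net, X, train = FALSE)
  vapply(seq_len(nrow(X)), function(i) fwd$logits[[last[i]]][i, 1], numeric(1))
}

.fit_mlp_reg <- function(Xtr, ztr, Xval, zval, config, seed) {
  net <- mlp_new(ncol(Xtr), config$fcnn_hidden, seed = derive_seed(seed, "fcnn-init"))
  opt <- adam_new(net$layers)
  best <- list(layers = net$layers, val = Inf)
  wait <- 0L
  with_local_seed(derive_seed(seed, "fcnn-shuffle"), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(nrow(Xtr))
      for (start in seq(1L, nrow(Xtr), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, nrow(Xtr))]
        fwd <- mlp_forward(net, Xtr[idx, , drop = FALSE],
                           dropout = config$fcnn_dropout, train = TRUE)
        dpred <- 2 * (fwd$pred - ztr[idx]) / length(idx)
        g <- mlp_backward(net, fwd, dpred)
        st <- adam_step(net$layers, g, opt, lr = config$learning_rate)
        net$layers <- st$params; opt <- st$opt
      }
      pv <- mlp_forward(net, Xval)$pred[, 1]
      val_mse <- mean((pv - zval)^2)
      if (val_mse < best$val - 1e-6) {
        best <- list(layers = net$layers, val = val_mse); wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stopping_patience) break
      }
    }
  })
  net$layers <- best$layers
  net
}

#' Train a QSAR model ensemble
#'
#' Implements the evaluation protocol: 15% of the curated records are held
#' out as the test set; the remaining 85% are split into `folds` folds, and
#' one model is trained per fold on the other folds (neural variants reserve
#' a further 15% of that portion as an inner validation split for early
#' stopping; the label scaler is fitted on the inner training portion only).
#' Each fold model is scored on the held-out test set and the report averages
#' the per-fold MSE and Q-squared.
#'
#' @param data data.frame with columns `smiles` and `pic50` (or a CSV path).
#' @param config A [qsar_config()].
#' @param seed Integer master seed.
#' @return A `dmg_qsar` object: per-fold fitted models with their scalers,
#'   the shared featurization state, and `$report` (`mse`, `q2`, `per_fold`).
#' @export
train_qsar <- function(data, config = qsar_config(), seed = 1L) {
  if (is.character(data) && length(data) == 1L) data <- read_activity_csv(data)
  stopifnot(all(c("smiles", "pic50") %in% names(data)))
  if (!all(is.finite(data$pic50))) stop("labels must be finite")
  n <- nrow(data)
  if (n < 50) stop("at least 50 records are required")
  kind <- config$model_kind

  # shared featurization
  if (kind == "smiles_rnn") {
    vocab <- build_vocabulary(data$smiles)
    toks <- lapply(data$smiles, tokenize)
    keep <- lengths(toks) + 2L <= config$max_len
    if (any(!keep)) {
      message(sprintf("train_qsar: dropped %d over-length molecule(s)", sum(!keep)))
      data <- data[keep, , drop = FALSE]; toks <- toks[keep]; n <- nrow(data)
    }
    feats <- unclass(encode_batch(lapply(toks, pad_and_mark,
                                         max_len = config$max_len,
                                         vocab = vocab), vocab))
  } else {
    vocab <- NULL
    feats <- fp_matrix(featurize_ecfp(data$smiles))
  }

  with_local_seed(derive_seed(seed, "split"), {
    test_idx <- sample.int(n, max(2L, round(config$test_fraction * n)))
    trainval <- setdiff(seq_len(n), test_idx)
    fold_id <- sample(rep_len(seq_len(config$folds), length(trainval)))
  })
  y_test <- data$pic50[test_idx]

  fold_models <- vector("list", config$folds)
  per_fold <- matrix(NA_real_, config$folds, 2,
                     dimnames = list(NULL, c("mse", "q2")))
  for (k in seq_len(config$folds)) {
    ftrain <- trainval[fold_id != k]
    seed_k <- derive_seed(seed, paste0("fold", k))
    if (kind %in% c("smiles_rnn", "fcnn_ecfp")) {
      with_local_seed(seed_k, {
        v_idx <- sample.int(length(ftrain),
                            max(1L, round(config$inner_validation_fraction *
                                          length(ftrain))))
      })
      inner_val <- ftrain[v_idx]; inner_train <- ftrain[-v_idx]
    } else {
      inner_val <- integer(0); inner_train <- ftrain
    }
    sc <- standardize_labels(data$pic50[inner_train])
    model <- switch(kind,
      smiles_rnn = .fit_rnn_reg(feats[inner_train, , drop = FALSE], sc$z,
                                feats[inner_val, , drop = FALSE],
                                apply_scaler(sc$scaler, data$pic50[inner_val]),
                                vocab, config, seed_k),
      fcnn_ecfp = .fit_mlp_reg(feats[inner_train, , drop = FALSE], sc$z,
                               feats[inner_val, , drop = FALSE],
                               apply_scaler(sc$scaler, data$pic50[inner_val]),
                               config, seed_k),
      svr_ecfp = e1071::svm(x = feats[inner_train, , drop = FALSE], y = sc$z,
                            kernel = "polynomial", cost = config$svr_cost,
                            gamma = config$svr_gamma, scale = FALSE),
      rf_ecfp = with_local_seed(seed_k,
        randomForest::randomForest(x = feats[inner_train, , drop = FALSE],
                                   y = sc$z, ntree = config$rf_trees,
                                   mtry = floor(sqrt(ncol(feats))))),
      knn_ecfp = caret::knnreg(x = feats[inner_train, , drop = FALSE],
                               y = sc$z, k = config$knn_k))
    fold_models[[k]] <- list(model = model, scaler = sc$scaler)
    pred_test <- .predict_fold(kind, fold_models[[k]],
                               feats[test_idx, , drop = FALSE], vocab)
    per_fold[k, ] <- unlist(evaluate_qsar(y_test, pred_test))
  }
  structure(list(kind = kind, config = config, vocab = vocab,
                 fold_models = fold_models,
                 splits = list(test_idx = test_idx, trainval = trainval,
                               fold_id = fold_id),
                 report = list(mse = mean(per_fold[, "mse"]),
                               q2 = mean(per_fold[, "q2"]),
                               per_fold = as.data.frame(per_fold))),
            class = "dmg_qsar")
}

.predict_fold <- function(kind, fm, feats, vocab) {
  z <- switch(kind,
    smiles_rnn = {
      pad_idx <- vocab$index_of[[vocab$pad_token]]
      .predict_rnn_reg(fm$model$net, feats, .last_real(feats, pad_idx))
    },
    fcnn_ecfp = mlp_forward(fm$model, feats)$pred[, 1],
    svr_ecfp = as.numeric(stats::predict(fm$model, feats)),
    rf_ecfp = as.numeric(stats::predict(fm$model, feats)),
    knn_ecfp = as.numeric(stats::predict(fm$model, as.data.frame(feats))))
  invert_scaler(fm$scaler, z)
}

#' @export
print.dmg_qsar <- function(x, ...) {
  cat(sprintf("<dmg_qsar> %s, %d fold models; test MSE %.4f, Q2 %.4f\n",
              x$kind, length(x$fold_models), x$report$mse, x$report$q2))
  invisible(x)
}

#' Predict activity for new molecules
#'
#' Fold-ensemble prediction: each fold model predicts on the standardized
#' scale, predictions are mapped back through that fold's scaler, and the
#' per-fold values are averaged.
#'
#' @param fit A `dmg_qsar` from [train_qsar()].
#' @param smiles Character vector of SMILES.
#' @return Numeric vector of predicted pIC50 values.
#' @export
predict_activity <- function(fit, smiles) {
  stopifnot(inherits(fit, "dmg_qsar"))
  feats <- if (fit$kind == "smiles_rnn") {
    toks <- lapply(smiles, tokenize)
    if (any(lengths(toks) + 2L > fit$config$max_len))
      stop("molecule exceeds the model's padded length")
    unclass(encode_batch(lapply(toks, pad_and_mark,
                                max_len = fit$config$max_len,
                                vocab = fit$vocab), fit$vocab))
  } else {
    fps <- featurize_ecfp(smiles)
    if (length(smiles) == 1L) fps <- list(fps)
    fp_matrix(fps)
  }
  preds <- vapply(fit$fold_models, function(fm)
    .predict_fold(fit$kind, fm, feats, fit$vocab), numeric(length(smiles)))
  if (length(smiles) == 1L) mean(preds) else rowMeans(matrix(preds, nrow = length(smiles)))
}

#' Regression metrics for QSAR evaluation
#'
#' Mean squared error and Q-squared,
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, with the observed mean
#' taken over the evaluation set itself.
#'
#' @param y_true,y_pred Equal-length numeric vectors (length >= 2).
#' @return List with elements `mse` (pIC50 squared units) and `q2`.
#' @export
evaluate_qsar <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  tss <- sum((y_true - mean(y_true))^2)
  if (tss == 0) stop("zero variance in y_true")
  rss <- sum((y_true - y_pred)^2)
  list(mse = mean((y_true - y_pred)^2), q2 = 1 - rss / tss)
}
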