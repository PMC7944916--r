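# The autoregressive SMILES generator: supervised pre-training with teacher
# forcing and temperature-controlled sampling.

#' Generator configuration
#'
#' Hyperparameters of the SMILES language model. Defaults are the full-scale
#' settings (two LSTM layers of 256 units, dropout 0.3, padded length 65,
#' Adam at 1e-3, batches of 16, 25 epochs, elementwise gradient clipping to
#' +/- 3). Desk-scale runs shrink `recurrent_units` and `max_len`.
#'
#' @param recurrent_layers,recurrent_units Stacked recurrent layers and units.
#' @param cell `"lstm"` (generator default) or `"gru"`.
#' @param dropout Dropout rate between recurrent layers, in `[0, 1)`.
#' @param max_len Padded sequence length including start/end markers.
#' @param learning_rate Adam learning rate.
#' @param batch_size,epochs Minibatch size and training epochs.
#' @param clip_bound Elementwise gradient clipping magnitude.
#' @return A `dmg_generator_config` list.
#' @export
generator_config <- function(recurrent_layers = 2L, recurrent_units = 256L,
                             cell = c("lstm", "gru"), dropout = 0.3,
                             max_len = 65L, learning_rate = 1e-3,
                             batch_size = 16L, epochs = 25L, clip_bound = 3) {
  cell <- match.arg(cell)
  stopifnot(dropout >= 0, dropout < 1, recurrent_layers >= 1,
            recurrent_units >= 1, max_len >= 3, batch_size >= 1, epochs >= 1)
  structure(list(recurrent_layers = as.integer(recurrent_layers),
                 recurrent_units = as.integer(recurrent_units), cell = cell,
                 dropout = dropout, max_len = as.integer(max_len),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), clip_bound = clip_bound),
            class = "dmg_generator_config")
}

.eps_prob <- 1e-8

#' Teacher-forcing cross-entropy loss
#'
#' The binary cross-entropy form applied token-wise over one-hot targets:
#' `-(1/T) * sum_t [ y_t log(yhat_t) + (1 - y_t) log(1 - yhat_t) ]`, where
#' the inner product runs over the vocabulary components of each step.
#' Probabilities are floored at `1e-8` inside the logarithms; masked (pad)
#' positions are excluded from both the sum and the normalizer `T`.
#'
#' @param y One-hot target matrix, steps x vocabulary.
#' @param y_hat Predicted probability matrix of the same shape (entries in
#'   `[0, 1]`; typically softmax rows, but the binary single-unit form is
#'   accepted).
#' @param mask Optional logical vector over steps; `FALSE` rows are ignored.
#' @return Non-negative scalar loss.
#' @export
teacher_forcing_loss <- function(y, y_hat, mask = NULL) {
  stopifnot(is.matrix(y), is.matrix(y_hat), all(dim(y) == dim(y_hat)),
            nrow(y) >= 1)
  if (any(y_hat < -1e-9) || any(y_hat > 1 + 1e-9))
    stop("'y_hat' entries must be probabilities in [0, 1]")
  if (is.null(mask)) mask <- rep(TRUE, nrow(y))
  keep <- which(mask)
  if (length(keep) == 0L) stop("mask excludes every step")
  p <- pmin(pmax(y_hat[keep, , drop = FALSE], .eps_prob), 1 - .eps_prob)
  yk <- y[keep, , drop = FALSE]
  -sum(yk * log(p) + (1 - yk) * log(1 - p)) / length(keep)
}

# Gradient of the masked BCE-on-softmax loss with respect to the logits.
# p: probabilities (B x V); y_idx: target indices; include: logical (B);
# norm: total unmasked step count the loss is averaged over.
.bce_softmax_dlogits <- function(p, y_idx, include, norm) {
  B <- nrow(p); V <- ncol(p)
  y <- matrix(0, B, V); y[cbind(seq_len(B), y_idx)] <- 1
  pc <- pmin(pmax(p, .eps_prob), 1 - .eps_prob)
  gp <- -(y / pc - (1 - y) / (1 - pc)) / norm
  gp[!include, ] <- 0
  p * (gp - rowSums(gp * p))
}

#' Pre-train the SMILES generator
#'
#' Teacher-forced maximum-likelihood training of the recurrent language model
#' on a curated SMILES corpus. Each molecule is tokenized, wrapped in
#' start/end markers, padded to `config$max_len` and one-hot fed; the model
#' learns to predict each next token. Over-length molecules are dropped with
#' a logged count. Gradients are clipped elementwise and weights updated with
#' Adam.
#'
#' @param corpus Character vector of SMILES (or data.frame with a `smiles`
#'   column).
#' @param config A [generator_config()].
#' @param seed Integer master seed (weight init, shuffling and dropout derive
#'   independent substreams).
#' @param vocab Optional pre-built [build_vocabulary()] result; built from
#'   the corpus when omitted.
#' @return A `dmg_policy` object: the trained policy network, its vocabulary,
#'   config, and per-epoch mean training loss in `$history`.
#' @export
train_generator <- function(corpus, config = generator_config(), seed = 1L,
                            vocab = NULL) {
  if (is.data.frame(corpus)) corpus <- corpus$smiles
  if (length(corpus) == 0L) stop("empty corpus")
  if (is.null(vocab)) vocab <- build_vocabulary(corpus)
  toks <- lapply(corpus, tokenize)
  fit <- lengths(toks) + 2L <= config$max_len
  if (any(!fit))
    message(sprintf("train_generator: dropped %d over-length molecule(s)", sum(!fit)))
  toks <- toks[fit]
  if (length(toks) == 0L) stop("no molecule fits within max_len")
  X <- encode_batch(lapply(toks, pad_and_mark, max_len = config$max_len,
                           vocab = vocab), vocab)
  X <- unclass(X); attr(X, "vocab") <- NULL; attr(X, "mode") <- NULL

  net <- rnn_new(vocab$size, layers = config$recurrent_layers,
                 units = config$recurrent_units, cell = config$cell,
                 out_dim = vocab$size, seed = derive_seed(seed, "init"))
  opt <- adam_new(net$params)
  pad_idx <- vocab$index_of[[vocab$pad_token]]
  n <- nrow(X); Tn <- ncol(X)
  history <- numeric(config$epochs)
  with_local_seed(derive_seed(seed, "shuffle"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_steps <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- X[idx, , drop = FALSE]
        xin <- xb[, -Tn, drop = FALSE]
        yout <- xb[, -1L, drop = FALSE]
        include <- yout != pad_idx
        norm <- sum(include)
        fwd <- rnn_forward(net, xin, dropout = config$dropout, train = TRUE)
        dlog <- vector("list", ncol(xin))
        for (t in seq_len(ncol(xin))) {
          p <- softmax_rows(fwd$logits[[t]])
          inc <- include[, t]
          if (any(inc)) {
            pc <- pmin(pmax(p, .eps_prob), 1 - .eps_prob)
            y <- matrix(0, nrow(p), ncol(p))
            y[cbind(seq_len(nrow(p)), yout[, t])] <- 1
            tot_loss <- tot_loss -
              sum((y * log(pc) + (1 - y) * log(1 - pc))[inc, ])
          }
          dlog[[t]] <- .bce_softmax_dlogits(p, yout[, t], inc, norm)
        }
        tot_steps <- tot_steps + norm
        g <- rnn_backward(net, xin, fwd, dlog)
        st <- adam_step(net$params, g, opt, lr = config$learning_rate,
                        clip = config$clip_bound)
        net$params <- st$params; opt <- st$opt
      }
      history[epoch] <- tot_loss / tot_steps
    }
  })
  structure(list(net = net, vocab = vocab, config = config,
                 history = history), class = "dmg_policy")
}

#' Create an untrained policy model
#'
#' A randomly initialized policy over the given vocabulary, mainly useful for
#' controlled experiments (e.g. bandit-style convergence checks of the
#' policy-gradient update) and as the starting point of custom training
#' loops.
#'
#' @param vocab A [build_vocabulary()] result.
#' @param config A [generator_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `dmg_policy`.
#' @export
new_policy <- function(vocab, config = generator_config(), seed = 1L) {
  net <- rnn_new(vocab$size, layers = config$recurrent_layers,
                 units = config$recurrent_units, cell = config$cell,
                 out_dim = vocab$size, seed = derive_seed(seed, "init"))
  structure(list(net = net, vocab = vocab, config = config,
                 history = numeric(0)), class = "dmg_policy")
}

#' @export
print.dmg_policy <- function(x, ...) {
  cat(sprintf("<dmg_policy> %d x %s-%d over %d tokens (max_len %d)\n",
              x$config$recurrent_layers, toupper(x$config$cell),
              x$config$recurrent_units, x$vocab$size, x$config$max_len))
  if (length(x$history))
    cat(sprintf("  final training loss %.4f after %d epoch(s)\n",
                utils::tail(x$history, 1), length(x$history)))
  invisible(x)
}

# Sampling-support mask: the pad and start tokens are never sampled.
.support_mask <- function(vocab) {
  m <- rep(TRUE, vocab$size)
  m[c(vocab$index_of[[vocab$pad_token]], vocab$index_of[[vocab$start_token]])] <- FALSE
  m
}

# Temperature-scaled, support-masked softmax of a logits matrix.
policy_probs <- function(logits, temperature, support) {
  if (temperature <= 0) stop("temperature must be > 0")
  z <- logits / temperature
  z[, !support] <- -Inf
  softmax_rows(z)
}

#' Next-token probability distribution
#'
#' The policy's distribution over the vocabulary given a token prefix, with
#' logits scaled by `1/temperature` before the softmax. The pad and start
#' tokens are excluded from the sampling support and the distribution is
#' renormalized. At `temperature = 1` this is the raw model distribution on
#' that support.
#'
#' @param model A `dmg_policy`.
#' @param prefix Character vector of tokens (or integer indices) beginning
#'   with the start token.
#' @param temperature Positive scalar.
#' @return Named probability vector over the vocabulary (sums to 1).
#' @export
next_token_distribution <- function(model, prefix, temperature = 1) {
  vocab <- model$vocab
  if (is.character(prefix)) prefix <- unname(vocab$index_of[prefix])
  if (anyNA(prefix)) stop("prefix contains tokens outside the vocabulary")
  if (prefix[1] != vocab$index_of[[vocab$start_token]])
    stop("prefix must begin with the start token")
  state <- rnn_state0(model$net, 1L)
  for (i in seq_along(prefix)) {
    st <- rnn_step(model$net, state, prefix[i])
    state <- st$state
  }
  p <- policy_probs(st$logits, temperature, .support_mask(vocab))
  stats::setNames(drop(p), vocab$tokens)
}

#' Sample molecules from the generator
#'
#' Autoregressive sampling: each sequence starts at the start token and draws
#' tokens from [next_token_distribution()] until the end token or the length
#' limit. The log-probability the sampling distribution assigned to each
#' emitted token is recorded.
#'
#' @param model A `dmg_policy`.
#' @param n Number of molecules.
#' @param temperature Softmax temperature (1 = unbiased evaluation).
#' @param seed Integer seed; identical seeds reproduce identical samples.
#' @return A list of `n` sample records: `smiles`, `tokens` (emitted payload
#'   tokens), `token_ids`, `logprobs` (one per emitted token, all `<= 0`),
#'   and `terminated` (end token emitted before the limit).
#' @export
sample_batch <- function(model, n, temperature = 1, seed = 1L) {
  stopifnot(n >= 1)
  vocab <- model$vocab
  V <- vocab$size
  end_idx <- vocab$index_of[[vocab$end_token]]
  start_idx <- vocab$index_of[[vocab$start_token]]
  support <- .support_mask(vocab)
  max_steps <- model$config$max_len - 1L
  with_local_seed(derive_seed(seed, "sample"), {
    state <- rnn_state0(model$net, n)
    cur <- rep(start_idx, n)
    alive <- rep(TRUE, n)
    toks <- vector("list", n); lps <- vector("list", n)
    for (t in seq_len(max_steps)) {
      st <- rnn_step(model$net, state, cur)
      state <- st$state
      p <- policy_probs(st$logits, temperature, support)
      nxt <- cur
      for (i in which(alive)) {
        k <- sample.int(V, 1L, prob = p[i, ])
        nxt[i] <- k
        toks[[i]] <- c(toks[[i]], k)
        lps[[i]] <- c(lps[[i]], log(max(p[i, k], .eps_prob)))
      }
      alive <- alive & nxt != end_idx
      cur <- nxt
      if (!any(alive)) break
    }
    lapply(seq_len(n), function(i) {
      ids <- toks[[i]]
      terminated <- length(ids) > 0 && ids[length(ids)] == end_idx
      payload <- if (terminated) ids[-length(ids)] else ids
      list(smiles = paste(vocab$tokens[payload], collapse = ""),
           tokens = unname(vocab$tokens[payload]),
           token_ids = ids, logprobs = lps[[i]], terminated = terminated)
    })
  })
}

#' Save / load a generator checkpoint
#'
#' A checkpoint directory holds the serialized parameter store plus a JSON
#' sidecar with the vocabulary, configuration and training history.
#'
#' @param model A `dmg_policy`.
#' @param dir Checkpoint directory (created if needed).
#' @return `save_policy` returns `dir` invisibly; `load_policy` a
#'   `dmg_policy`.
#' @export
save_policy <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$net, file.path(dir, "params.rds"))
  write_vocabulary(model$vocab, file.path(dir, "vocabulary.json"))
  jsonlite::write_json(list(config = unclass(model$config),
                            history = model$history),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_policy
#' @export
load_policy <- function(dir) {
  net <- readRDS(file.path(dir, "params.rds"))
  vocab <- read_vocabulary(file.path(dir, "vocabulary.json"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  config <- do.call(generator_config, meta$config[
    setdiff(names(meta$config), character(0))])
  structure(list(net = net, vocab = vocab, config = config,
                 history = meta$history), class = "dmg_policy")
}
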