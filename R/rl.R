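# REINFORCE fine-tuning of the generator with the dual-generator exploration
# schedule and the rolling-memory diversity penalty.
#
# Two copies of the pre-trained generator take part: G_u stays frozen
# (exploration) while G_b is updated (exploitation). At every token position
# a uniform draw below the schedule threshold lambda delegates the next token
# to G_u; lambda itself is chosen per batch from the reward trend. Each
# generated molecule is scored by the property oracle, converted to a reward,
# and the reward is cut by a fixed fraction when the molecule is too similar
# (mean Tanimoto distance below kappa) to the last 30 generated molecules.

#' Reinforcement-learning configuration
#'
#' Defaults follow the fine-tuning protocol: 85 iterations of 10-molecule
#' batches, Adam at 1e-3, sampling temperature 0.9, elementwise gradient
#' clipping to +/- 3, exploration schedule `tau = [0.05, 0.2, 0.1]`
#' (reward increasing / decreasing / no trend), diversity threshold
#' `kappa = 0.75`, a 30-molecule memory and a 15% reward penalty. The
#' discount factor gamma (0.97) applies per token position; a
#' per-molecule-index variant is available via `discount_by = "molecule"`.
#'
#' @param objective A [reward_spec()].
#' @param iterations,batch_size Training budget.
#' @param learning_rate,clip_bound Adam step size and gradient clip.
#' @param temperature Sampling temperature during fine-tuning.
#' @param gamma Discount factor in `[0, 1)`.
#' @param tau Numeric triple of lambda values, each in `[0, 1]`:
#'   `[increasing, decreasing, no trend]`.
#' @param kappa Tanimoto-distance threshold below which the penalty fires.
#' @param memory_size Rolling memory capacity (molecules).
#' @param penalty_fraction Fraction of the reward removed by the penalty.
#' @param discount_by `"token"` (position within the molecule) or
#'   `"molecule"` (index within the batch).
#' @param eval_every,eval_n,eval_temperature Periodic snapshot evaluation:
#'   every `eval_every` iterations, `eval_n` molecules are sampled at
#'   `eval_temperature` and scored for desirability and internal diversity.
#' @return A `dmg_rl_config`.
#' @export
rl_config <- function(objective, iterations = 85L, batch_size = 10L,
                      learning_rate = 1e-3, temperature = 0.9,
                      clip_bound = 3, gamma = 0.97,
                      tau = c(0.05, 0.2, 0.1), kappa = 0.75,
                      memory_size = 30L, penalty_fraction = 0.15,
                      discount_by = c("token", "molecule"),
                      eval_every = 10L, eval_n = 500L, eval_temperature = 1) {
  discount_by <- match.arg(discount_by)
  stopifnot(inherits(objective, "dmg_reward_spec"),
            all(tau >= 0 & tau <= 1), length(tau) == 3,
            kappa >= 0, kappa <= 1, gamma >= 0, gamma < 1,
            penalty_fraction >= 0, penalty_fraction < 1, memory_size >= 1)
  structure(list(objective = objective, iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, temperature = temperature,
                 clip_bound = clip_bound, gamma = gamma, tau = tau,
                 kappa = kappa, memory_size = as.integer(memory_size),
                 penalty_fraction = penalty_fraction,
                 discount_by = discount_by,
                 eval_every = as.integer(eval_every),
                 eval_n = as.integer(eval_n),
                 eval_temperature = eval_temperature),
            class = "dmg_rl_config")
}

#' Select the exploration threshold from the reward trend
#'
#' With fewer than three recorded batch means the no-trend value applies.
#' Otherwise the last two deltas of the batch-mean reward decide: both
#' positive (reward increasing) selects `tau[1]`, both negative `tau[2]`,
#' and a mixed trend `tau[3]`.
#'
#' @param history Numeric vector of per-batch mean rewards (oldest first).
#' @param tau Numeric triple `[increasing, decreasing, no trend]`.
#' @return One element of `tau`.
#' @export
select_lambda <- function(history, tau) {
  stopifnot(length(tau) == 3)
  n <- length(history)
  if (n < 3) return(tau[3])
  d1 <- history[n - 1] - history[n - 2]
  d2 <- history[n] - history[n - 1]
  if (d1 > 0 && d2 > 0) tau[1]
  else if (d1 < 0 && d2 < 0) tau[2]
  else tau[3]
}

#' Rolling diversity memory
#'
#' FIFO store of the fingerprints of the most recently generated valid
#' molecules, capped at `size` entries (oldest evicted first).
#'
#' @param size Capacity (default 30).
#' @return A `dmg_diversity_memory`.
#' @export
new_diversity_memory <- function(size = 30L) {
  structure(list(entries = list(), size = as.integer(size)),
            class = "dmg_diversity_memory")
}

#' Memory-based diversity penalty
#'
#' Computes the mean Tanimoto distance between the candidate molecule's
#' fingerprint and every fingerprint in the memory. If the memory is
#' non-empty and that distance falls below `kappa`, the reward is cut to
#' `(1 - penalty_fraction)` of its value. The candidate is then pushed into
#' the memory (FIFO).
#'
#' @param reward Scalar reward before the penalty.
#' @param fp Integer vector of fingerprint on-bit indices.
#' @param memory A [new_diversity_memory()].
#' @param kappa Distance threshold in `[0, 1]`.
#' @param penalty_fraction Fraction removed when triggered (default 0.15).
#' @return List: `reward` (adjusted), `triggered` (logical), `memory`
#'   (updated).
#' @export
memory_diversity_penalty <- function(reward, fp, memory, kappa,
                                     penalty_fraction = 0.15) {
  stopifnot(inherits(memory, "dmg_diversity_memory"))
  triggered <- FALSE
  if (length(memory$entries) > 0) {
    d <- mean(vapply(memory$entries,
                     function(m) 1 - tanimoto_similarity(fp, m), numeric(1)))
    triggered <- d < kappa
  }
  if (triggered) reward <- reward * (1 - penalty_fraction)
  memory$entries <- c(memory$entries, list(fp))
  if (length(memory$entries) > memory$size)
    memory$entries <- memory$entries[-1]
  list(reward = reward, triggered = triggered, memory = memory)
}

#' Sample molecules from the two-generator policy mixture
#'
#' Autoregressive sampling in which, at every token position, a uniform draw
#' `epsilon` below `lam` delegates the next token to the frozen generator
#' `g_u`, and otherwise the updated generator `g_b` emits it. Both models
#' condition on the same shared prefix. Step log-probabilities are recorded
#' under `g_b`'s (temperature-scaled, support-masked) distribution — the
#' policy being optimized — regardless of which model emitted the token.
#'
#' @param g_b,g_u `dmg_policy` models sharing one vocabulary.
#' @param n Number of molecules.
#' @param lam Delegation probability in `[0, 1]`.
#' @param temperature Softmax temperature.
#' @param seed Integer seed.
#' @return List of sample records as in [sample_batch()], each with an extra
#'   logical vector `from_gu` flagging the provenance of every emitted token.
#' @export
dual_sample <- function(g_b, g_u, n = 1L, lam, temperature = 0.9, seed = 1L) {
  if (!identical(g_b$vocab$tokens, g_u$vocab$tokens))
    stop("the two generators must share one vocabulary")
  stopifnot(lam >= 0, lam <= 1)
  vocab <- g_b$vocab
  V <- vocab$size
  end_idx <- vocab$index_of[[vocab$end_token]]
  start_idx <- vocab$index_of[[vocab$start_token]]
  support <- .support_mask(vocab)
  max_steps <- g_b$config$max_len - 1L
  with_local_seed(derive_seed(seed, "dual"), {
    sb <- rnn_state0(g_b$net, n); su <- rnn_state0(g_u$net, n)
    cur <- rep(start_idx, n)
    alive <- rep(TRUE, n)
    toks <- vector("list", n); lps <- vector("list", n); prov <- vector("list", n)
    for (t in seq_len(max_steps)) {
      stb <- rnn_step(g_b$net, sb, cur); sb <- stb$state
      stu <- rnn_step(g_u$net, su, cur); su <- stu$state
      pb <- policy_probs(stb$logits, temperature, support)
      pu <- policy_probs(stu$logits, temperature, support)
      eps <- stats::runif(n)
      nxt <- cur
      for (i in which(alive)) {
        use_u <- eps[i] < lam
        p <- if (use_u) pu[i, ] else pb[i, ]
        k <- sample.int(V, 1L, prob = p)
        nxt[i] <- k
        toks[[i]] <- c(toks[[i]], k)
        lps[[i]] <- c(lps[[i]], log(max(pb[i, k], .eps_prob)))
        prov[[i]] <- c(prov[[i]], use_u)
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
           token_ids = ids, logprobs = lps[[i]], from_gu = prov[[i]],
           terminated = terminated)
    })
  })
}

#' REINFORCE loss of a trajectory batch
#'
#' `J = -(1/n) sum_i sum_j R_i * gamma^e * log p(s_ij)`, with `e` the token
#' position `j` (starting at 1) by default, or the molecule index `i` when
#' `discount_by = "molecule"` (the per-molecule-index variant).
#'
#' @param samples List of sample records carrying `logprobs`.
#' @param rewards Numeric vector, one (post-penalty) reward per molecule.
#' @param gamma Discount factor.
#' @param discount_by `"token"` or `"molecule"`.
#' @return Scalar loss.
#' @export
reinforce_loss <- function(samples, rewards, gamma,
                           discount_by = c("token", "molecule")) {
  discount_by <- match.arg(discount_by)
  n <- length(samples)
  if (n == 0L) stop("empty batch")
  stopifnot(length(rewards) == n, all(is.finite(rewards)))
  total <- 0
  for (i in seq_len(n)) {
    lp <- samples[[i]]$logprobs
    if (length(lp) == 0L) next
    disc <- if (discount_by == "token") gamma^seq_along(lp) else gamma^i
    total <- total + sum(rewards[i] * disc * lp)
  }
  -total / n
}

#' One REINFORCE parameter update
#'
#' Teacher-forced reconstruction of the sampled sequences under the policy
#' being optimized, to obtain differentiable log-probabilities of every taken
#' action, followed by an Adam step with elementwise gradient clipping.
#' Exposed so custom loops (e.g. bandit-style convergence experiments) can
#' drive the identical update used by [rl_training_run()].
#'
#' @param model The `dmg_policy` being updated.
#' @param samples Sample records from [sample_batch()] or [dual_sample()].
#' @param rewards One (post-penalty) reward per sample.
#' @param config An [rl_config()] (temperature, gamma, discounting, learning
#'   rate and clip bound are used).
#' @param opt Adam state from a previous call, or `NULL` to start fresh.
#' @return List: `model` (updated), `opt`, `loss` (the REINFORCE loss value).
#' @export
reinforce_update <- function(model, samples, rewards, config, opt = NULL) {
  if (is.null(opt)) opt <- adam_new(model$net$params)
  vocab <- model$vocab
  start_idx <- vocab$index_of[[vocab$start_token]]
  pad_idx <- vocab$index_of[[vocab$pad_token]]
  support <- .support_mask(vocab)
  n <- length(samples)
  lens <- vapply(samples, function(s) length(s$token_ids), integer(1))
  Tn <- max(lens)
  if (Tn == 0L) return(list(model = model, opt = opt, loss = 0))
  X <- matrix(pad_idx, n, Tn)      # inputs: G then the sampled prefix
  Y <- matrix(NA_integer_, n, Tn)  # chosen tokens (targets)
  for (i in seq_len(n)) {
    ids <- samples[[i]]$token_ids
    if (length(ids) == 0L) next
    X[i, 1] <- start_idx
    if (length(ids) > 1L) X[i, 2:length(ids)] <- ids[-length(ids)]
    Y[i, seq_along(ids)] <- ids
  }
  fwd <- rnn_forward(model$net, X, train = TRUE)
  loss <- 0
  dlog <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    p <- policy_probs(fwd$logits[[t]], config$temperature, support)
    act <- which(!is.na(Y[, t]) & rewards != 0)
    dl <- matrix(0, n, vocab$size)
    for (i in act) {
      disc <- if (config$discount_by == "token") config$gamma^t
              else config$gamma^i
      coef <- rewards[i] * disc / n
      k <- Y[i, t]
      loss <- loss - coef * log(max(p[i, k], .eps_prob))
      # gradient of -coef * log softmax(z/temp)[k] with respect to z
      dl[i, ] <- (coef / config$temperature) * p[i, ]
      dl[i, k] <- dl[i, k] - coef / config$temperature
    }
    dlog[[t]] <- dl
  }
  g <- rnn_backward(model$net, X, fwd, dlog)
  st <- adam_step(model$net$params, g, opt, lr = config$learning_rate,
                  clip = config$clip_bound)
  model$net$params <- st$params
  list(model = model, opt = st$opt, loss = loss)
}

#' Fine-tune the generator by REINFORCE
#'
#' Runs the full reinforcement loop: the biased generator starts as a copy of
#' the pre-trained one; each iteration selects the exploration threshold from
#' the reward trend, samples a batch from the two-generator mixture, scores
#' valid molecules through the objective's property oracle, applies the
#' rolling-memory diversity penalty, and updates the biased generator with
#' clipped REINFORCE gradients. Invalid molecules (or oracle failures) take
#' the objective's `invalid_reward` and never enter the memory. Every
#' `eval_every` iterations a snapshot of `eval_n` sampled molecules is scored
#' for desirability and internal Tanimoto diversity, and the snapshot
#' maximizing `desirable fraction x diversity` is kept as the best
#' checkpoint.
#'
#' @param g_u The pre-trained (frozen) `dmg_policy`.
#' @param config An [rl_config()].
#' @param seed Integer master seed.
#' @param verbose Print per-iteration progress.
#' @return A `dmg_rl_run`: `model` (final G_b), `best_model` and
#'   `best_iteration` (snapshot checkpoint), `log` (per-iteration
#'   data.frame: `iteration`, `lambda`, `mean_reward`, `validity`,
#'   `penalty_triggers`), `history` (batch mean rewards) and `snapshots`.
#' @export
rl_training_run <- function(g_u, config, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(g_u, "dmg_policy"), inherits(config, "dmg_rl_config"))
  g_b <- g_u
  opt <- adam_new(g_b$net$params)
  memory <- new_diversity_memory(config$memory_size)
  history <- numeric(0)
  spec <- config$objective
  desir <- desirability_rule(spec)
  log_rows <- vector("list", config$iterations)
  snapshots <- list()
  for (it in seq_len(config$iterations)) {
    lam <- select_lambda(history, config$tau)
    samples <- dual_sample(g_b, g_u, n = config$batch_size, lam = lam,
                           temperature = config$temperature,
                           seed = derive_seed(seed, paste0("it", it)))
    smiles <- vapply(samples, `[[`, character(1), "smiles")
    valid <- smiles_valid(smiles)
    rewards <- rep(spec$invalid_reward, length(samples))
    triggers <- 0L
    if (any(valid)) {
      vals <- tryCatch(spec$property_oracle(smiles[valid]),
                       error = function(e) rep(NA_real_, sum(valid)))
      fps <- morgan_fingerprints(smiles[valid])
      vi <- which(valid)
      for (j in seq_along(vi)) {
        if (is.na(vals[j]) || is.null(fps[[j]])) next
        r <- compute_reward(vals[j], spec)
        adj <- memory_diversity_penalty(r, fps[[j]], memory, config$kappa,
                                        config$penalty_fraction)
        rewards[vi[j]] <- adj$reward
        memory <- adj$memory
        triggers <- triggers + adj$triggered
      }
    }
    upd <- reinforce_update(g_b, samples, rewards, config, opt)
    g_b <- upd$model; opt <- upd$opt
    history <- c(history, mean(rewards))
    log_rows[[it]] <- data.frame(iteration = it, lambda = lam,
                                 mean_reward = mean(rewards),
                                 validity = mean(valid),
                                 penalty_triggers = triggers)
    if (config$eval_every > 0 && it %% config$eval_every == 0L) {
      sm <- sample_batch(g_b, config$eval_n,
                         temperature = config$eval_temperature,
                         seed = derive_seed(seed, paste0("eval", it)))
      smi <- vapply(sm, `[[`, character(1), "smiles")
      v <- smiles_valid(smi)
      frac_des <- if (any(v)) mean(desir(smi[v])) else 0
      int_div <- if (sum(v) >= 2) set_diversity(smi[v]) else 0
      snapshots[[length(snapshots) + 1L]] <-
        list(iteration = it, frac_desirable = frac_des,
             internal_diversity = int_div, validity = mean(v),
             params = g_b$net$params)
    }
    if (verbose)
      message(sprintf("iter %3d  lambda %.2f  reward %.3f  valid %.0f%%  penalties %d",
                      it, lam, mean(rewards), 100 * mean(valid), triggers))
  }
  best_idx <- if (length(snapshots)) select_checkpoint(snapshots) else NA_integer_
  best_model <- g_b
  if (!is.na(best_idx)) best_model$net$params <- snapshots[[best_idx]]$params
  structure(list(model = g_b, best_model = best_model,
                 best_iteration = if (is.na(best_idx)) NA_integer_
                                  else snapshots[[best_idx]]$iteration,
                 log = do.call(rbind, log_rows), history = history,
                 snapshots = snapshots), class = "dmg_rl_run")
}

#' Choose the best snapshot of a reinforcement run
#'
#' Among the periodic snapshot evaluations, returns the index of the snapshot
#' maximizing `frac_desirable * internal_diversity`; ties resolve to the
#' earliest iteration.
#'
#' @param snapshots List of snapshot records (from [rl_training_run()]).
#' @return Integer index into `snapshots`.
#' @export
select_checkpoint <- function(snapshots) {
  if (length(snapshots) == 0L) stop("no snapshots recorded")
  scores <- vapply(snapshots, function(s)
    s$frac_desirable * s$internal_diversity, numeric(1))
  which.max(scores)   # which.max takes the earliest on ties
}

#' @export
print.dmg_rl_run <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<dmg_rl_run> %d iterations; mean reward %.3f -> %.3f; best snapshot at iteration %s\n",
              n, mean(utils::head(x$history, 10)),
              mean(utils::tail(x$history, 10)),
              ifelse(is.na(x$best_iteration), "<none>", x$best_iteration)))
  invisible(x)
}
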