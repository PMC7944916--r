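test_that("the reward rule follows the exponential conversion", {
  spec <- reward_spec("logp_range")   # oracle unused for compute_reward
  max_spec <- structure(list(mode = "maximize_pic50", invalid_reward = 0,
                             k0 = 2), class = "dmg_reward_spec")
  expect_equal(compute_reward(4, max_spec), 1)
  expect_equal(compute_reward(8, max_spec), exp(1))
  expect_gt(compute_reward(6.5, max_spec), compute_reward(6.0, max_spec))
  ps <- seq(2, 10, by = 0.5)
  expect_true(all(diff(compute_reward(ps, max_spec)) > 0))
  min_spec <- structure(list(mode = "minimize_pic50", invalid_reward = 0,
                             k0 = 2), class = "dmg_reward_spec")
  expect_true(all(diff(compute_reward(ps, min_spec)) < 0))
  expect_true(all(compute_reward(ps, min_spec) > 0))
  # logP window: flat plateau inside, smooth positive decay outside
  expect_equal(compute_reward(1, spec), 3)
  expect_equal(compute_reward(2.5, spec), 3)
  expect_equal(compute_reward(4, spec), 3)
  expect_equal(compute_reward(5, spec), 3 * exp(-1))
  expect_equal(compute_reward(-1, spec), 3 * exp(-2))
  expect_true(all(compute_reward(seq(-5, 10, 0.5), spec) > 0))
})

test_that("the exploration threshold tracks the reward trend", {
  tau2 <- c(0.05, 0.2, 0.1)
  expect_equal(select_lambda(c(1.0, 1.1, 1.2), tau2), 0.05)
  expect_equal(select_lambda(c(1.2, 1.1, 1.0), tau2), 0.2)
  expect_equal(select_lambda(c(1.0, 1.2, 1.1), tau2), 0.1)
  expect_equal(select_lambda(numeric(0), tau2), 0.1)
  expect_equal(select_lambda(c(1, 2), tau2), 0.1)
  # always a member of tau, replayable from history alone
  set.seed(5)
  for (k in 1:50) {
    h <- cumsum(rnorm(sample(1:10, 1)))
    expect_true(select_lambda(h, tau2) %in% tau2)
  }
})

test_that("the memory penalty is exact and the memory a strict FIFO", {
  fp <- c(1L, 5L, 9L)
  mem <- new_diversity_memory(30)
  r0 <- memory_diversity_penalty(2, fp, mem, kappa = 0.75)
  expect_equal(r0$reward, 2)          # empty memory: unchanged
  expect_false(r0$triggered)
  # thirty identical molecules, identical candidate: distance 0 < kappa
  mem <- new_diversity_memory(30)
  for (i in 1:30) mem <- memory_diversity_penalty(1, fp, mem, 0.75)$memory
  hit <- memory_diversity_penalty(2, fp, mem, kappa = 0.75)
  expect_true(hit$triggered)
  expect_identical(hit$reward, 2 * 0.85)
  # fully disjoint candidate: distance 1 >= kappa, unchanged
  miss <- memory_diversity_penalty(2, c(100L, 200L), mem, kappa = 0.75)
  expect_false(miss$triggered)
  expect_identical(miss$reward, 2)
  # capacity 30 with first-in evicted first
  mem <- new_diversity_memory(30)
  for (i in 1:31)
    mem <- memory_diversity_penalty(1, c(i, i + 1000L), mem, 0.75)$memory
  expect_length(mem$entries, 30)
  firsts <- vapply(mem$entries, `[[`, numeric(1), 1)
  expect_false(1 %in% firsts)    # molecule 1 evicted
  expect_true(31 %in% firsts)
})

test_that("dual sampling respects the delegation probability", {
  gb <- toy_policy(); gu <- toy_policy_b()
  s0 <- dual_sample(gb, gu, n = 20, lam = 0, temperature = 0.9, seed = 1)
  expect_false(any(unlist(lapply(s0, `[[`, "from_gu"))))
  s1 <- dual_sample(gb, gu, n = 20, lam = 1, temperature = 0.9, seed = 1)
  expect_true(all(unlist(lapply(s1, `[[`, "from_gu"))))
  # log-probabilities are recorded under the updated policy G_b
  smp <- s1[[1]]
  prefix <- gb$vocab$index_of[[gb$vocab$start_token]]
  for (j in seq_along(smp$token_ids)) {
    p <- next_token_distribution(gb, gb$vocab$tokens[prefix], temperature = 0.9)
    expect_equal(exp(smp$logprobs[j]), unname(p[smp$token_ids[j]]),
                 tolerance = 1e-9)
    prefix <- c(prefix, smp$token_ids[j])
  }
})

test_that("the REINFORCE loss matches hand evaluation and is linear in reward", {
  samples <- list(list(logprobs = -1))
  expect_equal(reinforce_loss(samples, rewards = 2, gamma = 0.9), 1.8)
  expect_equal(reinforce_loss(list(list(logprobs = numeric(0))), 0, 0.9), 0)
  set.seed(3)
  batch <- lapply(1:4, function(i) list(logprobs = -runif(sample(1:6, 1))))
  r <- runif(4)
  expect_equal(reinforce_loss(batch, rewards = rep(0, 4), gamma = 0.9), 0)
  expect_equal(reinforce_loss(batch, 2 * r, 0.9),
               2 * reinforce_loss(batch, r, 0.9), tolerance = 1e-12)
  # hand evaluation with token-position discounting (j from 1)
  manual <- -mean(vapply(seq_along(batch), function(i) {
    lp <- batch[[i]]$logprobs
    sum(r[i] * 0.9^seq_along(lp) * lp)
  }, numeric(1)))
  expect_equal(reinforce_loss(batch, r, 0.9), manual, tolerance = 1e-12)
  # per-molecule-index discount variant
  manual_m <- -mean(vapply(seq_along(batch), function(i)
    sum(r[i] * 0.9^i * batch[[i]]$logprobs), numeric(1)))
  expect_equal(reinforce_loss(batch, r, 0.9, discount_by = "molecule"),
               manual_m, tolerance = 1e-12)
  expect_error(reinforce_loss(list(), numeric(0), 0.9), "empty")
})

test_that("one policy-gradient update moves probability toward the rewarded token", {
  vocab <- build_vocabulary(c("C", "O"))
  cfg <- generator_config(recurrent_layers = 1, recurrent_units = 8,
                          max_len = 3, epochs = 1)
  model <- new_policy(vocab, cfg, seed = 5)
  rcfg <- rl_config(reward_spec("logp_range"), temperature = 1, gamma = 0.97,
                    learning_rate = 0.05)
  p_before <- next_token_distribution(model, "G")[["C"]]
  samples <- sample_batch(model, 20, temperature = 1, seed = 2)
  first <- vapply(samples, function(s) if (length(s$tokens)) s$tokens[1] else "",
                  character(1))
  rewards <- ifelse(first == "C", 1.0, 0.1)
  upd <- reinforce_update(model, samples, rewards, rcfg, NULL)
  p_after <- next_token_distribution(upd$model, "G")[["C"]]
  expect_gt(p_after, p_before)
})

test_that("short reinforcement runs are seed-deterministic", {
  g <- toy_policy()
  rcfg <- rl_config(reward_spec("logp_range"), iterations = 5, eval_every = 0)
  r1 <- rl_training_run(g, rcfg, seed = 9)
  r2 <- rl_training_run(g, rcfg, seed = 9)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$log, r2$log)
  expect_equal(nrow(r1$log), 5)
  expect_true(all(r1$log$lambda %in% rcfg$tau))
})

test_that("checkpoint selection maximizes desirability x diversity with early ties", {
  snaps <- list(list(iteration = 10, frac_desirable = 0.5, internal_diversity = 1),
                list(iteration = 20, frac_desirable = 0.9, internal_diversity = 1),
                list(iteration = 30, frac_desirable = 0.7, internal_diversity = 1))
  expect_equal(select_checkpoint(snaps), 2)
  expect_equal(select_checkpoint(snaps[1]), 1)
  tie <- list(list(iteration = 10, frac_desirable = 0.8, internal_diversity = 0.5),
              list(iteration = 20, frac_desirable = 0.5, internal_diversity = 0.8))
  expect_equal(select_checkpoint(tie), 1)
  expect_error(select_checkpoint(list()), "no snapshots")
})
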