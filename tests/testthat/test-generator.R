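test_that("teacher-forcing loss matches hand computations", {
  # probability 1 on every correct token: loss at the epsilon-induced floor
  y <- diag(3)
  expect_lt(teacher_forcing_loss(y, y), 1e-6)
  # single-step binary form: correct-token probability 0.5
  expect_equal(teacher_forcing_loss(matrix(1), matrix(0.5)), -log(0.5),
               tolerance = 1e-9)
  # random 5-step case against an independently hand-summed evaluation
  set.seed(1)
  V <- 4; Tn <- 5
  yh <- t(apply(matrix(runif(Tn * V), Tn), 1, function(r) r / sum(r)))
  y <- matrix(0, Tn, V); y[cbind(1:Tn, sample(1:V, Tn, TRUE))] <- 1
  manual <- 0
  for (t in 1:Tn) for (k in 1:V)
    manual <- manual - (y[t, k] * log(yh[t, k]) +
                        (1 - y[t, k]) * log(1 - yh[t, k])) / Tn
  expect_equal(teacher_forcing_loss(y, yh), manual, tolerance = 1e-12)
  # mask excludes pad steps from sum and normalizer
  masked <- teacher_forcing_loss(y, yh, mask = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  manual2 <- 0
  for (t in 1:2) for (k in 1:V)
    manual2 <- manual2 - (y[t, k] * log(yh[t, k]) +
                          (1 - y[t, k]) * log(1 - yh[t, k])) / 2
  expect_equal(masked, manual2, tolerance = 1e-12)
})

test_that("loss decreases along a 1-D sweep of correct-token mass", {
  masses <- seq(0.1, 0.9, by = 0.1)
  losses <- vapply(masses, function(m) {
    yh <- matrix(c(m, (1 - m) / 2, (1 - m) / 2), 1)
    teacher_forcing_loss(matrix(c(1, 0, 0), 1), yh)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("training reduces the loss epoch over epoch", {
  g <- toy_policy()
  expect_lt(utils::tail(g$history, 1), g$history[1])
})

test_that("a single repeated SMILES is memorized and reproduced at low temperature", {
  m <- train_generator(rep("CCO", 32),
                       generator_config(recurrent_units = 24, max_len = 8,
                                        epochs = 80, dropout = 0), seed = 2)
  sm <- sample_batch(m, 3, temperature = 0.01, seed = 1)
  expect_identical(vapply(sm, `[[`, character(1), "smiles"),
                   rep("CCO", 3))
})

test_that("next-token distributions are proper and temperature behaves", {
  g <- toy_policy()
  v <- g$vocab
  set.seed(4)
  for (k in 1:20) {
    prefix <- c("G", sample(c("C", "N", "O", "("), sample(0:4, 1), TRUE))
    p <- next_token_distribution(g, prefix)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
    expect_equal(unname(p[v$pad_token]), 0)   # pad excluded from support
    expect_equal(unname(p[v$start_token]), 0)
  }
  p1 <- next_token_distribution(g, "G", temperature = 1)
  p0 <- next_token_distribution(g, "G", temperature = 0.002)
  expect_gt(max(p0), 0.99)                    # temperature -> 0 concentrates
  expect_equal(which.max(p0), which.max(p1))
  entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  p10 <- next_token_distribution(g, "G", temperature = 10)
  expect_gt(entropy(p10), entropy(p1))
  expect_error(next_token_distribution(g, "G", temperature = 0), "temperature")
  expect_error(next_token_distribution(g, c("C")), "start token")
})

test_that("sampling is seed-reproducible and log-probabilities are faithful", {
  g <- toy_policy()
  s1 <- sample_batch(g, 5, temperature = 0.9, seed = 3)
  s2 <- sample_batch(g, 5, temperature = 0.9, seed = 3)
  expect_identical(vapply(s1, `[[`, character(1), "smiles"),
                   vapply(s2, `[[`, character(1), "smiles"))
  expect_true(all(unlist(lapply(s1, `[[`, "logprobs")) <= 0))
  # recompute each step's probability post hoc from the model
  smp <- s1[[1]]
  prefix <- g$vocab$index_of[[g$vocab$start_token]]
  for (j in seq_along(smp$token_ids)) {
    p <- next_token_distribution(g, g$vocab$tokens[prefix], temperature = 0.9)
    expect_equal(exp(smp$logprobs[j]), unname(p[smp$token_ids[j]]),
                 tolerance = 1e-9)
    prefix <- c(prefix, smp$token_ids[j])
  }
  expect_equal(length(smp$logprobs), length(smp$token_ids))
})

test_that("checkpoints round-trip through save and load", {
  g <- toy_policy()
  dir <- withr::local_tempdir()
  save_policy(g, dir)
  g2 <- load_policy(dir)
  expect_identical(g2$vocab$tokens, g$vocab$tokens)
  s1 <- sample_batch(g, 4, seed = 8)
  s2 <- sample_batch(g2, 4, seed = 8)
  expect_identical(vapply(s1, `[[`, character(1), "smiles"),
                   vapply(s2, `[[`, character(1), "smiles"))
})

test_that("over-length molecules are dropped with a message", {
  long <- paste(rep("C", 40), collapse = "")
  expect_message(
    m <- train_generator(c(rep("CCO", 30), long),
                         generator_config(recurrent_units = 8, max_len = 10,
                                          epochs = 1), seed = 1),
    "over-length")
  expect_error(train_generator(character(0)), "empty")
})
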