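# Shared fixtures, built once per test run and cached across files.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

fixture_corpus_small <- function() {
  get_fixture("corpus300", function() generate_fixture_corpus(300, seed = 5))
}

# A small but usable generator: enough training that samples are sometimes
# valid molecules; cheap enough (~10 s) to share across tests.
toy_policy <- function() {
  get_fixture("toy_policy", function()
    train_generator(generate_fixture_corpus(400, seed = 5),
                    generator_config(recurrent_units = 48, max_len = 32,
                                     epochs = 4, dropout = 0.15),
                    seed = 11))
}

# An independent second policy over the same vocabulary (for dual sampling).
toy_policy_b <- function() {
  get_fixture("toy_policy_b", function() {
    g <- toy_policy()
    new_policy(g$vocab, g$config, seed = 77)
  })
}

# Hand-written dynamic-programming edit distance (independent oracle).
dp_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (ca[i] != cb[j]))
  d[n + 1, m + 1]
}

random_string <- function(max_len = 12) {
  paste(sample(c(LETTERS[1:6], "(", ")", "=", "1"), sample(0:max_len, 1),
               replace = TRUE), collapse = "")
}
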