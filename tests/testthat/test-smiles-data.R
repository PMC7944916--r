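test_that("tokenizer splits multi-character tokens and round-trips", {
  expect_identical(tokenize("CNC(C)=O"), c("C", "N", "C", "(", "C", ")", "=", "O"))
  expect_identical(tokenize("CCO"), c("C", "C", "O"))
  toks <- tokenize("c1ccccc1Br")
  expect_length(toks, 9)
  expect_identical(toks[9], "Br")
  expect_identical(tokenize("CCl"), c("C", "Cl"))
  expect_identical(tokenize("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
  expect_identical(tokenize("[NH4+]C"), c("[NH4+]", "C"))
  # concatenation reproduces the input on a whole corpus
  for (s in fixture_corpus_small()[1:100])
    expect_identical(paste(tokenize(s), collapse = ""), s)
})

test_that("tokenizer errors name the offending character and position", {
  expect_error(tokenize("C[NH"), "dangling '\\['")
  expect_error(tokenize("C%1"), "dangling '%'")
  expect_error(tokenize("CCq"), "'q' at position 3")
  expect_error(tokenize(""), "non-empty")
})

test_that("vocabulary is specials-first, sorted and bijective", {
  v <- build_vocabulary(c("CCO"))
  expect_identical(v$tokens, c(" ", "G", "E", "C", "O"))
  expect_equal(v$size, 5)
  expect_identical(unname(v$index_of[v$tokens]), seq_len(v$size))
  v2 <- build_vocabulary(c("CCl"))
  expect_true("Cl" %in% v2$tokens)
  expect_false("l" %in% v2$tokens)
  expect_error(build_vocabulary("CCO", start_token = "G", end_token = "G"),
               "distinct")
  # persistence round-trip
  p <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(v, p)
  expect_identical(read_vocabulary(p)$tokens, v$tokens)
})

test_that("padding wraps sequences in start/end and fixed length", {
  expect_identical(pad_and_mark(tokenize("CNC(C)=O"), 10),
                   c("G", "C", "N", "C", "(", "C", ")", "=", "O", "E"))
  padded <- pad_and_mark(character(0), 65)
  expect_length(padded, 65)
  expect_identical(padded[1:2], c("G", "E"))
  expect_identical(unique(padded[3:65]), " ")
  expect_error(pad_and_mark(rep("C", 64), 65), "capacity")
})

test_that("encode/decode round-trips in both modes", {
  corpus <- fixture_corpus_small()[1:100]
  v <- build_vocabulary(corpus)
  padded <- lapply(lapply(corpus, tokenize), pad_and_mark, max_len = 32,
                   vocab = v)
  for (mode in c("integer", "onehot")) {
    enc <- encode_batch(padded, v, mode = mode)
    expect_identical(decode_batch(enc), padded)
  }
  oh <- encode_batch(padded[1:5], v, mode = "onehot")
  expect_true(all(apply(oh, c(1, 2), sum) == 1))
  expect_true(all(oh %in% c(0L, 1L)))
  vi <- build_vocabulary("C")   # tokens: pad G E C
  expect_identical(unname(unclass(encode_batch(list(c("G", "C", "E")), vi))[1, ]),
                   c(2L, 4L, 3L))
  expect_error(encode_batch(list(c("G", "N", "E")), vi), "'N'")
})

test_that("curation canonicalizes, deduplicates and filters", {
  # duplicate canonical forms collapse to one record
  cur <- curate_corpus(c("OCC", "CCO"), logp_range = c(-10, 10),
                       mw_range = c(0, 1000))
  expect_equal(nrow(cur), 1)
  # molecular-weight window
  cur2 <- curate_corpus(c("CCO"), logp_range = c(-10, 10), mw_range = c(200, 600))
  expect_equal(nrow(cur2), 0)
  # survivor count matches a brute-force filter on 20 straddling records
  smis <- generate_fixture_corpus(20, seed = 33)
  lp_r <- c(0, 2); mw_r <- c(60, 120)
  cur3 <- curate_corpus(smis, logp_range = lp_r, mw_range = mw_r)
  props <- mol_properties(smis)
  props <- props[!duplicated(props$canonical), ]
  brute <- sum(props$logp >= lp_r[1] & props$logp <= lp_r[2] &
               props$mw >= mw_r[1] & props$mw <= mw_r[2])
  expect_equal(nrow(cur3), brute)
  # idempotence
  again <- curate_corpus(cur3$smiles, logp_range = lp_r, mw_range = mw_r)
  expect_identical(again$smiles, cur3$smiles)
  # activity labels: duplicates collapse to the median
  act <- data.frame(smiles = c("CCO", "OCC", "CCN"), pic50 = c(5, 7, 6))
  cura <- curate_corpus(act, logp_range = c(-10, 10), mw_range = c(0, 1000))
  expect_equal(cura$pic50[cura$smiles == "CCO"], 6)
})

test_that("fixture corpus is deterministic, valid and diverse", {
  expect_identical(generate_fixture_corpus(10, seed = 1),
                   generate_fixture_corpus(10, seed = 1))
  smis <- generate_fixture_corpus(2000, seed = 7)
  expect_true(all(smiles_valid(smis)))
  uniq <- mean(!duplicated(canonical_smiles(smis)))
  expect_gt(uniq, 0.5)
})

test_that("smi and activity-table io round-trips", {
  p <- withr::local_tempfile(fileext = ".smi")
  write_smi(c("CCO", "CCN"), p)
  expect_identical(read_smi(p), c("CCO", "CCN"))
  writeLines(c("CCO mol1", "CCN mol2"), p)   # optional id column ignored
  expect_identical(read_smi(p), c("CCO", "CCN"))
  pc <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = "CCO", pIC50 = 6.1), pc, row.names = FALSE)
  tab <- read_activity_csv(pc)
  expect_identical(names(tab), c("smiles", "pic50"))
  expect_equal(tab$pic50, 6.1)
})
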