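test_that("the curate stage writes artifacts consistent with direct curation", {
  smis <- generate_fixture_corpus(20, seed = 33)
  src <- withr::local_tempfile(fileext = ".smi")
  write_smi(smis, src)
  out <- file.path(withr::local_tempdir(), "run-curate")
  man <- run_experiment(list(stage = "curate", inputs = list(corpus = src),
                             out = out, seed = 1,
                             stage_config = list(logp_range = c(-10, 10),
                                                 mw_range = c(0, 1000))))
  direct <- curate_corpus(smis, logp_range = c(-10, 10), mw_range = c(0, 1000))
  info <- jsonlite::read_json(file.path(out, "curation.json"),
                              simplifyVector = TRUE)
  expect_equal(info$n, nrow(direct))
  expect_identical(read_smi(file.path(out, "curated.smi")), direct$smiles)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(all(names(man$artifact_md5) %in%
                  list.files(out, full.names = TRUE)))
})

test_that("identical config and seed reproduce identical artifact hashes", {
  g <- toy_policy()
  ckpt <- file.path(withr::local_tempdir(), "gen")
  save_policy(g, ckpt)
  base <- withr::local_tempdir()
  cfg <- function(out) list(stage = "sample", inputs = list(generator = ckpt),
                            out = out, seed = 42,
                            stage_config = list(n = 30L, temperature = 1))
  m1 <- run_experiment(cfg(file.path(base, "a")))
  m2 <- run_experiment(cfg(file.path(base, "b")))
  expect_identical(unname(unlist(m1$artifact_md5)),
                   unname(unlist(m2$artifact_md5)))
})

test_that("completed runs are protected unless resumed", {
  smis <- generate_fixture_corpus(5, seed = 1)
  src <- withr::local_tempfile(fileext = ".smi")
  write_smi(smis, src)
  out <- file.path(withr::local_tempdir(), "run")
  cfg <- list(stage = "curate", inputs = list(corpus = src), out = out,
              seed = 1, stage_config = list(logp_range = c(-10, 10),
                                            mw_range = c(0, 1000)))
  run_experiment(cfg)
  md5_before <- tools::md5sum(file.path(out, "curated.smi"))
  expect_error(run_experiment(cfg), "resume")
  cfg$resume <- TRUE
  man <- run_experiment(cfg)
  expect_identical(tools::md5sum(file.path(out, "curated.smi")), md5_before)
  expect_equal(man$stage, "curate")
})

test_that("the evaluate stage validates inputs before producing artifacts", {
  empty <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), empty)
  out <- file.path(withr::local_tempdir(), "run-eval")
  expect_error(run_experiment(list(stage = "evaluate",
                                   inputs = list(samples = empty),
                                   out = out, seed = 1)), "empty")
  expect_false(file.exists(file.path(out, "manifest.json")))
  expect_error(run_experiment(list(stage = "nope", out = "x")), "stage")
  expect_error(run_experiment(list(stage = "evaluate",
                                   inputs = list(samples = "/no/such.smi"),
                                   out = out)), "missing input")
})

test_that("evaluation reports render as comparison tables", {
  src <- withr::local_tempfile(fileext = ".smi")
  write_smi(c("CCO", "CCN", "CCO", "C(C"), src)
  base <- withr::local_tempdir()
  out1 <- file.path(base, "eval1")
  run_experiment(list(stage = "evaluate", inputs = list(samples = src),
                      out = out1, seed = 1,
                      stage_config = list(objective = "logp-range")))
  tab <- render_report(out1)
  expect_identical(names(tab), c("run", "pct_desirable", "pct_unique",
                                 "pct_valid", "diversity", "mean_sas"))
  expect_equal(tab$pct_valid, 75)
  expect_equal(tab$pct_unique, 100 * 2 / 3)
  # two runs side by side
  out2 <- file.path(base, "eval2")
  run_experiment(list(stage = "evaluate", inputs = list(samples = src),
                      out = out2, seed = 1,
                      stage_config = list(objective = "logp-range")))
  tab2 <- render_report(c(out1, out2))
  expect_equal(nrow(tab2), 2)
  expect_error(render_report(base), "no evaluation report")
})

test_that("the rl-train stage logs one record per iteration, reproducibly", {
  g <- toy_policy()
  ckpt <- file.path(withr::local_tempdir(), "gen")
  save_policy(g, ckpt)
  base <- withr::local_tempdir()
  cfg <- function(out) list(stage = "rl-train",
                            inputs = list(generator = ckpt), out = out,
                            seed = 3,
                            stage_config = list(objective = "logp-range",
                                                iterations = 3L,
                                                eval_every = 0L))
  m1 <- run_experiment(cfg(file.path(base, "r1")))
  lines <- readLines(file.path(base, "r1", "rl_log.jsonl"))
  expect_length(lines, 3)
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("iteration", "lambda", "mean_reward", "validity",
                    "penalty_triggers") %in% names(rec)))
  m2 <- run_experiment(cfg(file.path(base, "r2")))
  expect_identical(unname(tools::md5sum(file.path(base, "r1", "rl_log.jsonl"))),
                   unname(tools::md5sum(file.path(base, "r2", "rl_log.jsonl"))))
})
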