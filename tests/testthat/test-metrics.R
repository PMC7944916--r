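test_that("Tanimoto similarity equals the set-arithmetic definition", {
  expect_equal(tanimoto_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(tanimoto_similarity(c(1, 2), c(3, 4)), 0)
  expect_equal(tanimoto_similarity(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto_similarity(integer(0), integer(0)), 1)
  set.seed(11)
  for (k in 1:100) {
    a <- sample(0:300, sample(0:40, 1))
    b <- sample(0:300, sample(1:40, 1))
    va <- logical(301); va[a + 1] <- TRUE
    vb <- logical(301); vb[b + 1] <- TRUE
    oracle <- if (!any(va) && !any(vb)) 1 else sum(va & vb) / sum(va | vb)
    expect_equal(tanimoto_similarity(a, b), oracle)
    expect_equal(tanimoto_similarity(b, a), tanimoto_similarity(a, b))
  }
})

test_that("Levenshtein distance matches an independent DP reference", {
  expect_equal(levenshtein_distance("CCO", "CCO"), 0)
  expect_equal(levenshtein_distance("", "CCO"), 3)
  expect_equal(levenshtein_distance("CCO", ""), 3)
  set.seed(12)
  for (k in 1:100) {
    a <- random_string(); b <- random_string()
    expect_equal(levenshtein_distance(a, b), dp_levenshtein(a, b))
    expect_equal(levenshtein_distance(a, b), drop(utils::adist(a, b)))
  }
})

test_that("Levenshtein distance satisfies the metric axioms", {
  set.seed(13)
  for (k in 1:200) {
    a <- random_string(8); b <- random_string(8); cc <- random_string(8)
    dab <- levenshtein_distance(a, b)
    expect_identical(dab == 0, a == b)
    expect_equal(dab, levenshtein_distance(b, a))
    expect_lte(levenshtein_distance(a, cc), dab + levenshtein_distance(b, cc))
  }
})

test_that("pairwise Levenshtein matrices agree with the scalar version", {
  A <- c("CCO", "CCN", "c1ccccc1")
  m <- levenshtein_matrix(A)
  for (i in 1:3) for (j in 1:3)
    expect_equal(m[i, j], levenshtein_distance(A[i], A[j]))
})

# Exhaustive maximum-common-induced-subgraph oracle for small molecules:
# tries every injective element-preserving atom mapping and keeps the largest
# whose bond pattern (presence and order) is consistent.
brute_mcs_atoms <- function(sa, sb) {
  ga <- parse_smiles_graph(sa); gb <- parse_smiles_graph(sb)
  na <- nrow(ga$atoms); nb <- nrow(gb$atoms)
  bond <- function(g, n) {
    m <- matrix(0, n, n)
    if (nrow(g$bonds)) {
      m[cbind(g$bonds$from, g$bonds$to)] <- g$bonds$order
      m[cbind(g$bonds$to, g$bonds$from)] <- g$bonds$order
    }
    m
  }
  ba <- bond(ga, na); bb <- bond(gb, nb)
  laba <- paste0(ga$atoms$element, ga$atoms$aromatic)
  labb <- paste0(gb$atoms$element, gb$atoms$aromatic)
  best <- 0
  extend <- function(i, map, used, count) {
    if (count + (na - i + 1) <= best) return(invisible())   # cannot improve
    if (i > na) { best <<- max(best, count); return(invisible()) }
    for (j in seq_len(nb)) {
      if (used[j] || laba[i] != labb[j]) next
      ok <- TRUE
      for (k in seq_len(i - 1)) {
        if (map[k] > 0 && ba[k, i] != bb[map[k], j]) { ok <- FALSE; break }
      }
      if (ok) {
        map[i] <- j; used[j] <- TRUE
        extend(i + 1, map, used, count + 1)
        map[i] <- 0; used[j] <- FALSE
      }
    }
    extend(i + 1, map, used, count)   # leave atom i unmapped
  }
  extend(1, integer(na), logical(nb), 0)
  best
}

test_that("MCS similarity matches an exhaustive subgraph search on small pairs", {
  expect_equal(mcs_ratio("CCO", "CCO"), 1)
  expect_equal(mcs_ratio("C", "O"), 0)
  expect_equal(as.numeric(mcs_ratio("CCO", "CCCO")), 0.75)
  cases <- list(c("CCO", "CCCO"), c("CCN", "CCO"), c("C=CC", "CCC"),
                c("CC(C)O", "CCO"))
  for (cs in cases) {
    m <- brute_mcs_atoms(cs[1], cs[2])
    na <- nrow(parse_smiles_graph(cs[1])$atoms)
    nb <- nrow(parse_smiles_graph(cs[2])$atoms)
    expect_equal(as.numeric(mcs_ratio(cs[1], cs[2])), m / (na + nb - m),
                 label = paste(cs, collapse = " vs "))
    expect_equal(as.numeric(mcs_ratio(cs[1], cs[2])),
                 as.numeric(mcs_ratio(cs[2], cs[1])))
  }
  expect_gte(as.numeric(mcs_ratio("CCO", "CCCCN")), 0)
  expect_lte(as.numeric(mcs_ratio("CCO", "CCCCN")), 1)
})

test_that("set diversity equals the brute-force double loop", {
  A <- generate_fixture_corpus(8, seed = 3)
  B <- generate_fixture_corpus(5, seed = 4)
  # internal, Tanimoto
  fps <- morgan_fingerprints(A)
  manual <- mean(outer(seq_along(A), seq_along(A), Vectorize(function(i, j)
    1 - tanimoto_similarity(fps[[i]], fps[[j]]))))
  expect_equal(set_diversity(A), manual, tolerance = 1e-12)
  # self-pairs contribute zero but stay in the 1/n^2 normalizer
  expect_equal(set_diversity(A[1]), 0)
  expect_equal(set_diversity(A[1], A[1]), 0)
  # external, Tanimoto
  fpb <- morgan_fingerprints(B)
  manual_ext <- mean(outer(seq_along(A), seq_along(B), Vectorize(function(i, j)
    1 - tanimoto_similarity(fps[[i]], fpb[[j]]))))
  expect_equal(set_diversity(A, B), manual_ext, tolerance = 1e-12)
  # internal, Levenshtein (unnormalized mean edit distance)
  manual_lev <- mean(outer(A, A, Vectorize(levenshtein_distance)))
  expect_equal(set_diversity(A, distance = "levenshtein"), manual_lev)
  # internal, MCS on a small set
  A5 <- A[1:5]
  manual_mcs <- mean(outer(seq_along(A5), seq_along(A5), Vectorize(function(i, j)
    1 - as.numeric(mcs_ratio(A5[i], A5[j])))))
  expect_equal(set_diversity(A5, distance = "mcs"), manual_mcs, tolerance = 1e-12)
  # permutation invariance
  expect_equal(set_diversity(sample(A)), set_diversity(A), tolerance = 1e-12)
  expect_error(set_diversity(character(0)), "non-empty")
})

test_that("synthetic accessibility is bounded, ordered and deterministic", {
  s <- sas_score(c("CC", "C1CC2CCC1CC2", "CC"))
  expect_true(all(s >= 1 & s <= 10))
  expect_lt(s[1], s[2])        # ethane easier than a fused bicycle
  expect_identical(s[1], s[3])
  expect_true(is.na(sas_score("C1CC")))
})

test_that("the evaluation report is internally consistent", {
  # all-identical valid samples
  rep1 <- evaluate_generated_set(rep("CCO", 10))
  expect_equal(rep1$pct_valid, 100)
  expect_equal(rep1$pct_unique, 10)       # 100 * 1/10
  expect_equal(unname(rep1$internal_diversity["tanimoto"]), 0)
  # counts reconstructed from percentages are integers that tally
  mixed <- c(rep("CCO", 3), "C(C", "C1CC")
  rep2 <- evaluate_generated_set(mixed,
                                 desirability = function(s) rep(TRUE, length(s)))
  expect_equal(rep2$n, 5)
  expect_equal(round(rep2$pct_valid / 100 * rep2$n), 3)
  expect_equal(rep2$n_valid, 3)
  expect_equal(rep2$pct_desirable, 100)
  # all-invalid set: percentages defined, diversity absent
  rep3 <- evaluate_generated_set(c("C(C", "C1CC"))
  expect_equal(rep3$pct_valid, 0)
  expect_true(is.na(rep3$pct_unique))
  expect_true(all(is.na(rep3$internal_diversity)))
  # external diversity appears only with a reference
  rep4 <- evaluate_generated_set(c("CCO", "CCN"), reference = c("CCCC"))
  expect_false(is.null(rep4$external_diversity))
  expect_gte(rep4$external_diversity[["tanimoto"]], 0)
})
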