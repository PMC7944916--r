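# Corpus handling: fixture generation, curation, .smi and activity-CSV I/O.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible substream seed (< 2^31) from a master seed and label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

.fixture_valence <- c(C = 4, N = 3, O = 2, S = 2)

# Write one tree-structured molecule (plus at most one ring bond) as SMILES.
.write_smiles_tree <- function(elem, parent, order, ring_pair, ring_digit = "1") {
  children <- lapply(seq_along(elem), function(i) which(parent == i))
  ring_at <- if (is.null(ring_pair)) integer(0) else ring_pair
  rec <- function(i) {
    tok <- elem[i]
    if (i %in% ring_at) tok <- paste0(tok, ring_digit)
    ch <- children[[i]]
    if (length(ch) == 0L) return(tok)
    parts <- vapply(ch, function(j) {
      pre <- if (order[j] == 2) "=" else ""
      paste0(pre, rec(j))
    }, character(1))
    if (length(parts) > 1L)
      tok <- paste0(tok, paste0("(", parts[-length(parts)], ")", collapse = ""))
    paste0(tok, parts[length(parts)])
  }
  rec(1L)
}

.one_fixture_molecule <- function() {
  n <- sample(3:12, 1L)
  elem <- character(n); parent <- rep(NA_integer_, n); order <- integer(n)
  free <- numeric(n)
  elem[1] <- "C"; free[1] <- 4
  for (i in seq_len(n)[-1]) {
    e <- sample(names(.fixture_valence), 1L, prob = c(0.72, 0.12, 0.12, 0.04))
    cand <- which(free[seq_len(i - 1L)] >= 1)
    if (length(cand) == 0L) {       # all valences used up: stop growing
      n <- i - 1L
      elem <- elem[seq_len(n)]; parent <- parent[seq_len(n)]
      order <- order[seq_len(n)]; free <- free[seq_len(n)]
      break
    }
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    ord <- if (free[p] >= 2 && .fixture_valence[[e]] >= 2 && stats::runif(1) < 0.15) 2L else 1L
    elem[i] <- e; parent[i] <- p; order[i] <- ord
    free[i] <- .fixture_valence[[e]] - ord
    free[p] <- free[p] - ord
  }
  # optional single ring closing two atoms at tree distance 4-5 (5/6-rings)
  ring_pair <- NULL
  if (stats::runif(1) < 0.35) {
    depth <- integer(n); depth[1] <- 0L
    for (i in seq_len(n)[-1]) depth[i] <- depth[parent[i]] + 1L
    anc <- function(i) { path <- i; while (!is.na(parent[i])) { i <- parent[i]; path <- c(path, i) }; path }
    cands <- which(free >= 1)
    if (length(cands) >= 2L) {
      pairs <- utils::combn(cands, 2L)
      dists <- apply(pairs, 2L, function(pr) {
        pa <- anc(pr[1]); pb <- anc(pr[2])
        common <- intersect(pa, pb)[1]
        (depth[pr[1]] - depth[common]) + (depth[pr[2]] - depth[common])
      })
      ok <- which(dists %in% c(4L, 5L))
      if (length(ok)) {
        pick <- pairs[, ok[sample.int(length(ok), 1L)]]
        ring_pair <- pick
        free[pick] <- free[pick] - 1
      }
    }
  }
  # halogen decoration on a carbon with spare valence
  smi <- .write_smiles_tree(elem, parent, order, ring_pair)
  if (stats::runif(1) < 0.25) {
    hal <- sample(c("F", "Cl"), 1L)
    host <- which(elem == "C" & free >= 1 & seq_along(elem) > 1)
    host <- host[!host %in% (ring_pair %||% integer(0))]
    if (length(host)) {
      # leaves can take the halogen by simple concatenation when written last;
      # easiest safe spot is appending to a terminal atom, so rebuild with the
      # halogen as an extra child of the chosen host
      i <- if (length(host) == 1L) host else sample(host, 1L)
      elem <- c(elem, hal); parent <- c(parent, i); order <- c(order, 1L)
      smi <- .write_smiles_tree(elem, parent, order, ring_pair)
    }
  }
  smi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a deterministic fixture corpus of valid SMILES
#'
#' Builds `n` small drug-fragment-like molecules (linear chains, branches,
#' 5/6-membered rings over C/N/O/S with single and double bonds, optional
#' halogen decoration) by a valence-tracked tree construction, so every
#' string is syntactically and chemically valid by construction. Used for
#' desk-scale training and testing; it emulates the shape of a SMILES corpus,
#' not the property distribution of a screening library.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed; the same `(n, seed)` always yields the same
#'   corpus.
#' @return Character vector of `n` SMILES strings.
#' @export
generate_fixture_corpus <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  with_local_seed(seed, vapply(seq_len(n), function(i) .one_fixture_molecule(),
                               character(1)))
}

#' Heteroatom fraction of a molecule
#'
#' Fraction of heavy atoms that are not carbon, computed on the parsed
#' molecular graph. Used by the synthetic structure-activity generator.
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric vector in `[0, 1]` (`NA` for unparseable input).
#' @export
heteroatom_fraction <- function(smiles) {
  vapply(smiles, function(s) {
    g <- tryCatch(parse_smiles_graph(s), error = function(e) NULL)
    if (is.null(g)) return(NA_real_)
    mean(g$atoms$element != "C")
  }, numeric(1), USE.NAMES = FALSE)
}

#' Synthetic structure-activity table
#'
#' A fixture activity dataset with a known generating rule for
#' parameter-recovery tests of the QSAR module:
#' `pIC50 = 4 + 2 * heteroatom_fraction + N(0, noise_sd)` over molecules from
#' [generate_fixture_corpus()].
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param noise_sd Gaussian label noise standard deviation (pIC50 units).
#' @return data.frame with columns `smiles` and `pic50`.
#' @export
synthetic_activity_table <- function(n, seed = 1L, noise_sd = 0.1) {
  smi <- generate_fixture_corpus(n, seed = seed)
  hf <- heteroatom_fraction(smi)
  noise <- with_local_seed(derive_seed(seed, "labels"), stats::rnorm(n, 0, noise_sd))
  data.frame(smiles = smi, pic50 = 4 + 2 * hf + noise, stringsAsFactors = FALSE)
}

#' Curate a molecule corpus
#'
#' Canonicalizes, deduplicates and range-filters a set of molecules the way a
#' generator pre-training corpus is prepared: unreadable SMILES are dropped
#' (and counted), duplicates are collapsed on canonical form keeping the first
#' occurrence (activity labels of duplicates are collapsed to their median),
#' molecules outside the closed logP / molecular-weight windows are removed,
#' and molecules whose token payload would not fit the padded length are
#' dropped.
#'
#' @param records Character vector of SMILES, or a data.frame with a `smiles`
#'   column and optionally a `pic50` column.
#' @param logp_range,mw_range Closed inclusion windows; defaults `[-2, 6]`
#'   and `[200, 600]` g/mol.
#' @param max_payload_tokens Maximum tokenized length (default `63`, i.e.
#'   padded length 65 minus the start/end markers).
#' @return A data.frame with columns `smiles` (canonical), `logp`, `mw` and,
#'   when present in the input, `pic50`; attribute `"dropped"` records the
#'   counts removed at each step.
#' @export
curate_corpus <- function(records, logp_range = c(-2, 6), mw_range = c(200, 600),
                          max_payload_tokens = 63L) {
  df <- if (is.character(records)) data.frame(smiles = records, stringsAsFactors = FALSE)
        else as.data.frame(records)
  stopifnot("smiles" %in% names(df))
  has_act <- "pic50" %in% names(df)
  if (has_act && any(!is.finite(df$pic50)))
    stop("pic50 labels must be finite")
  props <- mol_properties(df$smiles)
  unparseable <- sum(is.na(props$canonical))
  keep <- !is.na(props$canonical)
  df <- df[keep, , drop = FALSE]; props <- props[keep, , drop = FALSE]
  df$smiles <- props$canonical; df$logp <- props$logp; df$mw <- props$mw

  dup <- duplicated(df$smiles)
  n_dup <- sum(dup)
  if (has_act && n_dup > 0) {
    med <- tapply(df$pic50, df$smiles, stats::median)
    df$pic50 <- unname(med[df$smiles])
  }
  df <- df[!dup, , drop = FALSE]

  in_range <- df$logp >= logp_range[1] & df$logp <= logp_range[2] &
              df$mw >= mw_range[1] & df$mw <= mw_range[2]
  n_range <- sum(!in_range)
  df <- df[in_range, , drop = FALSE]

  ntok <- vapply(df$smiles, function(s) length(tokenize(s)), integer(1))
  n_long <- sum(ntok > max_payload_tokens)
  if (n_long > 0)
    message(sprintf("curate_corpus: dropped %d over-length molecule(s) (> %d tokens)",
                    n_long, max_payload_tokens))
  df <- df[ntok <= max_payload_tokens, , drop = FALSE]
  rownames(df) <- NULL
  cols <- c("smiles", "logp", "mw", if (has_act) "pic50")
  out <- df[, cols, drop = FALSE]
  attr(out, "dropped") <- c(unparseable = unparseable, duplicate = n_dup,
                            out_of_range = n_range, over_length = n_long)
  out
}

#' Read and write .smi files
#'
#' One SMILES per line; an optional second whitespace-separated identifier
#' column is ignored on read.
#'
#' @param path File path.
#' @param smiles Character vector to write.
#' @return `read_smi` returns a character vector of SMILES.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vapply(strsplit(trimws(lines), "[ \t]+"), `[[`, character(1), 1L)
}

#' @rdname read_smi
#' @export
write_smi <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}

#' Read an activity table
#'
#' CSV with a header and columns `smiles,pIC50` (case-insensitive label
#' column). pIC50 is the negative decadic logarithm of IC50 in molar units.
#'
#' @param path File path.
#' @return data.frame with columns `smiles` and `pic50`.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("smiles", "pic50") %in% names(df)))
    stop("activity CSV must have columns 'smiles' and 'pIC50'")
  df[, c("smiles", "pic50")]
}
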