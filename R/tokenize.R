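#' @useDynLib divmolgen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Tokens that span more than one character: two-letter elements outside
# brackets, bracket atoms kept whole, and %NN ring closures.
.two_letter_elements <- c("Cl", "Br")

# Characters allowed as single-character tokens outside brackets.
.single_char_tokens <- c(
  "B", "C", "N", "O", "S", "P", "F", "I",      # organic-subset elements
  "b", "c", "n", "o", "s", "p",                # aromatic forms
  as.character(0:9),                           # ring-bond closures
  "(", ")", "-", "=", "#", ":", "/", "\\", "."
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into chemical tokens by a greedy left-to-right scan:
#' two-letter elements (`Cl`, `Br`) are single tokens, bracket atoms
#' `[...]` are kept intact, and `%NN` ring closures form one token.
#' Concatenating the returned tokens always reproduces the input exactly.
#'
#' @param smiles A single non-empty SMILES string.
#' @return A character vector of tokens.
#' @examples
#' tokenize("CNC(C)=O")
#' tokenize("c1ccccc1Br")
#' @export
tokenize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stop("'smiles' must be a single non-empty string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n)
        stop(sprintf("dangling '[' at position %d in \"%s\"", i, smiles))
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)])))
        stop(sprintf("dangling '%%' ring closure at position %d in \"%s\"", i, smiles))
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% .two_letter_elements) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% .single_char_tokens) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop(sprintf("untokenizable character '%s' at position %d in \"%s\"", ch, i, smiles))
    }
  }
  tokens
}

#' Build a token vocabulary from a corpus
#'
#' Collects every token observed in `corpus`, adds the start/end/pad special
#' tokens, and fixes a deterministic order: specials first (pad, start, end),
#' then the observed tokens sorted.
#'
#' @param corpus Character vector of SMILES strings (non-empty).
#' @param start_token,end_token,pad_token Special tokens; defaults `"G"`,
#'   `"E"`, and a single space.
#' @return An object of class `dmg_vocabulary` with fields `tokens`,
#'   `index_of` (named integer vector, 1-based), `start_token`, `end_token`,
#'   `pad_token` and `size`.
#' @export
build_vocabulary <- function(corpus, start_token = "G", end_token = "E",
                             pad_token = " ") {
  if (length(corpus) == 0L) stop("'corpus' must be non-empty")
  specials <- c(pad_token, start_token, end_token)
  if (anyDuplicated(specials))
    stop("start, end and pad tokens must be pairwise distinct")
  observed <- sort(unique(unlist(lapply(corpus, tokenize))))
  observed <- setdiff(observed, specials)
  tokens <- c(specials, observed)
  vocab <- structure(list(
    tokens      = tokens,
    index_of    = stats::setNames(seq_along(tokens), tokens),
    start_token = start_token,
    end_token   = end_token,
    pad_token   = pad_token,
    size        = length(tokens)
  ), class = "dmg_vocabulary")
  vocab
}

#' @export
print.dmg_vocabulary <- function(x, ...) {
  cat(sprintf("<dmg_vocabulary> %d tokens (start '%s', end '%s', pad '%s')\n",
              x$size, x$start_token, x$end_token,
              ifelse(x$pad_token == " ", "<space>", x$pad_token)))
  cat("  ", paste(setdiff(x$tokens, c(x$pad_token)), collapse = " "), "\n")
  invisible(x)
}

#' Save / load a vocabulary as JSON
#'
#' The vocabulary is persisted as a JSON object listing the ordered tokens and
#' annotating which are the start/end/pad specials, so a trained model can be
#' reloaded with the exact token indexing it was built with.
#'
#' @param vocab A `dmg_vocabulary`.
#' @param path File path.
#' @return `write_vocabulary` returns `path` invisibly; `read_vocabulary`
#'   returns a `dmg_vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "dmg_vocabulary"))
  jsonlite::write_json(list(
    tokens = vocab$tokens,
    start_token = vocab$start_token,
    end_token = vocab$end_token,
    pad_token = vocab$pad_token
  ), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tokens <- obj$tokens
  structure(list(
    tokens      = tokens,
    index_of    = stats::setNames(seq_along(tokens), tokens),
    start_token = obj$start_token,
    end_token   = obj$end_token,
    pad_token   = obj$pad_token,
    size        = length(tokens)
  ), class = "dmg_vocabulary")
}

#' Pad a token sequence and add start/end markers
#'
#' Produces `[start] tokens [end] pad ... pad` of total length exactly
#' `max_len`. Sequences whose payload exceeds `max_len - 2` are rejected.
#'
#' @param tokens Character vector of payload tokens (may be empty).
#' @param max_len Total padded length, default 65.
#' @param vocab Optional `dmg_vocabulary` supplying the special tokens;
#'   defaults to `"G"`/`"E"`/space.
#' @return Character vector of length `max_len`.
#' @export
pad_and_mark <- function(tokens, max_len = 65L, vocab = NULL) {
  start <- if (is.null(vocab)) "G" else vocab$start_token
  end   <- if (is.null(vocab)) "E" else vocab$end_token
  pad   <- if (is.null(vocab)) " " else vocab$pad_token
  if (length(tokens) + 2L > max_len)
    stop(sprintf("sequence of %d tokens exceeds capacity %d (max_len %d minus start/end)",
                 length(tokens), max_len - 2L, max_len))
  c(start, tokens, end, rep(pad, max_len - length(tokens) - 2L))
}

#' Encode padded token sequences numerically
#'
#' @param batch A list of equal-length character vectors (padded token
#'   sequences) or a single character vector.
#' @param vocab A `dmg_vocabulary`.
#' @param mode `"integer"` (batch x length matrix of 1-based vocabulary
#'   indices) or `"onehot"` (batch x length x vocabulary-size 0/1 array).
#' @return An `EncodedBatch`: the matrix or array described above, with the
#'   vocabulary attached as attribute `"vocab"` and mode as `"mode"`.
#' @export
encode_batch <- function(batch, vocab, mode = c("integer", "onehot")) {
  mode <- match.arg(mode)
  if (is.character(batch)) batch <- list(batch)
  lens <- lengths(batch)
  if (length(unique(lens)) != 1L)
    stop("all sequences in a batch must have equal (padded) length")
  all_tok <- unlist(batch, use.names = FALSE)
  idx <- vocab$index_of[all_tok]
  if (anyNA(idx)) {
    bad <- unique(all_tok[is.na(idx)])
    stop(sprintf("token(s) not in vocabulary: %s",
                 paste(sprintf("'%s'", bad), collapse = ", ")))
  }
  m <- matrix(as.integer(idx), nrow = length(batch), ncol = lens[1], byrow = TRUE)
  out <- if (mode == "integer") m else {
    a <- array(0L, dim = c(nrow(m), ncol(m), vocab$size))
    for (t in seq_len(ncol(m)))
      a[cbind(seq_len(nrow(m)), t, m[, t])] <- 1L
    a
  }
  structure(out, vocab = vocab, mode = mode, class = c("dmg_encoded", class(out)))
}

#' Decode an encoded batch back to token sequences
#'
#' Inverse of [encode_batch()] for both encoding modes.
#'
#' @param encoded An object returned by [encode_batch()], or a plain integer
#'   matrix with `vocab` supplied.
#' @param vocab A `dmg_vocabulary` (taken from the attribute if absent).
#' @return List of character token vectors.
#' @export
decode_batch <- function(encoded, vocab = attr(encoded, "vocab")) {
  if (is.null(vocab)) stop("no vocabulary attached or supplied")
  if (length(dim(encoded)) == 3L) {
    idx <- apply(encoded, c(1, 2), which.max)
  } else {
    idx <- encoded
  }
  lapply(seq_len(nrow(idx)), function(i) unname(vocab$tokens[idx[i, ]]))
}

# Strip start/end/pad from a padded token vector, returning the payload.
strip_specials <- function(tokens, vocab) {
  keep <- !(tokens %in% c(vocab$start_token, vocab$end_token, vocab$pad_token))
  tokens[keep]
}
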