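# Chemistry backend.
#
# Standard chemistry (canonical SMILES, logP, molecular weight, ECFP6
# fingerprints) is delegated to the OpenBabel command line tool, called once
# per batch. Structural validity is checked by the package's own sanitizer
# (OpenBabel accepts hypervalent atoms and silently repairs broken syntax, so
# it cannot serve as a validity oracle on its own).

.dmg_cache <- new.env(parent = emptyenv())

find_obabel <- function() {
  if (!is.null(.dmg_cache$obabel)) return(.dmg_cache$obabel)
  path <- Sys.which("obabel")
  if (!nzchar(path))
    stop("the 'obabel' executable was not found on PATH; OpenBabel is required")
  .dmg_cache$obabel <- unname(path)
  .dmg_cache$obabel
}

# Run obabel on a batch of SMILES. Returns the raw output lines. Molecules
# are titled m1..mn so results can be mapped back to inputs even when obabel
# skips unreadable entries (-e continues after errors).
ob_run <- function(smiles, out_args) {
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles, paste0("m", seq_along(smiles))), infile)
  out <- suppressWarnings(system2(find_obabel(), c(shQuote(infile), out_args, "-e"),
                                  stdout = TRUE, stderr = FALSE))
  out
}

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to OpenBabel's canonical form. Unreadable entries map
#' to `NA`.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES, aligned with the input.
#' @export
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- ob_run(smiles, "-ocan")
  res <- rep(NA_character_, n)
  parts <- strsplit(out, "[ \t]+")
  for (p in parts) {
    if (length(p) >= 2L && grepl("^m[0-9]+$", p[2])) {
      i <- as.integer(sub("^m", "", p[2]))
      res[i] <- p[1]
    }
  }
  res
}

#' Compute logP and molecular weight
#'
#' Octanol/water partition coefficient (unitless, OpenBabel's logP model) and
#' molecular weight in g/mol. Unreadable entries map to `NA`.
#'
#' @param smiles Character vector of SMILES.
#' @return A data.frame with columns `smiles`, `canonical`, `logp`, `mw`.
#' @export
mol_properties <- function(smiles) {
  n <- length(smiles)
  res <- data.frame(smiles = smiles, canonical = rep(NA_character_, n),
                    logp = rep(NA_real_, n), mw = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(res)
  out <- ob_run(smiles, c("-ocan", "--append", shQuote("logP MW")))
  parts <- strsplit(out, "[ \t]+")
  for (p in parts) {
    if (length(p) >= 4L && grepl("^m[0-9]+$", p[2])) {
      i <- as.integer(sub("^m", "", p[2]))
      res$canonical[i] <- p[1]
      res$logp[i] <- suppressWarnings(as.numeric(p[3]))
      res$mw[i] <- suppressWarnings(as.numeric(p[4]))
    }
  }
  res
}

.hex_bits <- local({
  tab <- lapply(0:15, function(v) as.integer(intToBits(v)[1:4]))
  names(tab) <- c(0:9, letters[1:6])
  tab
})

#' Morgan (extended-connectivity) fingerprints
#'
#' Radius-3 circular fingerprints folded to 4096 bits (OpenBabel's ECFP6),
#' the single fingerprint definition used throughout the package: by the QSAR
#' featurizer, the diversity metrics, and the reinforcement-learning memory
#' penalty.
#'
#' @param smiles Character vector of SMILES.
#' @param nbits Folded length (fixed at 4096 by the backend; checked).
#' @return A list, aligned with the input, of sorted 0-based on-bit index
#'   vectors; `NULL` for molecules the backend cannot read.
#' @export
morgan_fingerprints <- function(smiles, nbits = 4096L) {
  n <- length(smiles)
  if (n == 0L) return(list())
  out <- ob_run(smiles, c("-ofpt", "-xfECFP6", "-xh"))
  res <- vector("list", n)
  cur <- NA_integer_
  bits <- list()
  flush <- function() {
    if (!is.na(cur) && length(bits)) {
      stream <- unlist(bits, use.names = FALSE)
      if (length(stream) != nbits)
        stop(sprintf("fingerprint backend returned %d bits, expected %d",
                     length(stream), nbits))
      res[[cur]] <<- which(stream == 1L) - 1L
    }
  }
  for (line in out) {
    if (startsWith(line, ">")) {
      flush()
      title <- sub("^>\\s*(\\S+).*$", "\\1", line)
      cur <- if (grepl("^m[0-9]+$", title)) as.integer(sub("^m", "", title)) else NA_integer_
      bits <- list()
    } else if (!is.na(cur) && grepl("^[0-9a-f]", line)) {
      words <- strsplit(trimws(line), "\\s+")[[1]]
      chars <- strsplit(paste(words, collapse = ""), "")[[1]]
      bits[[length(bits) + 1L]] <- unlist(.hex_bits[chars], use.names = FALSE)
    }
  }
  flush()
  res
}

# Fingerprint list -> dense 0/1 matrix (rows = molecules).
fp_matrix <- function(fps, nbits = 4096L) {
  m <- matrix(0, nrow = length(fps), ncol = nbits)
  for (i in seq_along(fps)) if (length(fps[[i]])) m[i, fps[[i]] + 1L] <- 1
  m
}

# ---------------------------------------------------------------------------
# SMILES graph parser and sanitizer.

.organic_default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                              F = 1, Cl = 1, Br = 1, I = 1)
.max_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 5, S = 6,
                  F = 1, Cl = 1, Br = 1, I = 1)

#' Parse a SMILES string into a molecular graph
#'
#' A linear parse of the tokenized SMILES into atoms and bonds, tracking
#' branches, ring-bond closures, bond orders and bracket-atom annotations
#' (element, charge, explicit hydrogens). Aromatic bonds carry order 1.5.
#'
#' @param smiles A single SMILES string.
#' @return A list with `atoms` (data.frame: `element`, `aromatic`, `charge`,
#'   `hcount`, `bracket`) and `bonds` (data.frame: `from`, `to`, `order`).
#'   Errors describe the offending token and position.
#' @export
parse_smiles_graph <- function(smiles) {
  tokens <- tokenize(smiles)
  elem <- character(0); arom <- logical(0); chg <- integer(0)
  hx <- integer(0); brk <- logical(0)
  b_from <- integer(0); b_to <- integer(0); b_ord <- numeric(0)
  prev <- NA_integer_
  stack <- integer(0)
  ring <- list()        # key -> list(atom, order)
  pending <- NA_real_   # explicit bond order awaiting the next atom/closure
  bond_orders <- c("-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "/" = 1, "\\" = 1)

  add_atom <- function(e, aromatic, charge = 0L, h = NA_integer_, bracket = FALSE) {
    elem <<- c(elem, e); arom <<- c(arom, aromatic); chg <<- c(chg, charge)
    hx <<- c(hx, h); brk <<- c(brk, bracket)
    id <- length(elem)
    if (!is.na(prev)) {
      ord <- if (!is.na(pending)) pending
             else if (arom[prev] && aromatic) 1.5 else 1
      b_from <<- c(b_from, prev); b_to <<- c(b_to, id); b_ord <<- c(b_ord, ord)
    }
    prev <<- id
    pending <<- NA_real_
  }

  for (k in seq_along(tokens)) {
    tok <- tokens[k]
    if (tok %in% c("B", "C", "N", "O", "S", "P", "F", "I", "Cl", "Br")) {
      add_atom(tok, FALSE)
    } else if (tok %in% c("b", "c", "n", "o", "s", "p")) {
      add_atom(toupper(tok), TRUE)
    } else if (startsWith(tok, "[")) {
      m <- regmatches(tok, regexec(
        "^\\[([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H([0-9]*))?(([+-])([0-9]*)|(\\+{2,})|(-{2,}))?\\]$", tok))[[1]]
      if (length(m) == 0L)
        stop(sprintf("unparseable bracket atom '%s' (token %d)", tok, k))
      e <- m[3]
      aromatic <- e %in% c("b", "c", "n", "o", "s", "p", "se", "as")
      h <- if (nzchar(m[5])) { if (nzchar(m[6])) as.integer(m[6]) else 1L } else 0L
      charge <- 0L
      if (nzchar(m[8])) {
        mag <- if (nzchar(m[9])) as.integer(m[9]) else 1L
        charge <- if (m[8] == "+") mag else -mag
      } else if (nzchar(m[10])) charge <- nchar(m[10])
      else if (nzchar(m[11])) charge <- -nchar(m[11])
      add_atom(if (aromatic) toupper(e) else e, aromatic, charge, h, TRUE)
    } else if (tok %in% names(bond_orders)) {
      if (is.na(prev)) stop(sprintf("bond '%s' with no preceding atom (token %d)", tok, k))
      if (!is.na(pending)) stop(sprintf("two consecutive bond symbols (token %d)", k))
      pending <- bond_orders[[tok]]
    } else if (tok == "(") {
      if (is.na(prev)) stop(sprintf("branch opened before any atom (token %d)", k))
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) stop(sprintf("unmatched ')' (token %d)", k))
      if (!is.na(pending)) stop(sprintf("dangling bond before ')' (token %d)", k))
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (grepl("^[0-9]$", tok) || startsWith(tok, "%")) {
      if (is.na(prev)) stop(sprintf("ring closure before any atom (token %d)", k))
      key <- sub("^%", "", tok)
      if (!is.null(ring[[key]])) {
        op <- ring[[key]]
        if (op$atom == prev) stop(sprintf("ring bond to the same atom (token %d)", k))
        ord <- if (!is.na(pending)) pending
               else if (!is.na(op$order)) op$order
               else if (arom[op$atom] && arom[prev]) 1.5 else 1
        b_from <- c(b_from, op$atom); b_to <- c(b_to, prev); b_ord <- c(b_ord, ord)
        ring[[key]] <- NULL
        pending <- NA_real_
      } else {
        ring[[key]] <- list(atom = prev, order = pending)
        pending <- NA_real_
      }
    } else if (tok == ".") {
      if (!is.na(pending)) stop(sprintf("bond before '.' separator (token %d)", k))
      prev <- NA_integer_
    } else {
      stop(sprintf("unsupported token '%s' (token %d)", tok, k))
    }
  }
  if (length(stack)) stop("unclosed '(' branch")
  if (length(ring)) stop(sprintf("unmatched ring bond(s): %s",
                                 paste(names(ring), collapse = ", ")))
  if (!is.na(pending)) stop("dangling bond at end of SMILES")
  if (length(elem) == 0L) stop("no atoms parsed")
  list(atoms = data.frame(element = elem, aromatic = arom, charge = chg,
                          hcount = hx, bracket = brk, stringsAsFactors = FALSE),
       bonds = data.frame(from = b_from, to = b_to, order = b_ord))
}

# Per-atom valence and aromaticity sanity on a parsed graph.
graph_valence_ok <- function(g) {
  na <- nrow(g$atoms)
  bsum <- numeric(na); narom <- integer(na)
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      f <- g$bonds$from[i]; t <- g$bonds$to[i]; o <- g$bonds$order[i]
      bsum[f] <- bsum[f] + o; bsum[t] <- bsum[t] + o
      if (o == 1.5) { narom[f] <- narom[f] + 1L; narom[t] <- narom[t] + 1L }
    }
  }
  for (i in seq_len(na)) {
    e <- g$atoms$element[i]
    if (g$atoms$aromatic[i] && narom[i] < 2L) return(FALSE)
    maxv <- .max_valence[[e]]
    if (is.null(maxv) || is.na(maxv)) next   # uncommon element: skip the check
    allowed <- maxv + max(g$atoms$charge[i], 0L)
    used <- ceiling(bsum[i]) + ifelse(is.na(g$atoms$hcount[i]), 0L, g$atoms$hcount[i])
    if (used > allowed) return(FALSE)
  }
  TRUE
}

#' Check chemical validity of SMILES strings
#'
#' A molecule is valid when (i) it tokenizes and parses into a connected-ring
#' consistent graph (balanced branches, matched ring bonds, no dangling
#' bonds), (ii) every atom respects its maximum valence (aromatic bonds
#' counted as 1.5, charges widening the allowance), with aromatic atoms
#' required to sit on at least two aromatic bonds, and (iii) OpenBabel can
#' read it. This mirrors the role of a structure sanitizer in the evaluation
#' of generated molecules.
#'
#' @param smiles Character vector of SMILES.
#' @return Logical vector, aligned with the input.
#' @export
smiles_valid <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(logical(0))
  ok <- vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    g <- tryCatch(parse_smiles_graph(s), error = function(e) NULL)
    !is.null(g) && graph_valence_ok(g)
  }, logical(1), USE.NAMES = FALSE)
  if (any(ok)) {
    can <- canonical_smiles(smiles[ok])
    ok[ok] <- !is.na(can)
  }
  ok
}
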