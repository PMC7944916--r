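# Molecular diversity metrics: Tanimoto similarity over Morgan fingerprints,
# Levenshtein distance on raw SMILES strings, maximum-common-substructure
# similarity, and their internal/external set aggregation.

#' Tanimoto similarity of two fingerprints
#'
#' `|a n b| / |a u b|` over the on-bit index sets of two Morgan fingerprints.
#' Two empty fingerprints are defined as identical (similarity 1).
#'
#' @param a,b Integer vectors of on-bit indices (as returned by
#'   [morgan_fingerprints()]).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

# All-pairs Tanimoto similarity between two fingerprint lists (dense algebra).
tanimoto_cross <- function(fps_a, fps_b) {
  ma <- fp_matrix(fps_a); mb <- fp_matrix(fps_b)
  inter <- tcrossprod(ma, mb)
  na <- rowSums(ma); nb <- rowSums(mb)
  uni <- outer(na, nb, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1e-12))
  sim
}

#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and substitutions
#' transforming one SMILES string into the other, computed on the raw
#' character strings by the standard dynamic-programming recurrence.
#'
#' @param a,b Strings.
#' @return Non-negative integer distance.
#' @export
levenshtein_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  .lev_pair(a, b)
}

#' All-pairs Levenshtein distances
#'
#' @param A,B Character vectors.
#' @return `length(A)` x `length(B)` integer matrix.
#' @export
levenshtein_matrix <- function(A, B = A) .lev_matrix(A, B)

# ---------------------------------------------------------------------------
# Maximum common substructure.

# Build the modular (compatibility) graph of two molecular graphs: vertices
# are element-compatible atom pairs (i, j); two pairs are adjacent when they
# are consistent (both bonded with equal order, or both non-bonded). A
# maximum clique is a maximum common induced subgraph.
.mcs_atoms <- function(ga, gb, timeout) {
  na <- nrow(ga$atoms); nb <- nrow(gb$atoms)
  lab_a <- paste0(ga$atoms$element, ifelse(ga$atoms$aromatic, "~", ""))
  lab_b <- paste0(gb$atoms$element, ifelse(gb$atoms$aromatic, "~", ""))
  bond_a <- matrix(0, na, na); bond_b <- matrix(0, nb, nb)
  if (nrow(ga$bonds)) {
    bond_a[cbind(ga$bonds$from, ga$bonds$to)] <- ga$bonds$order
    bond_a[cbind(ga$bonds$to, ga$bonds$from)] <- ga$bonds$order
  }
  if (nrow(gb$bonds)) {
    bond_b[cbind(gb$bonds$from, gb$bonds$to)] <- gb$bonds$order
    bond_b[cbind(gb$bonds$to, gb$bonds$from)] <- gb$bonds$order
  }
  pairs <- which(outer(lab_a, lab_b, "=="), arr.ind = TRUE)
  np <- nrow(pairs)
  if (np == 0L) return(list(size = 0L, exact = TRUE))
  # adjacency of the modular graph
  ia <- pairs[, 1]; jb <- pairs[, 2]
  same_i <- outer(ia, ia, "==") | outer(jb, jb, "==")
  ord_i <- bond_a[cbind(rep(ia, np), rep(ia, each = np))]
  ord_j <- bond_b[cbind(rep(jb, np), rep(jb, each = np))]
  compat <- matrix(ord_i == ord_j, np, np) & !same_i
  diag(compat) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(compat, mode = "undirected")
  res <- tryCatch({
    setTimeLimit(elapsed = timeout, transient = TRUE)
    on.exit(setTimeLimit(elapsed = Inf, transient = TRUE), add = TRUE)
    list(size = igraph::clique_num(g), exact = TRUE)
  }, error = function(e) {
    # timeout: greedy lower bound on the clique size
    setTimeLimit(elapsed = Inf, transient = TRUE)
    deg <- igraph::degree(g)
    ordv <- order(deg, decreasing = TRUE)
    cl <- integer(0)
    for (v in ordv) if (all(compat[v, cl])) cl <- c(cl, v)
    list(size = length(cl), exact = FALSE)
  })
  res
}

#' Maximum-common-substructure similarity
#'
#' The ratio `mcs / (atoms(a) + atoms(b) - mcs)`, where `mcs` is the heavy-atom
#' count of the maximum common (induced) substructure of the two molecules,
#' found by a maximum-clique search on the modular product of the two
#' molecular graphs with element and bond-order matching.
#'
#' @param a,b SMILES strings of valid molecules.
#' @param timeout Seconds allowed for the exact clique search; on timeout a
#'   greedy lower bound is returned, flagged via attribute `"approximate"`.
#' @return Similarity in `[0, 1]`; 1 iff the molecular graphs are identical.
#' @export
mcs_ratio <- function(a, b, timeout = 10) {
  ga <- parse_smiles_graph(a); gb <- parse_smiles_graph(b)
  res <- .mcs_atoms(ga, gb, timeout)
  val <- res$size / (nrow(ga$atoms) + nrow(gb$atoms) - res$size)
  if (!res$exact) attr(val, "approximate") <- TRUE
  val
}

#' Average pairwise diversity of molecule sets
#'
#' The mean pairwise distance between two sets of molecules,
#' `sum(distance(a, b)) / (|A| |B|)`. With `B` omitted the internal diversity
#' of `A` is computed: `B = A` including self-pairs, i.e. the `1/n^2`
#' normalization (self-pairs contribute 0 for the two normalized distances).
#' Distances: `1 - Tanimoto` over Morgan fingerprints, raw Levenshtein edit
#' distance (unnormalized mean), or `1 - MCS` similarity.
#'
#' @param A Character vector of SMILES (non-empty).
#' @param B Optional second set; omit for internal diversity.
#' @param distance One of `"tanimoto"`, `"levenshtein"`, `"mcs"`.
#' @param mcs_timeout Per-pair timeout for the MCS search.
#' @return A single non-negative number (in `[0, 1]` except for Levenshtein).
#' @export
set_diversity <- function(A, B = NULL,
                          distance = c("tanimoto", "levenshtein", "mcs"),
                          mcs_timeout = 10) {
  distance <- match.arg(distance)
  if (length(A) == 0L || (!is.null(B) && length(B) == 0L))
    stop("molecule sets must be non-empty")
  internal <- is.null(B)
  if (internal) B <- A
  if (distance == "tanimoto") {
    sim <- tanimoto_cross(morgan_fingerprints(A), morgan_fingerprints(B))
    mean(1 - sim)
  } else if (distance == "levenshtein") {
    mean(levenshtein_matrix(A, B))
  } else {
    d <- matrix(0, length(A), length(B))
    for (i in seq_along(A)) for (j in seq_along(B)) {
      if (internal && j < i) { d[i, j] <- d[j, i]; next }
      d[i, j] <- 1 - as.numeric(mcs_ratio(A[i], B[j], timeout = mcs_timeout))
    }
    mean(d)
  }
}

# ---------------------------------------------------------------------------
# Synthetic accessibility.

#' Calibrate the synthetic-accessibility fragment scores
#'
#' The synthetic-accessibility score combines a fragment-familiarity term with
#' structural complexity penalties. Familiarity is estimated from the
#' frequency of Morgan-fingerprint fragments in a reference corpus: fragments
#' common in the corpus are considered easy to make. This calibration replaces
#' the large published fragment-frequency table with one estimated from a
#' corpus the user supplies (by default the package's synthetic fixture
#' corpus), which preserves the ordering behaviour of the score at desk scale.
#'
#' @param corpus Character vector of valid SMILES.
#' @return An object of class `dmg_sas_calibration`.
#' @export
sas_calibration <- function(corpus) {
  fps <- morgan_fingerprints(corpus)
  fps <- fps[!vapply(fps, is.null, logical(1))]
  counts <- numeric(4096)
  for (fp in fps) counts[fp + 1L] <- counts[fp + 1L] + 1
  structure(list(counts = counts, n = length(fps)), class = "dmg_sas_calibration")
}

default_sas_calibration <- function() {
  if (is.null(.dmg_cache$sas_cal))
    .dmg_cache$sas_cal <- sas_calibration(generate_fixture_corpus(2000, seed = 20210501))
  .dmg_cache$sas_cal
}

#' Synthetic accessibility score
#'
#' A fragment-contribution synthetic-accessibility estimate on a 1 (easy) to
#' 10 (hard) scale: the mean rarity of the molecule's circular fragments in a
#' reference corpus, plus size and ring-complexity penalties, affinely mapped
#' and clamped to `[1, 10]`. Molecules scoring above 6 are conventionally
#' regarded as hard to synthesize.
#'
#' @param smiles Character vector of valid SMILES.
#' @param calibration A `dmg_sas_calibration`; defaults to one built from the
#'   package's deterministic fixture corpus.
#' @return Numeric vector of scores in `[1, 10]` (`NA` for unreadable input).
#' @export
sas_score <- function(smiles, calibration = default_sas_calibration()) {
  stopifnot(inherits(calibration, "dmg_sas_calibration"))
  fps <- morgan_fingerprints(smiles)
  out <- rep(NA_real_, length(smiles))
  for (i in seq_along(smiles)) {
    fp <- fps[[i]]
    if (is.null(fp)) next
    g <- tryCatch(parse_smiles_graph(smiles[i]), error = function(e) NULL)
    if (is.null(g)) next
    rarity <- mean(-log10((calibration$counts[fp + 1L] + 1) / (calibration$n + 1)))
    natoms <- nrow(g$atoms)
    nbonds <- nrow(g$bonds)
    parent <- seq_len(natoms)                    # union-find for components
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (nbonds) for (k in seq_len(nbonds)) {
      ra <- find(g$bonds$from[k]); rb <- find(g$bonds$to[k])
      if (ra != rb) parent[ra] <- rb
    }
    ncomp <- length(unique(vapply(seq_len(natoms), find, integer(1))))
    nrings <- max(0L, nbonds - natoms + ncomp)
    size_pen <- natoms^1.005 - natoms
    ring_pen <- 0.6 * log2(1 + nrings) + if (nrings >= 2) 0.5 else 0
    deg <- tabulate(c(g$bonds$from, g$bonds$to), nbins = natoms)
    branch_pen <- 0.3 * sum(deg >= 4)
    raw <- 1.3 * rarity + size_pen + ring_pen + branch_pen
    out[i] <- min(10, max(1, 1 + 9 * (raw - 1) / 7))
  }
  out
}
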