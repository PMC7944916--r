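# Aggregate evaluation of generated molecule sets.

#' Evaluate a set of generated molecules
#'
#' Computes the standard generation report: percentage of chemically valid
#' molecules (per [smiles_valid()]), percentage of unique canonical forms
#' among the valid ones, percentage of desirable molecules under the supplied
#' rule, mean synthetic-accessibility score, and internal (and, given a
#' reference set, external) diversity under the requested distance
#' definitions. Diversities are computed over valid molecules only; when no
#' molecule is valid the diversity and uniqueness fields are `NA`.
#'
#' @param samples Character vector of SMILES, or a list of sample records
#'   from [sample_batch()] / [dual_sample()].
#' @param reference Optional character vector of reference SMILES (e.g. the
#'   training corpus) for external diversity; assumed valid.
#' @param desirability Optional function `character -> logical` (see
#'   [reward_spec()] and [desirability_rule()]); e.g. predicted pIC50 at
#'   least 6.5, or logP within `[1, 4]`.
#' @param distances Distance definitions to report (any of `"tanimoto"`,
#'   `"levenshtein"`, `"mcs"`). The MCS search being the expensive one, MCS
#'   diversity is computed on at most `mcs_max_n` molecules (the first that
#'   many valid ones).
#' @param mcs_max_n Cap for the MCS diversity subset.
#' @param sas Compute the mean synthetic-accessibility score.
#' @return A `dmg_evaluation_report` list: `n`, `n_valid`, `pct_valid`,
#'   `pct_unique`, `pct_desirable`, `mean_sas`, `internal_diversity`,
#'   `external_diversity`.
#' @export
evaluate_generated_set <- function(samples, reference = NULL,
                                   desirability = NULL,
                                   distances = c("tanimoto", "levenshtein"),
                                   mcs_max_n = 30L, sas = TRUE) {
  if (is.list(samples) && !is.null(samples[[1]]$smiles))
    samples <- vapply(samples, `[[`, character(1), "smiles")
  if (length(samples) == 0L) stop("'samples' must be non-empty")
  distances <- match.arg(distances, c("tanimoto", "levenshtein", "mcs"),
                         several.ok = TRUE)
  n <- length(samples)
  valid <- smiles_valid(samples)
  vs <- samples[valid]
  rep_out <- list(n = n, n_valid = sum(valid), pct_valid = 100 * mean(valid),
                  pct_unique = NA_real_, pct_desirable = NA_real_,
                  mean_sas = NA_real_,
                  internal_diversity = stats::setNames(
                    rep(NA_real_, length(distances)), distances),
                  external_diversity = NULL)
  if (length(vs) > 0) {
    can <- canonical_smiles(vs)
    rep_out$pct_unique <- 100 * length(unique(can)) / length(vs)
    if (!is.null(desirability))
      rep_out$pct_desirable <- 100 * mean(desirability(vs))
    if (sas) rep_out$mean_sas <- mean(sas_score(vs), na.rm = TRUE)
    for (d in distances) {
      set <- if (d == "mcs") utils::head(vs, mcs_max_n) else vs
      rep_out$internal_diversity[[d]] <-
        if (length(set) >= 1) set_diversity(set, distance = d) else NA_real_
    }
    if (!is.null(reference)) {
      rep_out$external_diversity <- stats::setNames(
        rep(NA_real_, length(distances)), distances)
      for (d in distances) {
        set <- if (d == "mcs") utils::head(vs, mcs_max_n) else vs
        refd <- if (d == "mcs") utils::head(reference, mcs_max_n) else reference
        rep_out$external_diversity[[d]] <- set_diversity(set, refd, distance = d)
      }
    }
  }
  structure(rep_out, class = "dmg_evaluation_report")
}

#' @export
print.dmg_evaluation_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "-", formatC(v, digits = 3, format = "fg"))
  cat(sprintf("<dmg_evaluation_report> n = %d\n", x$n))
  cat(sprintf("  %% valid      %s\n", fmt(x$pct_valid)))
  cat(sprintf("  %% unique     %s\n", fmt(x$pct_unique)))
  cat(sprintf("  %% desirable  %s\n", fmt(x$pct_desirable)))
  cat(sprintf("  mean SAS     %s\n", fmt(x$mean_sas)))
  for (d in names(x$internal_diversity))
    cat(sprintf("  internal diversity (%s)  %s\n", d,
                fmt(x$internal_diversity[[d]])))
  for (d in names(x$external_diversity))
    cat(sprintf("  external diversity (%s)  %s\n", d,
                fmt(x$external_diversity[[d]])))
  invisible(x)
}
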