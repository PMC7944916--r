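# Property-to-reward conversion and property oracles.

#' Reward specification
#'
#' Maps a molecular property value to the scalar reward driving the policy
#' gradient. Three modes:
#' \describe{
#'   \item{maximize_pic50}{`exp(pIC50 / 4 - 1)`: 1 at pIC50 4, e at 8,
#'     strictly increasing.}
#'   \item{minimize_pic50}{`exp((k0 - pIC50) / 4)` with `k0 = 2`, so low
#'     affinity maps to a high reward on a scale comparable to the
#'     maximization rule.}
#'   \item{logp_range}{flat maximal reward (3) while logP lies inside
#'     `logp_bounds`, decaying as `3 exp(-d)` with the distance `d` to the
#'     nearest bound outside.}
#' }
#' Chemically invalid molecules receive `invalid_reward` (default 0).
#'
#' @param mode One of `"maximize_pic50"`, `"minimize_pic50"`, `"logp_range"`.
#' @param property_oracle Function mapping a character vector of SMILES to
#'   property values (predicted pIC50 or computed logP); `NA` marks failures.
#' @param logp_bounds Closed desirability window for `logp_range`.
#' @param invalid_reward Reward for invalid molecules (>= 0).
#' @param k0 Offset of the minimization rule.
#' @return A `dmg_reward_spec`.
#' @export
reward_spec <- function(mode = c("maximize_pic50", "minimize_pic50", "logp_range"),
                        property_oracle = NULL, logp_bounds = c(1, 4),
                        invalid_reward = 0, k0 = 2) {
  mode <- match.arg(mode)
  stopifnot(invalid_reward >= 0)
  if (is.null(property_oracle))
    property_oracle <- if (mode == "logp_range") logp_oracle() else
      stop("a property oracle is required for the pIC50 modes")
  structure(list(mode = mode, property_oracle = property_oracle,
                 logp_bounds = logp_bounds, invalid_reward = invalid_reward,
                 k0 = k0), class = "dmg_reward_spec")
}

#' Convert a property value to a reward
#'
#' @param property_value Finite numeric vector of property values.
#' @param spec A [reward_spec()].
#' @return Positive numeric rewards of the same length.
#' @export
compute_reward <- function(property_value, spec) {
  stopifnot(inherits(spec, "dmg_reward_spec"))
  switch(spec$mode,
    maximize_pic50 = exp(property_value / 4 - 1),
    minimize_pic50 = exp((spec$k0 - property_value) / 4),
    logp_range = {
      lo <- spec$logp_bounds[1]; hi <- spec$logp_bounds[2]
      d <- pmax(0, pmax(lo - property_value, property_value - hi))
      3 * exp(-d)
    })
}

#' Property oracles
#'
#' `logp_oracle()` returns a function computing logP for a batch of SMILES;
#' `predictor_oracle(fit)` wraps a trained QSAR ensemble, mapping prediction
#' failures (e.g. tokens outside the model's vocabulary) to `NA` so the
#' reinforcement-learning loop can route them to the invalid-molecule reward.
#'
#' @param fit A `dmg_qsar` from [train_qsar()].
#' @return A function `character -> numeric`.
#' @export
logp_oracle <- function() {
  function(smiles) mol_properties(smiles)$logp
}

#' @rdname logp_oracle
#' @export
predictor_oracle <- function(fit) {
  stopifnot(inherits(fit, "dmg_qsar"))
  function(smiles) {
    vapply(smiles, function(s)
      tryCatch(predict_activity(fit, s), error = function(e) NA_real_),
      numeric(1), USE.NAMES = FALSE)
  }
}

#' Desirability rule implied by a reward specification
#'
#' Returns the predicate used for the "% desirable" metric: property value
#' at least 6.5 (predicted pIC50) for the maximization objective, at most
#' 6.5 for minimization, or logP inside the objective's bounds for the
#' logP-window objective. Oracle failures count as not desirable.
#'
#' @param spec A [reward_spec()].
#' @return A function `character -> logical`.
#' @export
desirability_rule <- function(spec) {
  force(spec)
  function(smiles) {
    v <- spec$property_oracle(smiles)
    switch(spec$mode,
      maximize_pic50 = !is.na(v) & v >= 6.5,
      minimize_pic50 = !is.na(v) & v <= 6.5,
      logp_range = !is.na(v) & v >= spec$logp_bounds[1] & v <= spec$logp_bounds[2])
  }
}
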