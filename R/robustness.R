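#' Robustness to combinatorial production-rate noise
#'
#' A consistent circuit is scored by re-solving the model for every
#' combination of adding or subtracting a fixed fraction (default 20%) to
#' each of the production-rate parameters (4 regulated + 2 basal = 6, so
#' 2^6 = 64 noise combinations) and asking whether all identity-merged phase
#' durations stay within 10% of the unperturbed durations. The score is the
#' percentage of such "close" combinations. Degradation rates are left
#' untouched: they set the time scale of the dynamics.
#'
#' @name robustness
NULL

production_param_names <- function(topology = build_default_topology()) {
  nm <- param_names(topology)
  nm[grepl("^beta", nm)]
}

#' Enumerate noise combinations
#'
#' All sign patterns of multiplying each production parameter by `1 - eps` or
#' `1 + eps`, in lexicographic order (last parameter varies fastest),
#' deterministic.
#'
#' @param p Number of production parameters (default 6).
#' @param eps Noise amplitude (default 0.2 for +/-20%).
#' @return `2^p x p` numeric matrix of multipliers.
#' @export
noise_combinations <- function(p = 6, eps = 0.2) {
  stopifnot(p >= 1, eps > 0, eps < 1)
  g <- do.call(expand.grid, rep(list(c(1 - eps, 1 + eps)), p))
  # expand.grid cycles the first factor fastest; reversing the columns yields
  # plain lexicographic row order (last parameter varies fastest)
  m <- as.matrix(g[, rev(seq_len(p)), drop = FALSE])
  dimnames(m) <- NULL
  m
}

# Durations of TTF expression phases only: intervals where no TTF is on
# (identity "none", e.g. before Hb rises) are not expression phases and do
# not enter the duration comparison.
phase_durations <- function(merged) {
  keep <- merged$identity != "none"
  data.frame(identity = merged$identity[keep],
             duration = (merged$end - merged$start)[keep],
             stringsAsFactors = FALSE)
}

#' Are perturbed phases "close" to the originals?
#'
#' Close iff the identity-merged phase sequences have the same identity order
#' and every corresponding duration is within `tol` relative distance of the
#' original. Any order mismatch (including an extra or missing phase) is not
#' close. The final, open-ended phase's duration is measured to the horizon.
#'
#' @param perturbed,original Identity-merged `ttf_phases`
#'   (see [merge_identity_phases()]).
#' @param tol Relative tolerance, default 0.10.
#' @return Logical flag.
#' @export
is_close <- function(perturbed, original, tol = 0.10) {
  a <- phase_durations(perturbed)
  b <- phase_durations(original)
  if (nrow(a) != nrow(b) || any(a$identity != b$identity)) return(FALSE)
  all(abs(a$duration - b$duration) <= tol * b$duration)
}

#' Robustness score of a circuit
#'
#' @param params A consistent `ttf_params`.
#' @param topology A `ttf_topology`.
#' @param constants Structural constants.
#' @param identity_map On-set -> identity map for phase merging.
#' @param eps Noise amplitude (default 0.2).
#' @param tol Duration tolerance (default 0.10).
#' @return Percentage in `[0, 100]` of close noise combinations. A solver
#'   failure in a combination counts it as not close.
#' @export
robustness_score <- function(params, topology = build_default_topology(),
                             constants = model_constants(),
                             identity_map = default_identity_map(),
                             eps = 0.2, tol = 0.10) {
  thresholds <- on_thresholds(params, topology, constants)
  base <- simulate_circuit(params, topology, pert_none(), constants)
  base_m <- merge_identity_phases(
    trajectory_to_phases(base, thresholds, constants$min_phase), identity_map)
  pp <- production_param_names(topology)
  combos <- noise_combinations(length(pp), eps)
  close <- logical(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    pk <- unclass(params)
    pk[pp] <- pk[pp] * combos[k, ]
    ok <- try({
      traj <- simulate_circuit(as_ttf_params(pk, topology), topology,
                               pert_none(), constants)
      m <- merge_identity_phases(
        trajectory_to_phases(traj, thresholds, constants$min_phase),
        identity_map)
      close[k] <- is_close(m, base_m, tol)
    }, silent = TRUE)
    if (inherits(ok, "try-error")) close[k] <- FALSE
  }
  100 * mean(close)
}

#' Score many records
#'
#' Adds a `robustness_score` column to consistent screen records
#' (non-consistent records get NA).
#'
#' @param records Screen records data frame.
#' @inheritParams robustness_score
#' @param verbose Log progress.
#' @return `records` with a `robustness_score` column.
#' @export
score_records <- function(records, topology = build_default_topology(),
                          constants = model_constants(),
                          identity_map = default_identity_map(),
                          eps = 0.2, tol = 0.10, verbose = FALSE) {
  records$robustness_score <- NA_real_
  idx <- which(records$consistent == 1 & records$failed == 0)
  for (j in seq_along(idx)) {
    i <- idx[j]
    records$robustness_score[i] <- robustness_score(
      record_params(records, i, topology), topology, constants, identity_map,
      eps, tol)
    if (verbose && j %% 50 == 0)
      message(sprintf("robustness: %d/%d scored", j, length(idx)))
  }
  records
}
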