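#' One-step timers: activator accumulation vs repressor decay
#'
#' The elementary timer measures the delay from the onset of the dynamics
#' until a regulator crosses a readout threshold `Tr`. An accumulation timer
#' starts production of an activator at t = 0 (`X(t) = beta/k (1 - e^{-kt})`);
#' a decay timer stops production of a repressor at t = 0 (`X(t) = P0
#' e^{-kt}`). Closed forms:
#' accumulation `t = -(1/k) log(1 - Tr k / beta)` (finite only for
#' `Tr < beta/k`); decay `t = (1/k) log(P0 / Tr)`.
#'
#' @name single_step
NULL

#' Sentinel: an accumulation timer whose threshold is unreachable
#' @export
NEVER <- "NEVER"

#' Construct a one-step timer
#'
#' @param kind `"accumulation"` or `"decay"`.
#' @param beta Production rate (conc/min), accumulation only.
#' @param p0 Initial repressor level (conc), decay only.
#' @param k Degradation rate (1/min).
#' @param tr Readout threshold (conc).
#' @return A `one_step_timer`.
#' @export
one_step_timer <- function(kind = c("accumulation", "decay"),
                           beta = NULL, p0 = NULL, k, tr) {
  kind <- match.arg(kind)
  stopifnot(k > 0, tr > 0)
  if (kind == "accumulation") {
    if (is.null(beta) || beta <= 0) stop("accumulation timer needs beta > 0")
    p0 <- NULL
  } else {
    if (is.null(p0) || p0 <= 0) stop("decay timer needs p0 > 0")
    beta <- NULL
  }
  structure(list(kind = kind, beta = beta, p0 = p0, k = k, tr = tr),
            class = "one_step_timer")
}

#' Delay of a one-step timer
#'
#' @param timer A `one_step_timer`.
#' @return Delay in minutes, or [NEVER] for an accumulation timer with
#'   `tr >= beta/k` (the threshold exceeds the steady state).
#' @export
timer_delay <- function(timer) {
  stopifnot(inherits(timer, "one_step_timer"))
  if (timer$kind == "accumulation") {
    ss <- timer$beta / timer$k
    if (timer$tr >= ss) return(NEVER)
    -log(1 - timer$tr / ss) / timer$k
  } else {
    if (timer$tr > timer$p0) return(0)   # already below threshold
    log(timer$p0 / timer$tr) / timer$k
  }
}

#' Delay shift under a fold-change in production
#'
#' Difference (min) between the delay after multiplying production by `fold`
#' and the reference delay. For a decay timer the production change rescales
#' the initial level `P0`, so the shift is `-log(fold)/k` exactly,
#' independent of the threshold: the decay timer is only logarithmically
#' sensitive to production. The accumulation timer's shift grows without
#' bound as `Tr` approaches the perturbed steady state.
#'
#' @param timer A `one_step_timer`.
#' @param fold Production fold-change (> 0), e.g. 0.5 for two-fold reduction.
#' @return Shift in minutes, or [NEVER] if the perturbed accumulation timer
#'   never reaches threshold.
#' @export
delay_shift_under_production_change <- function(timer, fold) {
  stopifnot(fold > 0)
  t0 <- timer_delay(timer)
  if (identical(t0, NEVER)) return(NEVER)
  pert <- timer
  if (timer$kind == "accumulation") pert$beta <- timer$beta * fold
  else pert$p0 <- timer$p0 * fold
  t1 <- timer_delay(pert)
  if (identical(t1, NEVER)) return(NEVER)
  t1 - t0
}

#' Fig-style sensitivity curve over a threshold grid
#'
#' For each threshold in `tr_grid`, the delay shift under `fold`-change in
#' production, for both timer kinds at equal degradation rate.
#'
#' @param k Degradation rate (1/min).
#' @param beta Accumulation production rate (conc/min).
#' @param p0 Decay initial level (conc).
#' @param tr_grid Threshold grid (conc).
#' @param fold Production fold change.
#' @return Data frame: `tr`, `shift_accumulation` (NA where NEVER),
#'   `shift_decay`.
#' @export
one_step_sensitivity_curve <- function(k, beta = k, p0 = 1,
                                       tr_grid = seq(0.01, 0.99, length.out = 99),
                                       fold = 0.5) {
  acc <- vapply(tr_grid, function(tr) {
    s <- delay_shift_under_production_change(
      one_step_timer("accumulation", beta = beta, k = k, tr = tr), fold)
    if (identical(s, NEVER)) NA_real_ else s
  }, numeric(1))
  dec <- vapply(tr_grid, function(tr) {
    s <- delay_shift_under_production_change(
      one_step_timer("decay", p0 = p0, k = k, tr = tr), fold)
    if (identical(s, NEVER)) NA_real_ else s
  }, numeric(1))
  data.frame(tr = tr_grid, shift_accumulation = acc, shift_decay = dec)
}
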