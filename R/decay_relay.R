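#' Decay-relay timer space
#'
#' Each consistent circuit is positioned by how much the induction times of
#' the last two TTFs (Pdm and Cas) shift when the repressor-decay or
#' activator-relay links governing their induction are removed. For Pdm the
#' decay-removal perturbation is removal of Hb-|Pdm and the relay removal is
#' removal of Kr->Pdm; for Cas they are removal of Kr-|Cas (Hb-|Cas is left
#' intact: Hb has already decayed by the time Cas turns on) and of Pdm->Cas.
#' Deletion sensitivities (full TTF knockouts) give the Hb-Kr sensitivity
#' coordinates used to connect model and experiment.
#'
#' @name decay_relay
NULL

#' Induction time of a TTF from a trajectory
#'
#' Earliest upcrossing of the on-threshold after which the level stays above
#' threshold for at least `sustain` minutes (or through the end of the
#' simulation), discounting early transients.
#'
#' @param traj A `ttf_trajectory`.
#' @param ttf TTF name.
#' @param threshold On-threshold (concentration) for this TTF.
#' @param sustain Minimum sustained time above threshold (min), default 10.
#' @return Time in minutes, or the [NOT_INDUCED] sentinel.
#' @export
induction_time <- function(traj, ttf, threshold, sustain = 10) {
  y <- traj$levels[, ttf]
  above <- y >= threshold
  if (!any(above)) return(NOT_INDUCED)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dt <- traj$times[2] - traj$times[1]
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    dur <- (r$lengths[k] - 1) * dt
    if (dur >= sustain || ends[k] == length(y))
      return(traj$times[starts[k]])
  }
  NOT_INDUCED
}

#' Percent shift of induction time under a perturbation
#'
#' `100 * (t_pert - t_wt) / t_wt`. A perturbed TTF that is never induced is
#' capped at the horizon and flagged.
#'
#' @param t_pert Perturbed induction time (min) or [NOT_INDUCED].
#' @param t_wt Wild-type induction time (min, finite, > 0).
#' @param horizon Cap applied when `t_pert` is [NOT_INDUCED].
#' @return List with `delta_pct` (signed percent) and `capped` flag.
#' @export
delta_t_ind <- function(t_pert, t_wt, horizon = model_constants()$horizon) {
  if (identical(t_wt, NOT_INDUCED) || !is.finite(t_wt) || t_wt <= 0)
    stop("wild-type induction time must be finite and positive ",
         "(circuit not consistent)")
  capped <- identical(t_pert, NOT_INDUCED)
  if (capped) t_pert <- horizon
  list(delta_pct = 100 * (t_pert - t_wt) / t_wt, capped = capped)
}

# The (ttf, perturbation) pairs whose induction shifts feed the analyses.
shift_plan <- function() {
  data.frame(
    name = c("pdm_rm_decay", "pdm_rm_relay", "cas_rm_decay", "cas_rm_relay",
             "pdm_del_hb", "pdm_del_kr", "cas_del_kr", "cas_del_pdm"),
    ttf  = c("Pdm", "Pdm", "Cas", "Cas", "Pdm", "Pdm", "Cas", "Cas"),
    kind = c("remove_link", "remove_link", "remove_link", "remove_link",
             "deletion", "deletion", "deletion", "deletion"),
    target = c("Hb-|Pdm", "Kr->Pdm", "Kr-|Cas", "Pdm->Cas",
               "Hb", "Kr", "Kr", "Pdm"),
    stringsAsFactors = FALSE
  )
}

#' Induction-time shifts of one circuit under all scoring perturbations
#'
#' Simulates the four link removals and three TTF deletions that feed the
#' decay/relay significance scores and the deletion-sensitivity analyses, and
#' returns the signed percent shift of Pdm/Cas induction for each.
#'
#' @param params A consistent `ttf_params`.
#' @param topology A `ttf_topology`.
#' @param constants Structural constants.
#' @return Named list: for each plan entry, `delta_pct` and `capped`; plus
#'   `t_wt_Pdm`, `t_wt_Cas`.
#' @export
induction_shifts <- function(params, topology = build_default_topology(),
                             constants = model_constants()) {
  thr <- on_thresholds(params, topology, constants)
  wt <- simulate_circuit(params, topology, pert_none(), constants)
  t_wt <- list(
    Pdm = induction_time(wt, "Pdm", thr["Pdm"], constants$sustain),
    Cas = induction_time(wt, "Cas", thr["Cas"], constants$sustain))
  plan <- shift_plan()
  out <- list(t_wt_Pdm = t_wt$Pdm, t_wt_Cas = t_wt$Cas)
  for (i in seq_len(nrow(plan))) {
    traj <- simulate_circuit(params, topology,
                             perturbation(plan$kind[i], plan$target[i]),
                             constants)
    tp <- induction_time(traj, plan$ttf[i], thr[plan$ttf[i]],
                         constants$sustain)
    d <- delta_t_ind(tp, t_wt[[plan$ttf[i]]], constants$horizon)
    out[[plan$name[i]]] <- d$delta_pct
    out[[paste0(plan$name[i], "_capped")]] <- d$capped
  }
  out
}

#' Induction shifts for all consistent records
#'
#' @param records Screen records (with or without robustness scores).
#' @inheritParams induction_shifts
#' @param verbose Log progress.
#' @return `records` with one signed-percent column per scoring perturbation
#'   (`pdm_rm_decay`, `pdm_rm_relay`, `cas_rm_decay`, `cas_rm_relay`,
#'   `pdm_del_hb`, `pdm_del_kr`, `cas_del_kr`, `cas_del_pdm`) and matching
#'   `*_capped` flags; non-consistent rows stay NA.
#' @export
shift_records <- function(records, topology = build_default_topology(),
                          constants = model_constants(), verbose = FALSE) {
  plan <- shift_plan()
  for (nm in plan$name) {
    records[[nm]] <- NA_real_
    records[[paste0(nm, "_capped")]] <- NA
  }
  idx <- which(records$consistent == 1 & records$failed == 0)
  for (j in seq_along(idx)) {
    i <- idx[j]
    sh <- try(induction_shifts(record_params(records, i, topology), topology,
                               constants), silent = TRUE)
    if (inherits(sh, "try-error")) next
    for (nm in plan$name) {
      records[[nm]][i] <- sh[[nm]]
      records[[paste0(nm, "_capped")]][i] <- sh[[paste0(nm, "_capped")]]
    }
    if (verbose && j %% 50 == 0)
      message(sprintf("shifts: %d/%d circuits", j, length(idx)))
  }
  records
}

#' Decay and relay significance coordinates
#'
#' Per circuit, the absolute per-TTF link-removal shifts are normalized as a
#' percentage of the maximal shift observed over the whole ensemble (per
#' perturbation), then the two decay contributions (Pdm via Hb-|Pdm removal,
#' Cas via Kr-|Cas removal) are combined, and likewise the two relay
#' contributions; the combined scores are rescaled to `[0, 100]`.
#'
#' @param records Records with shift columns (see [shift_records()]).
#' @return `records` with `decay_significance` and `relay_significance`
#'   columns in `[0, 100]`.
#' @export
significance_scores <- function(records) {
  idx <- which(records$consistent == 1 & records$failed == 0)
  if (!length(idx)) stop("no consistent records")
  norm_abs <- function(col) {
    v <- abs(records[[col]][idx])
    mx <- max(v, na.rm = TRUE)
    if (mx == 0) rep(0, length(v)) else 100 * v / mx
  }
  decay <- (norm_abs("pdm_rm_decay") + norm_abs("cas_rm_decay")) / 2
  relay <- (norm_abs("pdm_rm_relay") + norm_abs("cas_rm_relay")) / 2
  records$decay_significance <- NA_real_
  records$relay_significance <- NA_real_
  records$decay_significance[idx] <- decay
  records$relay_significance[idx] <- relay
  records
}

#' Deletion-sensitivity coordinates (Hb-Kr sensitivity space)
#'
#' The signed percent change of Pdm induction under Hb deletion and under Kr
#' deletion position each circuit in the Hb-Kr sensitivity space.
#'
#' @param records Records with shift columns.
#' @param robust_cutoff Robustness score above which a record counts as
#'   robust (used only for the `robust` flag).
#' @return Data frame: `params_id`, `hb_deletion_shift`, `kr_deletion_shift`,
#'   `capped` flags, `robust` flag (NA without scores).
#' @export
deletion_sensitivity <- function(records, robust_cutoff = 80) {
  idx <- which(records$consistent == 1 & records$failed == 0)
  data.frame(
    params_id = records$params_id[idx],
    hb_deletion_shift = records$pdm_del_hb[idx],
    kr_deletion_shift = records$pdm_del_kr[idx],
    hb_capped = records$pdm_del_hb_capped[idx],
    kr_capped = records$pdm_del_kr_capped[idx],
    robust = if ("robustness_score" %in% names(records))
      records$robustness_score[idx] > robust_cutoff else NA,
    stringsAsFactors = FALSE
  )
}

correlation_pairs <- function() {
  data.frame(
    pair = c("pdm_hb", "pdm_kr", "cas_pdm", "cas_kr"),
    deletion = c("pdm_del_hb", "pdm_del_kr", "cas_del_pdm", "cas_del_kr"),
    link = c("pdm_rm_decay", "pdm_rm_relay", "cas_rm_relay", "cas_rm_decay"),
    stringsAsFactors = FALSE
  )
}

#' Correlation between deletion and link-removal shifts
#'
#' For each of the four (TTF, regulator) pairs, the Pearson correlation
#' between the induction shift under regulator deletion and under removal of
#' just the corresponding regulatory link, over all consistent records and
#' over robust (score > cutoff) records only.
#'
#' @param records Records with shift columns and `robustness_score`.
#' @param robust_cutoff Robustness cutoff, default 80.
#' @param exclude_capped Drop records whose shift was capped at the horizon
#'   (the perturbed TTF never reached a sustained induction); capped values
#'   are bounds, not measurements, and act as leverage points.
#' @return Data frame: `pair`, `r_all`, `n_all`, `r_robust`, `n_robust`
#'   (correlations are NA when variance is degenerate or n < 3).
#' @export
deletion_vs_link_correlation <- function(records, robust_cutoff = 80,
                                         exclude_capped = TRUE) {
  idx <- which(records$consistent == 1 & records$failed == 0)
  if (length(idx) < 10) stop("need at least 10 consistent records")
  pairs <- correlation_pairs()
  safe_cor <- function(x, y, keep) {
    ok <- is.finite(x) & is.finite(y) & keep
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  }
  keep_of <- function(sub, cols) {
    keep <- rep(TRUE, length(sub))
    if (exclude_capped) for (cc in cols) {
      cap <- records[[paste0(cc, "_capped")]]
      if (!is.null(cap)) keep <- keep & !cap[sub] %in% TRUE
    }
    keep
  }
  rob <- if ("robustness_score" %in% names(records))
    idx[which(records$robustness_score[idx] > robust_cutoff)] else integer(0)
  out <- pairs
  out$r_all <- out$r_robust <- NA_real_
  out$n_all <- length(idx)
  out$n_robust <- length(rob)
  for (i in seq_len(nrow(pairs))) {
    cols <- c(pairs$deletion[i], pairs$link[i])
    out$r_all[i] <- safe_cor(records[[cols[1]]][idx],
                             records[[cols[2]]][idx], keep_of(idx, cols))
    out$r_robust[i] <- safe_cor(records[[cols[1]]][rob],
                                records[[cols[2]]][rob], keep_of(rob, cols))
  }
  out
}

#' Classify circuits into thirds of the decay-relay plane
#'
#' The plane is split into three diagonal bands by the dominance difference
#' `decay - relay`: the decay-dominant third (`> 100/3`), the relay-dominant
#' third (`< -100/3`) and the mixed band between.
#'
#' @param decay,relay Significance coordinates in `[0, 100]`.
#' @return Character vector: `"decay"`, `"relay"` or `"mixed"`.
#' @export
dominance_class <- function(decay, relay) {
  d <- decay - relay
  ifelse(d > 100 / 3, "decay", ifelse(d < -100 / 3, "relay", "mixed"))
}

#' 2D density / mean-score maps over a coordinate plane
#'
#' Bins records over (by default) the `[0,100]^2` decay-relay plane and
#' returns per-bin counts and, when `values` is given, per-bin means. Empty
#' bins are NA, not zero.
#'
#' @param x,y Coordinates.
#' @param values Optional values to average per bin (e.g. robustness scores).
#' @param bins Number of bins per axis, default 20.
#' @param lims Axis limits `c(low, high)`, shared by both axes.
#' @return List: `x_breaks`, `y_breaks`, `counts` (bins x bins matrix, NA for
#'   empty), `means` (if `values` given).
#' @export
density_map <- function(x, y, values = NULL, bins = 20, lims = c(0, 100)) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(values)) values <- values[ok]
  bx <- seq(lims[1], lims[2], length.out = bins + 1)
  ix <- pmin(pmax(findInterval(x, bx, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y, bx, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(NA_real_, bins, bins)
  means <- if (!is.null(values)) matrix(NA_real_, bins, bins) else NULL
  for (k in seq_along(ix)) {
    c0 <- counts[ix[k], iy[k]]
    counts[ix[k], iy[k]] <- if (is.na(c0)) 1 else c0 + 1
  }
  if (!is.null(values)) {
    sums <- matrix(0, bins, bins)
    for (k in seq_along(ix)) sums[ix[k], iy[k]] <- sums[ix[k], iy[k]] + values[k]
    means[!is.na(counts)] <- sums[!is.na(counts)] / counts[!is.na(counts)]
  }
  list(x_breaks = bx, y_breaks = bx, counts = counts, means = means)
}
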