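#' In-vivo positioning statistics
#'
#' Statistics on staged per-neuroblast staining measurements: nuclear-volume
#' outlier filtering, per-stage summaries of log(TTF/En) intensity ratios,
#' induction-stage calling against a wild-type background, measured induction
#' shifts with interval error bars, translation of deletion shifts to
#' link-removal shifts through the screened ensemble, and the final placement
#' of the in-vivo circuit in decay-relay space.
#'
#' @name invivo
NULL

#' Default embryonic stage list
#' @return Ordered character vector of stage labels.
#' @export
default_stages <- function() c("S9", "S10E", "S10", "S11E", "S11", "S12")

#' Default stage-to-minutes table
#'
#' Minutes on the cascade clock per embryonic stage. The mapping is a
#' reconstructed, configurable default (the stage timing is only implicit in
#' published figure axes); stage-dependent outputs carry this table's hash
#' for provenance.
#'
#' @return Data frame: `stage`, `t_start`, `t_end` (min), contiguous and
#'   increasing.
#' @export
default_stage_table <- function() {
  st <- data.frame(stage = default_stages(),
                   t_start = c(0, 40, 70, 100, 160, 220),
                   t_end = c(40, 70, 100, 160, 220, 340),
                   stringsAsFactors = FALSE)
  validate_stage_table(st)
}

validate_stage_table <- function(st) {
  stopifnot(is.data.frame(st),
            all(c("stage", "t_start", "t_end") %in% names(st)))
  if (any(st$t_end <= st$t_start)) stop("stage durations must be positive")
  if (nrow(st) > 1 && any(st$t_start[-1] != st$t_end[-nrow(st)]))
    stop("stage table must be contiguous")
  attr(st, "hash") <- sum(st$t_start * seq_len(nrow(st))) +
    sum(st$t_end * 31 * seq_len(nrow(st)))
  st
}

#' Read / write a stage-time table (YAML)
#' @param path File path.
#' @export
read_stage_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  st <- do.call(rbind, lapply(cfg$stages, function(x)
    data.frame(stage = x$stage, t_start = x$t_start, t_end = x$t_end,
               stringsAsFactors = FALSE)))
  validate_stage_table(st)
}

#' @rdname read_stage_table
#' @param stage_table Stage table data frame.
#' @export
write_stage_table <- function(stage_table, path) {
  yaml::write_yaml(list(stages = lapply(seq_len(nrow(stage_table)), function(i)
    list(stage = stage_table$stage[i], t_start = stage_table$t_start[i],
         t_end = stage_table$t_end[i]))), path)
  invisible(path)
}

stage_for_time <- function(t, stage_table) {
  i <- which(t >= stage_table$t_start & t < stage_table$t_end)
  if (!length(i)) {
    if (t >= stage_table$t_end[nrow(stage_table)])
      return(stage_table$stage[nrow(stage_table)])
    return(NA_character_)
  }
  stage_table$stage[i[1]]
}

#' Filter measurements by nuclear volume
#'
#' Mean and SD of nuclear volume are computed over the wild-type population;
#' every record (any genotype) whose volume lies further than `k` SD from
#' that mean is excluded (such cells are assumed to be dividing or
#' misidentified). With fewer than 3 WT records the filter is the identity.
#'
#' @param measurements Data frame with columns `genotype`, `stage`, `ttf`,
#'   `log_ratio`, `volume`.
#' @param k SD multiple, default 2.
#' @param wt_genotype Label of the wild-type genotype.
#' @return List: `kept` (filtered data frame), `excluded` (removed rows with
#'   a `reason` column).
#' @export
filter_by_volume <- function(measurements, k = 2, wt_genotype = "WT") {
  wt <- measurements$volume[measurements$genotype == wt_genotype]
  if (length(wt) < 3) {
    message("fewer than 3 WT records: volume filter skipped")
    return(list(kept = measurements,
                excluded = measurements[0, , drop = FALSE]))
  }
  m <- mean(wt); s <- sd(wt)
  out <- abs(measurements$volume - m) > k * s
  excluded <- measurements[out, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- sprintf("volume %.3g beyond %g SD of WT mean %.3g",
                               excluded$volume, k, m)
  list(kept = measurements[!out, , drop = FALSE], excluded = excluded)
}

#' Per-stage summaries of log-ratio intensities
#'
#' @param measurements Filtered measurement data frame.
#' @param stages Ordered stage labels.
#' @return Data frame per (genotype, ttf, stage): `n`, `mean`, `sd`, `sem`,
#'   `ci_half = 1.96 * sem`.
#' @export
stage_summaries <- function(measurements, stages = default_stages()) {
  sp <- split(measurements,
              list(measurements$genotype, measurements$ttf,
                   measurements$stage), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    n <- nrow(d)
    s <- if (n > 1) sd(d$log_ratio) else NA_real_
    data.frame(genotype = d$genotype[1], ttf = d$ttf[1], stage = d$stage[1],
               n = n, mean = mean(d$log_ratio), sd = s,
               sem = s / sqrt(n), stringsAsFactors = FALSE)
  }))
  out$ci_half <- 1.96 * out$sem
  out$stage <- factor(out$stage, levels = stages)
  out <- out[order(out$genotype, out$ttf, out$stage), ]
  out$stage <- as.character(out$stage)
  rownames(out) <- NULL
  out
}

#' Call the induction stage of a TTF
#'
#' Background is the mean of the wild-type stage means in the second and
#' third stages (S10E and S10). The induction stage is the first stage, in
#' stage order but skipping the first stage (S9, which can carry an early
#' transient), whose 95% confidence interval lies entirely above background
#' (`mean - 1.96 SEM > background`); `"NONE"` if no stage qualifies.
#'
#' @param summaries Stage summaries for one (genotype, ttf).
#' @param wt_summaries Wild-type stage summaries for the same ttf (used only
#'   for the background; pass `summaries` again for WT itself).
#' @param stages Ordered stage labels.
#' @param background_stages Stages averaged into the background.
#' @param skip Stages never called (early-transient guard).
#' @return Stage label or `"NONE"`.
#' @export
call_induction_stage <- function(summaries, wt_summaries,
                                 stages = default_stages(),
                                 background_stages = c("S10E", "S10"),
                                 skip = stages[1]) {
  miss <- setdiff(background_stages, wt_summaries$stage)
  if (length(miss))
    stop("WT summaries missing background stage(s): ",
         paste(miss, collapse = ", "))
  background <- mean(wt_summaries$mean[match(background_stages,
                                             wt_summaries$stage)])
  for (st in setdiff(stages, skip)) {
    row <- summaries[summaries$stage == st, ]
    if (!nrow(row) || !is.finite(row$sem[1])) next
    if (row$mean[1] - 1.96 * row$sem[1] > background) return(st)
  }
  "NONE"
}

#' Measured induction shift between two called stages
#'
#' Induction times are taken as the midpoints of the called stages; the error
#' margin on each is half that stage's duration. The shift
#' `100 (t_mut - t_wt)/t_wt` is propagated by worst-case interval arithmetic
#' over the two midpoint intervals.
#'
#' @param stage_wt,stage_mut Called stage labels (not `"NONE"`).
#' @param stage_table Stage-time table.
#' @return List: `delta_pct`, `lo`, `hi` (percent), `t_wt`, `t_mut` (min).
#' @export
measured_delta_t <- function(stage_wt, stage_mut,
                             stage_table = default_stage_table()) {
  if (identical(stage_wt, "NONE") || identical(stage_mut, "NONE"))
    stop("both stages must be called (got NONE); use the capped workflow")
  mid_half <- function(stage) {
    i <- match(stage, stage_table$stage)
    if (is.na(i)) stop("unknown stage: ", stage)
    c(mid = (stage_table$t_start[i] + stage_table$t_end[i]) / 2,
      half = (stage_table$t_end[i] - stage_table$t_start[i]) / 2)
  }
  w <- mid_half(stage_wt); m <- mid_half(stage_mut)
  f <- function(tp, tw) 100 * (tp - tw) / tw
  corners <- c(f(m["mid"] - m["half"], w["mid"] + w["half"]),
               f(m["mid"] + m["half"], w["mid"] - w["half"]),
               f(m["mid"] - m["half"], w["mid"] - w["half"]),
               f(m["mid"] + m["half"], w["mid"] + w["half"]))
  list(delta_pct = unname(f(m["mid"], w["mid"])),
       lo = unname(min(corners)), hi = unname(max(corners)),
       t_wt = unname(w["mid"]), t_mut = unname(m["mid"]))
}

#' Translate a measured deletion shift into a link-removal shift range
#'
#' On the deletion-vs-link-removal correlation of the screened ensemble, the
#' measured deletion shift interval selects robust records (robustness score
#' > cutoff) whose deletion shift lies inside it; the returned range is the
#' min-max of their corresponding link-removal shifts.
#'
#' @param records Scored + shifted screen records.
#' @param measured_range `c(lo, hi)` percent (deletion shift interval).
#' @param pair One of `"pdm_hb"`, `"pdm_kr"`, `"cas_pdm"`, `"cas_kr"`.
#' @param robust_cutoff Robustness cutoff, default 80.
#' @return List: `lo`, `hi` (link-removal shift percent), `n` records used.
#' @export
translate_deletion_to_link_range <- function(records, measured_range, pair,
                                             robust_cutoff = 80) {
  pairs <- correlation_pairs()
  i <- match(pair, pairs$pair)
  if (is.na(i)) stop("unknown pair: ", pair)
  idx <- which(records$consistent == 1 & records$failed == 0 &
                 records$robustness_score > robust_cutoff)
  if (!length(idx)) stop("no robust records in the ensemble")
  del <- records[[pairs$deletion[i]]][idx]
  lnk <- records[[pairs$link[i]]][idx]
  sel <- which(del >= min(measured_range) & del <= max(measured_range))
  if (!length(sel)) {
    nearest <- idx[which.min(pmin(abs(del - min(measured_range)),
                                  abs(del - max(measured_range))))]
    stop("no robust record inside the measured range [",
         round(min(measured_range), 1), ", ", round(max(measured_range), 1),
         "]; nearest robust record: params_id=", records$params_id[nearest],
         " with deletion shift ",
         round(records[[pairs$deletion[i]]][nearest], 1), "%")
  }
  list(lo = min(lnk[sel]), hi = max(lnk[sel]), n = length(sel))
}

#' Position the in-vivo circuit in decay-relay space
#'
#' Combines per-TTF link-removal shift ranges into decay and relay
#' significance coordinates exactly as [significance_scores()] does for
#' simulated circuits, but with measurement-driven normalizers: the Pdm decay
#' shift is normalized by 100% (induction at t = 0 is the largest observable
#' advance); the Pdm and Cas relay shifts by the largest observable delay
#' (induction at the middle of the last experimental stage); the Cas decay
#' shift by the largest Cas decay-removal shift observed in the simulated
#' ensemble (Cas cannot be advanced to t = 0 while Hb still represses it).
#' Error bars come from propagating the range endpoints.
#'
#' @param link_ranges Named list of `c(lo, hi)` percent shifts:
#'   `pdm_decay`, `pdm_relay`, `cas_decay`, `cas_relay`.
#' @param normalizers Named positive values: `pdm_decay`, `pdm_relay`,
#'   `cas_decay`, `cas_relay` (maximal |shift| per contribution, percent).
#' @return An `invivo_position`: list with `decay`, `relay` (each `value`,
#'   `lo`, `hi` in `[0, 100]`).
#' @export
position_invivo <- function(link_ranges, normalizers) {
  need <- c("pdm_decay", "pdm_relay", "cas_decay", "cas_relay")
  miss <- setdiff(need, names(link_ranges))
  if (length(miss)) stop("missing link range(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need, names(normalizers))
  if (length(miss)) stop("missing normalizer(s): ", paste(miss, collapse = ", "))
  if (any(unlist(normalizers[need]) <= 0)) stop("normalizers must be positive")
  contrib <- function(rng, nrm) {
    v <- sort(abs(as.numeric(rng)))
    pmin(100 * v / nrm, 100)
  }
  comb <- function(a, b) {
    lo <- (a[1] + b[1]) / 2; hi <- (a[2] + b[2]) / 2
    list(value = (lo + hi) / 2, lo = lo, hi = hi)
  }
  decay <- comb(contrib(link_ranges$pdm_decay, normalizers$pdm_decay),
                contrib(link_ranges$cas_decay, normalizers$cas_decay))
  relay <- comb(contrib(link_ranges$pdm_relay, normalizers$pdm_relay),
                contrib(link_ranges$cas_relay, normalizers$cas_relay))
  structure(list(decay = decay, relay = relay), class = "invivo_position")
}

#' @export
print.invivo_position <- function(x, ...) {
  cat(sprintf("in-vivo position: decay %.1f [%.1f, %.1f], relay %.1f [%.1f, %.1f]\n",
              x$decay$value, x$decay$lo, x$decay$hi,
              x$relay$value, x$relay$lo, x$relay$hi))
  invisible(x)
}
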