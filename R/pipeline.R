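#' End-to-end pipeline
#'
#' Orchestrates screen -> robustness scoring -> perturbation shifts ->
#' decay-relay positioning -> synthetic in-vivo study -> in-vivo positioning,
#' with explicit seeds and tabular outputs (CSV for records, JSON for nested
#' results).
#'
#' @name pipeline
NULL

#' Predicted induction stages of a circuit
#'
#' Simulates the circuit under each genotype of interest and maps the Pdm and
#' Cas induction times onto embryonic stages via the stage-time table.
#'
#' @param params A `ttf_params` (a consistent circuit).
#' @param topology,constants Model configuration.
#' @param stage_table Stage-time table.
#' @return Data frame: `genotype`, `ttf`, `t_ind` (min or NA), `stage`
#'   (label or `"NONE"`).
#' @export
predict_induction_stages <- function(params,
                                     topology = build_default_topology(),
                                     constants = model_constants(),
                                     stage_table = default_stage_table()) {
  thr <- on_thresholds(params, topology, constants)
  plan <- data.frame(
    genotype = c("WT", "hb_del", "kr_del", "WT", "kr_del", "pdm_del"),
    ttf = c("Pdm", "Pdm", "Pdm", "Cas", "Cas", "Cas"),
    stringsAsFactors = FALSE)
  perts <- list(WT = pert_none(),
                hb_del = perturbation("deletion", "Hb"),
                kr_del = perturbation("deletion", "Kr"),
                pdm_del = perturbation("deletion", "Pdm"))
  trajs <- lapply(perts, function(p)
    simulate_circuit(params, topology, p, constants))
  plan$t_ind <- NA_real_
  plan$stage <- "NONE"
  for (i in seq_len(nrow(plan))) {
    ti <- induction_time(trajs[[plan$genotype[i]]], plan$ttf[i],
                         thr[plan$ttf[i]], constants$sustain)
    if (!identical(ti, NOT_INDUCED)) {
      plan$t_ind[i] <- ti
      st <- stage_for_time(ti, stage_table)
      if (!is.na(st)) plan$stage[i] <- st
    }
  }
  plan
}

#' Synthesize an in-vivo style staining study from a ground-truth circuit
#'
#' Generates staged staining measurements for Pdm (WT, hb-null, Kr-null) and
#' Cas (WT, Kr-null, pdm-null) whose true induction stages are the circuit's
#' predicted stages. Wild-type Pdm carries an early first-stage transient
#' (as seen in vivo); volumes carry planted outliers.
#'
#' @param params Ground-truth `ttf_params`.
#' @param seed Integer seed.
#' @param n_per_stage Cells per stage.
#' @param noise_sd Log-ratio noise SD.
#' @param effect Induction step (log-ratio units).
#' @param transient Early-transient amplitude for WT Pdm.
#' @param outlier_frac Planted volume-outlier fraction.
#' @param topology,constants,stage_table Model configuration.
#' @return List: `measurements` data frame, `truth` (predicted stages).
#' @export
synthesize_invivo_study <- function(params, seed = 1, n_per_stage = 10,
                                    noise_sd = 0.5, effect = 1.5,
                                    transient = 1, outlier_frac = 0.05,
                                    topology = build_default_topology(),
                                    constants = model_constants(),
                                    stage_table = default_stage_table()) {
  truth <- predict_induction_stages(params, topology, constants, stage_table)
  set.seed(as.integer(seed))
  cfgs <- lapply(seq_len(nrow(truth)), function(i)
    staining_config(genotype = truth$genotype[i], ttf = truth$ttf[i],
                    stages = stage_table$stage, n_per_stage = n_per_stage,
                    baseline = 0, effect = effect,
                    induction_stage = truth$stage[i],
                    transient = if (truth$genotype[i] == "WT" &&
                                    truth$ttf[i] == "Pdm") transient else 0,
                    noise_sd = noise_sd, outlier_frac = outlier_frac))
  list(measurements = generate_staining_dataset(cfgs), truth = truth)
}

#' Position an in-vivo style study in decay-relay space
#'
#' The full measurement-side procedure: volume filtering, stage summaries,
#' induction-stage calling per (genotype, ttf), measured deletion-shift
#' intervals, translation to link-removal intervals through the robust
#' members of the screened ensemble, and the final normalized positioning.
#'
#' @param measurements Staining measurement data frame.
#' @param records Scored + shifted screen records (the simulated ensemble).
#' @param stage_table Stage-time table.
#' @param robust_cutoff Robustness cutoff for the translation step.
#' @return List: `position` (`invivo_position`), `stages` (called stages),
#'   `deletion_ranges`, `link_ranges`, `normalizers`, `n_excluded` (volume
#'   filter).
#' @export
run_invivo_positioning <- function(measurements, records,
                                   stage_table = default_stage_table(),
                                   robust_cutoff = 80) {
  flt <- filter_by_volume(measurements)
  summ <- stage_summaries(flt$kept, stages = stage_table$stage)
  get_summ <- function(gt, tf) summ[summ$genotype == gt & summ$ttf == tf, ]
  call_for <- function(gt, tf)
    call_induction_stage(get_summ(gt, tf), get_summ("WT", tf),
                         stages = stage_table$stage)
  stages <- list(
    pdm_wt = call_for("WT", "Pdm"), pdm_hb = call_for("hb_del", "Pdm"),
    pdm_kr = call_for("kr_del", "Pdm"),
    cas_wt = call_for("WT", "Cas"), cas_kr = call_for("kr_del", "Cas"),
    cas_pdm = call_for("pdm_del", "Cas"))
  # Interval of the measured deletion shift. When the mutant calls at the
  # earliest scannable stage, the advance is only bounded from above by the
  # stage clock (induction at t = 0 would read the same), so the advanced
  # end of the interval extends to -100% -- the observability limit that
  # also defines the decay-side normalizer.
  first_scannable <- stage_table$stage[2]
  last_stage <- stage_table$stage[nrow(stage_table)]
  mk_range <- function(wt, mut) {
    d <- measured_delta_t(wt, mut, stage_table)
    lo <- d$lo
    hi <- d$hi
    if (identical(mut, first_scannable)) lo <- -100
    # a call at the last stage cannot be told apart from any later induction
    if (identical(mut, last_stage)) hi <- Inf
    c(lo, hi)
  }
  deletion_ranges <- list(
    pdm_hb = mk_range(stages$pdm_wt, stages$pdm_hb),
    pdm_kr = mk_range(stages$pdm_wt, stages$pdm_kr),
    cas_kr = mk_range(stages$cas_wt, stages$cas_kr),
    cas_pdm = mk_range(stages$cas_wt, stages$cas_pdm))
  tr <- function(rng, pair)
    translate_deletion_to_link_range(records, rng, pair, robust_cutoff)
  link_ranges <- list(
    pdm_decay = unlist(tr(deletion_ranges$pdm_hb, "pdm_hb")[c("lo", "hi")]),
    pdm_relay = unlist(tr(deletion_ranges$pdm_kr, "pdm_kr")[c("lo", "hi")]),
    cas_decay = unlist(tr(deletion_ranges$cas_kr, "cas_kr")[c("lo", "hi")]),
    cas_relay = unlist(tr(deletion_ranges$cas_pdm, "cas_pdm")[c("lo", "hi")]))
  mid <- function(stage) {
    i <- match(stage, stage_table$stage)
    (stage_table$t_start[i] + stage_table$t_end[i]) / 2
  }
  last_mid <- mid(stage_table$stage[nrow(stage_table)])
  idx <- which(records$consistent == 1 & records$failed == 0)
  normalizers <- list(
    pdm_decay = 100,
    pdm_relay = 100 * (last_mid - mid(stages$pdm_wt)) / mid(stages$pdm_wt),
    cas_decay = max(abs(records$cas_rm_decay[idx]), na.rm = TRUE),
    cas_relay = 100 * (last_mid - mid(stages$cas_wt)) / mid(stages$cas_wt))
  list(position = position_invivo(link_ranges, normalizers),
       stages = stages, deletion_ranges = deletion_ranges,
       link_ranges = link_ranges, normalizers = normalizers,
       n_excluded = nrow(flt$excluded))
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param n_circuits Screen size.
#' @param seed Master seed (all stage seeds derive from it).
#' @param n_per_stage,noise_sd,effect Synthetic staining study conditions.
#' @param robust_cutoff Robustness cutoff.
#' @return Named list.
#' @export
pipeline_config <- function(out_dir = tempfile("nbtimer_run_"),
                            n_circuits = 2000, seed = 1, n_per_stage = 10,
                            noise_sd = 0.5, effect = 1.5,
                            robust_cutoff = 80, ranges = NULL) {
  list(out_dir = out_dir, n_circuits = n_circuits, seed = seed,
       n_per_stage = n_per_stage, noise_sd = noise_sd, effect = effect,
       robust_cutoff = robust_cutoff, ranges = ranges)
}

#' Run the full pipeline
#'
#' screen -> robustness -> shifts -> significance coordinates -> density maps
#' -> synthetic in-vivo study from the shipped decay-dominant fixture ->
#' in-vivo positioning. Writes `records.csv`, `coords.csv`, `density.json`,
#' `position.json` and `manifest.json` under `config$out_dir`; identical
#' seeds give identical record CSVs.
#'
#' @param config List from [pipeline_config()].
#' @return The run manifest (invisibly the same as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  need <- c("out_dir", "n_circuits", "seed", "n_per_stage", "noise_sd",
            "effect", "robust_cutoff")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("missing config key(s): ", paste(miss, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  topology <- build_default_topology()
  constants <- model_constants()
  stage_table <- default_stage_table()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  rec_path <- file.path(config$out_dir, "records.csv")
  ranges <- if (is.null(config$ranges)) default_ranges(topology)
            else config$ranges
  rec <- stage("screen",
               run_screen(config$n_circuits, ranges = ranges,
                          seed = config$seed, topology = topology,
                          constants = constants, out = rec_path))
  rec <- stage("score", score_records(rec, topology, constants))
  write.csv(rec, rec_path, row.names = FALSE)
  rec <- stage("shifts", shift_records(rec, topology, constants))
  rec <- stage("significance", significance_scores(rec))
  write.csv(rec, rec_path, row.names = FALSE)

  idx <- which(rec$consistent == 1 & rec$failed == 0)
  coords <- data.frame(params_id = rec$params_id[idx],
                       decay_significance = rec$decay_significance[idx],
                       relay_significance = rec$relay_significance[idx],
                       robustness_score = rec$robustness_score[idx])
  coords_path <- file.path(config$out_dir, "coords.csv")
  write.csv(coords, coords_path, row.names = FALSE)
  dm <- density_map(coords$decay_significance, coords$relay_significance,
                    coords$robustness_score)
  dens_path <- file.path(config$out_dir, "density.json")
  jsonlite::write_json(dm, dens_path, auto_unbox = TRUE, digits = NA,
                       na = "null")

  truth_params <- fixture_circuit("decay_dominant", topology)
  study <- stage("synthesize",
                 synthesize_invivo_study(truth_params, seed = config$seed + 1,
                                         n_per_stage = config$n_per_stage,
                                         noise_sd = config$noise_sd,
                                         effect = config$effect,
                                         topology = topology,
                                         constants = constants,
                                         stage_table = stage_table))
  meas_path <- file.path(config$out_dir, "measurements.csv")
  write.csv(study$measurements, meas_path, row.names = FALSE)
  pos <- stage("position",
               run_invivo_positioning(study$measurements, rec, stage_table,
                                      config$robust_cutoff))
  pos_path <- file.path(config$out_dir, "position.json")
  # plain-list, finite-number view for JSON (open-ended measured intervals
  # carry Inf endpoints; JSON has no Inf)
  de_inf <- function(x) if (is.numeric(x)) ifelse(is.finite(x), x, NA) else x
  pos_out <- list(position = lapply(unclass(pos$position),
                                    function(ax) lapply(ax, de_inf)),
                  stages = pos$stages,
                  deletion_ranges = lapply(pos$deletion_ranges, de_inf),
                  link_ranges = lapply(pos$link_ranges, de_inf),
                  normalizers = lapply(pos$normalizers, de_inf),
                  n_excluded = pos$n_excluded)
  jsonlite::write_json(pos_out, pos_path, auto_unbox = TRUE, digits = NA,
                       na = "null")

  manifest <- list(
    seed = config$seed,
    stage_table_hash = attr(stage_table, "hash"),
    n_drawn = nrow(rec), n_consistent = length(idx),
    n_robust = sum(rec$robustness_score[idx] > config$robust_cutoff,
                   na.rm = TRUE),
    outputs = list(records = rec_path, coords = coords_path,
                   density = dens_path, measurements = meas_path,
                   position = pos_path))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
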