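#' Random-parameter consistency screen
#'
#' Draws parameter sets log-uniformly within configured ranges, simulates
#' wild type and every genotype of the phenotype table, and retains circuits
#' whose on-TTF phase sequences match the expected sequences for all
#' genotypes. Rejection sampling, as in the original analysis.
#'
#' @name screen
NULL

# Derived per-draw seed so the consistent subset is invariant to batching:
# draw i always sees the same RNG substream regardless of chunking.
draw_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647)
}

simulate_genotypes <- function(params, topology, table, constants,
                               thresholds, params_id = NA) {
  seqs <- list()
  for (g in names(table)) {
    traj <- simulate_circuit(params, topology, table[[g]]$perturbation,
                             constants, params_id = params_id)
    seqs[[g]] <- trajectory_to_phases(traj, thresholds, constants$min_phase)
    got <- seqs[[g]]$on_set
    if (!identical(got[got != ""], table[[g]]$expected))
      return(list(seqs = seqs, consistent = FALSE, first_fail = g,
                  last_traj = traj))
  }
  list(seqs = seqs, consistent = TRUE, first_fail = NA_character_,
       last_traj = NULL)
}

screen_one <- function(params, topology, table, constants, params_id = NA) {
  thresholds <- on_thresholds(params, topology, constants)
  res <- try(simulate_genotypes(params, topology, table, constants,
                                thresholds, params_id), silent = TRUE)
  if (inherits(res, "try-error"))
    return(list(consistent = FALSE, failed = TRUE,
                wt_induction = setNames(rep(NA_real_, length(topology$ttfs)),
                                        topology$ttfs)))
  wt_ind <- setNames(rep(NA_real_, length(topology$ttfs)), topology$ttfs)
  if (!is.null(res$seqs$WT)) {
    wt_traj <- simulate_circuit(params, topology, pert_none(), constants,
                                params_id = params_id)
    for (tf in topology$ttfs) {
      ti <- induction_time(wt_traj, tf, thresholds[tf], constants$sustain)
      wt_ind[tf] <- if (identical(ti, NOT_INDUCED)) NA_real_ else ti
    }
  }
  list(consistent = res$consistent, failed = FALSE, wt_induction = wt_ind)
}

#' Run the consistency screen
#'
#' Fully reproducible: draw `i` uses an RNG substream derived from
#' `(seed, i)`, so results are invariant to chunking and restart. When `out`
#' is given, records are appended to disk in chunks so memory stays bounded
#' in `n`.
#'
#' @param n Number of circuits to draw.
#' @param ranges Parameter ranges ([default_ranges()]).
#' @param topology A `ttf_topology`.
#' @param table A `ttf_phenotype_table`.
#' @param seed Integer seed.
#' @param constants Structural constants.
#' @param out Optional CSV path; records are streamed there.
#' @param chunk Chunk size for streaming/progress.
#' @param verbose Log progress to stderr.
#' @return Data frame of screen records: `params_id`, the 17 parameter
#'   columns, `consistent`, `failed`, and WT induction times `t_ind_<TTF>`
#'   (min; NA encodes not-induced in the CSV, the `NOT_INDUCED` sentinel is
#'   used in list APIs).
#' @export
run_screen <- function(n, ranges = default_ranges(topology),
                       topology = build_default_topology(),
                       table = default_phenotype_table(),
                       seed = 1, constants = model_constants(),
                       out = NULL, chunk = 1000, verbose = FALSE) {
  stopifnot(n >= 0)
  cols <- c("params_id", param_names(topology), "consistent", "failed",
            paste0("t_ind_", topology$ttfs))
  empty <- as.data.frame(matrix(numeric(0), ncol = length(cols),
                                dimnames = list(NULL, cols)))
  if (n == 0) return(empty)
  acc <- list()
  buf <- list()
  first_write <- TRUE
  for (i in seq_len(n)) {
    set.seed(draw_seed(seed, i))
    params <- sample_parameter_set(ranges, topology)
    r <- screen_one(params, topology, table, constants, params_id = i)
    row <- c(list(params_id = i), as.list(unclass(params)),
             list(consistent = as.integer(r$consistent),
                  failed = as.integer(r$failed)),
             as.list(setNames(unname(r$wt_induction),
                              paste0("t_ind_", topology$ttfs))))
    buf[[length(buf) + 1L]] <- as.data.frame(row)
    if (length(buf) == chunk || i == n) {
      block <- do.call(rbind, buf)
      if (!is.null(out)) {
        write.table(block, out, sep = ",", row.names = FALSE,
                    col.names = first_write, append = !first_write)
        first_write <- FALSE
      }
      acc[[length(acc) + 1L]] <- block
      buf <- list()
      if (verbose)
        message(sprintf("screen: %d/%d drawn, %d consistent", i, n,
                        sum(vapply(acc, function(b) sum(b$consistent), 0))))
    }
  }
  res <- do.call(rbind, acc)
  rownames(res) <- NULL
  res
}

#' Consistent records of a screen result
#' @param records Data frame from [run_screen()].
#' @return Subset with `consistent == 1`.
#' @export
consistent_records <- function(records) {
  records[records$consistent == 1 & records$failed == 0, , drop = FALSE]
}

record_params <- function(records, i, topology = build_default_topology()) {
  as_ttf_params(unlist(records[i, param_names(topology)]), topology)
}
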