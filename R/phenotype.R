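#' Phase sequences and phenotype consistency
#'
#' A trajectory is discretized into a phase sequence: maximal time intervals
#' with a constant set of "on" (above threshold) TTFs. Consistency of a
#' circuit means that, for wild type and every mutant/misexpression genotype,
#' the ordered list of non-empty on-sets equals the experimentally expected
#' list; phase durations are ignored for consistency.
#'
#' @name phenotype
NULL

on_set_key <- function(on, ttfs) paste(ttfs[on], collapse = "+")

#' Discretize a trajectory into a phase sequence
#'
#' A TTF is "on" at a time point when its level is >= its on-threshold.
#' Phases shorter than `min_phase` minutes are merged into the preceding
#' phase (the leading phase, having no predecessor, is merged into its
#' successor); adjacent equal on-sets are then re-merged.
#'
#' @param traj A `ttf_trajectory`.
#' @param thresholds Named per-TTF on-thresholds (from [on_thresholds()] of
#'   the unperturbed parameter set).
#' @param min_phase Minimum phase duration (min), default 2.
#' @return A `ttf_phases` data frame with columns `on_set` (canonical string,
#'   e.g. `"Hb+Kr"`, `""` for none), `start`, `end` (min).
#' @export
trajectory_to_phases <- function(traj, thresholds, min_phase = 2) {
  stopifnot(inherits(traj, "ttf_trajectory"))
  if (length(traj$times) < 2) stop("empty trajectory")
  ttfs <- colnames(traj$levels)
  stopifnot(all(ttfs %in% names(thresholds)), all(thresholds[ttfs] > 0))
  on <- sweep(traj$levels, 2, thresholds[ttfs], ">=")
  # integer-encode on-sets (bitmask) and translate only the distinct codes
  code <- as.integer(on %*% 2^(seq_along(ttfs) - 1))
  key_of <- vapply(0:(2^length(ttfs) - 1), function(cd)
    on_set_key(bitwAnd(cd, 2^(seq_along(ttfs) - 1)) > 0, ttfs), character(1))
  r <- rle(code)
  r$values <- key_of[r$values + 1L]
  ends <- cumsum(r$lengths)
  starts <- c(1, ends[-length(ends)] + 1)
  # refine each phase boundary by linear interpolation of the crossing TTF's
  # level through its threshold, so durations are not quantized to the grid
  bounds <- vapply(starts[-1], function(j) {
    flip <- which(on[j, ] != on[j - 1, ])
    if (!length(flip)) return(traj$times[j])
    tc <- vapply(flip, function(k) {
      y0 <- traj$levels[j - 1, k]; y1 <- traj$levels[j, k]
      if (y1 == y0) return(traj$times[j])
      traj$times[j - 1] + (thresholds[ttfs[k]] - y0) / (y1 - y0) *
        (traj$times[j] - traj$times[j - 1])
    }, numeric(1))
    min(max(mean(tc), traj$times[j - 1]), traj$times[j])
  }, numeric(1))
  ph <- data.frame(on_set = r$values,
                   start = c(traj$times[1], bounds),
                   end = c(bounds, traj$times[length(traj$times)]),
                   stringsAsFactors = FALSE)
  ph <- merge_short_phases(ph, min_phase)
  class(ph) <- c("ttf_phases", "data.frame")
  ph
}

merge_short_phases <- function(ph, min_phase) {
  repeat {
    if (nrow(ph) <= 1) break
    dur <- ph$end - ph$start
    short <- which(dur < min_phase)
    if (!length(short)) break
    i <- short[1]
    if (i == 1) {            # merge leading short phase into its successor
      ph$start[2] <- ph$start[1]
      ph <- ph[-1, , drop = FALSE]
    } else {                 # absorb into preceding phase
      ph$end[i - 1] <- ph$end[i]
      ph <- ph[-i, , drop = FALSE]
    }
    # re-merge adjacent equal on-sets
    keep <- c(TRUE, ph$on_set[-1] != ph$on_set[-nrow(ph)])
    if (!all(keep)) {
      grp <- cumsum(keep)
      ph <- data.frame(on_set = as.character(tapply(ph$on_set, grp, `[`, 1)),
                       start = as.numeric(tapply(ph$start, grp, min)),
                       end = as.numeric(tapply(ph$end, grp, max)),
                       stringsAsFactors = FALSE)
    }
    rownames(ph) <- NULL
  }
  rownames(ph) <- NULL
  ph
}

#' Default progeny identity map
#'
#' Maps each on-set occurring in consistent wild-type runs to the neuronal
#' identity it confers in the NB7-1 lineage. Hb-only and Hb+Kr co-expression
#' share the early "U1/U2" identity (so those two phases merge for duration
#' bookkeeping); Kr+Pdm marks the later-recognized GMC between the classic
#' Kr and Pdm windows.
#'
#' @return Named character vector: on-set key -> identity label.
#' @export
default_identity_map <- function() {
  setNames(c("none", "U1/U2", "U1/U2", "U3", "U4", "U4", "U5", "interneuron"),
           c("", "Hb", "Hb+Kr", "Kr", "Kr+Pdm", "Pdm", "Pdm+Cas", "Cas"))
}

#' Merge adjacent phases that confer the same neuronal identity
#'
#' A phase of Hb-only expression followed by Hb+Kr co-expression counts as a
#' single phase, since both lead to the same early fates; timing of the
#' internal transition is irrelevant for the lineage. Idempotent.
#'
#' @param phases A `ttf_phases` data frame.
#' @param identity_map Named vector, on-set key -> identity label.
#' @return A `ttf_phases` data frame with an extra `identity` column.
#' @export
merge_identity_phases <- function(phases, identity_map = default_identity_map()) {
  unmapped <- unique(phases$on_set)
  unmapped <- unmapped[is.na(match(unmapped, names(identity_map)))]
  if (length(unmapped))
    stop("on-set(s) without identity: ",
         paste(vapply(unmapped, function(k) if (k == "") "<none>" else k, ""),
               collapse = ", "))
  id <- unname(identity_map[match(phases$on_set, names(identity_map))])
  keep <- c(TRUE, id[-1] != id[-length(id)])
  grp <- cumsum(keep)
  out <- data.frame(on_set = as.character(tapply(phases$on_set, grp, `[`, 1)),
                    identity = as.character(tapply(id, grp, `[`, 1)),
                    start = as.numeric(tapply(phases$start, grp, min)),
                    end = as.numeric(tapply(phases$end, grp, max)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ttf_phases", "data.frame")
  out
}

#' Default genotype phenotype table
#'
#' Expected ordered on-set lists per genotype (NB7-1), encoding the reported
#' wild-type, mutant and misexpression expression sequences as they manifest
#' in this model. The hb-null expectation reflects the model's scope: Kr's
#' induction by a cascade-external factor is not modeled (Hb->Kr is its only
#' activating input), so in hb-null simulations Kr is absent and Pdm is
#' advanced by loss of its repressor, which is the experimentally observed
#' advance of Pdm. The table is a config file so other encodings can be
#' swapped in.
#'
#' @return A `ttf_phenotype_table`: named list; each element has
#'   `perturbation` and `expected` (character vector of on-set keys).
#' @export
default_phenotype_table <- function() {
  tab <- list(
    WT = list(perturbation = pert_none(),
              expected = c("Hb", "Hb+Kr", "Kr", "Kr+Pdm", "Pdm", "Pdm+Cas",
                           "Cas")),
    hb_del = list(perturbation = perturbation("deletion", "Hb"),
                  expected = c("Pdm", "Pdm+Cas", "Cas")),
    kr_del = list(perturbation = perturbation("deletion", "Kr"),
                  expected = c("Hb", "Pdm", "Pdm+Cas", "Cas")),
    pdm_del = list(perturbation = perturbation("deletion", "Pdm"),
                   expected = c("Hb", "Hb+Kr", "Kr", "Cas")),
    hb_const = list(perturbation = perturbation("constitutive", "Hb"),
                    expected = c("Hb", "Hb+Kr"))
  )
  structure(tab, class = "ttf_phenotype_table")
}

#' Read / write a phenotype table (YAML)
#' @param path File path.
#' @export
read_phenotype_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$genotypes) || !"WT" %in% names(cfg$genotypes))
    stop("phenotype table must contain a WT genotype")
  tab <- lapply(cfg$genotypes, function(g) {
    pk <- if (is.null(g$perturbation)) "none" else g$perturbation$kind
    list(perturbation = perturbation(pk, g$perturbation$target),
         expected = as.character(unlist(g$expected)))
  })
  structure(tab, class = "ttf_phenotype_table")
}

#' @rdname read_phenotype_table
#' @param table A `ttf_phenotype_table`.
#' @export
write_phenotype_table <- function(table, path) {
  yaml::write_yaml(list(genotypes = lapply(table, function(g) list(
    perturbation = list(kind = g$perturbation$kind,
                        target = g$perturbation$target),
    expected = as.list(g$expected)))), path)
  invisible(path)
}

#' Test phase sequences against a phenotype table
#'
#' A circuit is consistent iff, for every genotype, the ordered list of
#' non-empty on-sets equals the expected list (exact list equality; durations
#' ignored). Empty on-sets (gaps where no TTF is above threshold) are dropped
#' before comparison.
#'
#' @param phase_seqs Named list of `ttf_phases`, one per genotype; must cover
#'   every genotype in the table.
#' @param table A `ttf_phenotype_table`.
#' @return List: `consistent` flag; if inconsistent, `genotype` and
#'   `position` of the first mismatch.
#' @export
check_consistency <- function(phase_seqs, table = default_phenotype_table()) {
  missing <- setdiff(names(table), names(phase_seqs))
  if (length(missing))
    stop("phase sequences missing for genotype(s): ",
         paste(missing, collapse = ", "))
  for (g in names(table)) {
    got <- phase_seqs[[g]]$on_set
    got <- got[got != ""]
    exp <- table[[g]]$expected
    if (length(got) != length(exp) || any(got != exp)) {
      pos <- if (!length(got)) 1L else {
        k <- min(length(got), length(exp))
        d <- which(got[seq_len(k)] != exp[seq_len(k)])
        if (length(d)) d[1] else k + 1L
      }
      return(list(consistent = FALSE, genotype = g, position = pos))
    }
  }
  list(consistent = TRUE, genotype = NA_character_, position = NA_integer_)
}

#' Progeny identities at division times
#'
#' At each neuroblast division time, the progeny identity is the identity of
#' the set of TTFs whose level is >= the identity threshold at that instant
#' (ties count as on). An empty above-threshold set yields identity
#' `"none"`.
#'
#' @param traj A `ttf_trajectory`.
#' @param division_times Division times (min) within the simulated window;
#'   default every 45 min.
#' @param identity_map Named vector, on-set key -> identity.
#' @param identity_thresholds Named per-TTF thresholds (constant over time).
#' @return Character vector of identities, one per division.
#' @export
progeny_identities <- function(traj, division_times, identity_map,
                               identity_thresholds) {
  stopifnot(all(division_times >= min(traj$times)),
            all(division_times <= max(traj$times)))
  ttfs <- colnames(traj$levels)
  vapply(division_times, function(td) {
    i <- which.min(abs(traj$times - td))
    on <- traj$levels[i, ] >= identity_thresholds[ttfs]
    key <- on_set_key(on, ttfs)
    j <- match(key, names(identity_map))   # [""] indexing would return NA
    if (is.na(j)) stop("on-set without identity: ", key)
    unname(identity_map[j])
  }, character(1))
}
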