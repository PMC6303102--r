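#' Kinetic parameter sets
#'
#' A parameter set holds the 17 free kinetic parameters of one candidate
#' circuit: per-TTF production rates `beta_*` (conc/min), basal production
#' `beta0_Pdm`, `beta0_Cas` (conc/min), per-TTF degradation rates `alpha_*`
#' (1/min) and one regulation threshold `T_*` (conc) per threshold-bearing
#' interaction. Concentration units are arbitrary: dynamics depend only on
#' level-to-threshold ratios.
#'
#' @name ttf_params
NULL

param_names <- function(topology = build_default_topology()) {
  c(paste0("beta_", topology$ttfs), "beta0_Pdm", "beta0_Cas",
    paste0("alpha_", topology$ttfs), threshold_param_names(topology))
}

#' Construct and validate a parameter set
#'
#' @param x Named numeric vector with one entry per free parameter (see
#'   [param_names][sample_parameter_set] order: `beta_Hb ... T_CasPdm`).
#' @param topology Circuit topology the thresholds refer to.
#' @return Named numeric vector of class `ttf_params`.
#' @export
as_ttf_params <- function(x, topology = build_default_topology()) {
  nm <- param_names(topology)
  if (is.null(names(x)) || !all(nm %in% names(x)))
    stop("parameter set must be named and contain: ", paste(nm, collapse = ", "))
  x <- as.numeric(x[nm])
  names(x) <- nm
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all rates and thresholds must be strictly positive and finite")
  structure(x, class = "ttf_params")
}

#' Number of free parameters of a topology
#' @param topology A `ttf_topology`.
#' @return Integer count (17 for the default configuration).
#' @export
n_free_parameters <- function(topology = build_default_topology()) {
  length(param_names(topology))
}

#' Parameter ranges for the random screen
#'
#' Ranges for the log-uniform draw. Degradation rates span roughly two orders
#' of magnitude centred (geometrically) on 0.05 1/min, the rate implied by a
#' ~15 min protein half-life. Production and basal rates span 0.01-10 in
#' arbitrary concentration units. Regulation thresholds are drawn as ratios
#' of the source TTF's maximal level beta/alpha: repression thresholds in
#' 0.01-0.1 (targets de-repress when the repressor has decayed to 1-10% of
#' maximum, the estimate for Hb on Pdm), activation thresholds in 0.01-1
#' (an activator may need to accumulate anywhere up to its steady state,
#' which is what lets relay-driven circuits exist in the ensemble at all).
#' These defaults are reconstructed, not transcribed from a published table,
#' and live in a config file.
#'
#' @param topology A `ttf_topology`.
#' @return Data frame with columns `param`, `low`, `high`, `kind`
#'   (`"rate"` or `"threshold_ratio"`).
#' @export
default_ranges <- function(topology = build_default_topology()) {
  nm <- param_names(topology)
  kind <- ifelse(grepl("^T_", nm), "threshold_ratio",
                 ifelse(grepl("^alpha_", nm), "degradation", "production"))
  low  <- ifelse(kind == "threshold_ratio", 0.01,
                 ifelse(kind == "degradation", 0.005, 0.01))
  high <- ifelse(kind == "threshold_ratio", 0.1,
                 ifelse(kind == "degradation", 0.5, 10))
  # activation thresholds may sit anywhere up to the activator's steady state
  ints <- topology$interactions[topology$interactions$has_threshold, ]
  act <- paste0("T_", ints$source, ints$target)[ints$sign == "activation"]
  high[nm %in% act] <- 1
  data.frame(param = nm, low = low, high = high, kind = kind,
             stringsAsFactors = FALSE)
}

#' Ranges centred on a parameter set
#'
#' Builds a range table spanning `center/spread` to `center*spread` for every
#' free parameter, in absolute units (`kind = "rate"`, so thresholds are not
#' re-derived from ratios). Useful for local ensembles around a reference
#' circuit, e.g. demo pipelines and end-to-end recovery studies.
#'
#' @param params A `ttf_params` to centre on.
#' @param spread Multiplicative half-width (> 1).
#' @param topology A `ttf_topology`.
#' @return Ranges data frame as for [default_ranges()].
#' @export
ranges_around <- function(params, spread = 1.5,
                          topology = build_default_topology()) {
  stopifnot(spread > 1)
  nm <- param_names(topology)
  v <- unclass(params)[nm]
  data.frame(param = nm, low = v / spread, high = v * spread,
             kind = "rate", stringsAsFactors = FALSE, row.names = NULL)
}

#' Read / write screen parameter ranges (YAML)
#' @param path File path.
#' @export
read_ranges <- function(path) {
  cfg <- yaml::read_yaml(path)
  rng <- do.call(rbind, lapply(cfg$ranges, function(x)
    data.frame(param = x$param, low = x$low, high = x$high, kind = x$kind,
               stringsAsFactors = FALSE)))
  validate_ranges(rng)
  rng
}

#' @rdname read_ranges
#' @param ranges Ranges data frame as from [default_ranges()].
#' @export
write_ranges <- function(ranges, path) {
  validate_ranges(ranges)
  yaml::write_yaml(list(ranges = lapply(seq_len(nrow(ranges)), function(i)
    list(param = ranges$param[i], low = ranges$low[i], high = ranges$high[i],
         kind = ranges$kind[i]))), path)
  invisible(path)
}

validate_ranges <- function(ranges) {
  stopifnot(is.data.frame(ranges),
            all(c("param", "low", "high", "kind") %in% names(ranges)))
  if (any(ranges$low <= 0) || any(ranges$high <= 0))
    stop("range bounds must be strictly positive")
  if (any(ranges$low > ranges$high)) stop("range low must be <= high")
  invisible(ranges)
}

log_uniform <- function(n, low, high) {
  exp(runif(n, log(low), log(high)))
}

#' Draw one random parameter set
#'
#' Each free parameter is drawn independently log-uniformly within its range.
#' Threshold parameters are drawn as ratios and converted to absolute
#' concentrations against the source TTF's maximal level `beta/alpha` of the
#' same draw, confining thresholds to the configured fraction (default 1-10%)
#' of maximal expression.
#'
#' @param ranges Ranges data frame (see [default_ranges()]).
#' @param topology A `ttf_topology`.
#' @return A `ttf_params` vector.
#' @export
sample_parameter_set <- function(ranges = default_ranges(topology),
                                 topology = build_default_topology()) {
  validate_ranges(ranges)
  nm <- param_names(topology)
  missing <- setdiff(nm, ranges$param)
  if (length(missing))
    stop("ranges missing parameters: ", paste(missing, collapse = ", "))
  r <- ranges[match(nm, ranges$param), ]
  x <- log_uniform(nrow(r), r$low, r$high)
  names(x) <- nm
  # convert threshold ratios to absolute concentrations
  ints <- topology$interactions[topology$interactions$has_threshold, ]
  tn <- threshold_param_names(topology)
  for (i in seq_along(tn)) {
    if (r$kind[match(tn[i], r$param)] == "threshold_ratio") {
      src <- ints$source[i]
      x[tn[i]] <- x[tn[i]] * x[paste0("beta_", src)] / x[paste0("alpha_", src)]
    }
  }
  as_ttf_params(x, topology)
}

#' Serialize parameter sets to/from CSV rows
#'
#' One row per parameter set, stable column order `beta_Hb, ..., T_CasPdm`.
#'
#' @param params A `ttf_params` or a list of them.
#' @param path CSV path.
#' @param topology A `ttf_topology`.
#' @export
write_parameter_sets <- function(params, path,
                                 topology = build_default_topology()) {
  if (inherits(params, "ttf_params")) params <- list(params)
  m <- do.call(rbind, lapply(params, function(p) unclass(p)[param_names(topology)]))
  write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameter_sets
#' @export
read_parameter_sets <- function(path, topology = build_default_topology()) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i)
    as_ttf_params(unlist(df[i, param_names(topology)]), topology))
}

#' Maximal expression levels implied by a parameter set
#'
#' `(beta + beta0) / alpha` per TTF; the scale against which "on" and
#' identity thresholds are set.
#'
#' @param params A `ttf_params`.
#' @param topology A `ttf_topology`.
#' @return Named numeric vector per TTF.
#' @export
max_levels <- function(params, topology = build_default_topology()) {
  ttfs <- topology$ttfs
  beta <- unclass(params)[paste0("beta_", ttfs)]
  beta0 <- setNames(numeric(length(ttfs)), ttfs)
  for (tf in ttfs) {
    b0 <- paste0("beta0_", tf)
    if (b0 %in% names(params)) beta0[tf] <- params[[b0]]
  }
  setNames((beta + beta0) / unclass(params)[paste0("alpha_", ttfs)], ttfs)
}

#' Per-TTF "on" thresholds for phase calling
#'
#' @param params Unperturbed `ttf_params` (thresholds are always taken from
#'   the wild-type set, also when discretizing perturbed trajectories).
#' @param topology A `ttf_topology`.
#' @param constants Structural constants ([model_constants()]).
#' @param fraction Fraction of maximal level; defaults to
#'   `constants$on_fraction`.
#' @return Named numeric vector per TTF.
#' @export
on_thresholds <- function(params, topology = build_default_topology(),
                          constants = model_constants(),
                          fraction = constants$on_fraction) {
  fraction * max_levels(params, topology)
}
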