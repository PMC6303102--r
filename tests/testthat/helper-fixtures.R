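# Shared helpers: hand-built parameter sets and toy trajectories.

# A fully named parameter set from a few scalars; thresholds default to
# `thr_frac` of the source TTF's beta/alpha.
make_params <- function(beta = c(Hb = 1, Kr = 1, Pdm = 1, Cas = 1),
                        beta0 = c(Pdm = 0.3, Cas = 0.3),
                        alpha = c(Hb = 0.05, Kr = 0.05, Pdm = 0.05,
                                  Cas = 0.05),
                        thr_frac = 0.05,
                        topology = build_default_topology()) {
  x <- c(setNames(beta[topology$ttfs], paste0("beta_", topology$ttfs)),
         beta0_Pdm = unname(beta0["Pdm"]), beta0_Cas = unname(beta0["Cas"]),
         setNames(alpha[topology$ttfs], paste0("alpha_", topology$ttfs)))
  ints <- topology$interactions[topology$interactions$has_threshold, ]
  for (i in seq_len(nrow(ints))) {
    src <- ints$source[i]
    x[paste0("T_", src, ints$target[i])] <-
      thr_frac * beta[src] / alpha[src]
  }
  as_ttf_params(x, topology)
}

# Square-wave toy trajectory: given a list of (ttf-levels over segments),
# build a ttf_trajectory on a 1-min grid.
toy_trajectory <- function(segments, horizon = 100,
                           ttfs = c("Hb", "Kr", "Pdm", "Cas")) {
  times <- seq(0, horizon, by = 1)
  lev <- matrix(0, length(times), length(ttfs),
                dimnames = list(NULL, ttfs))
  for (seg in segments) {
    sel <- times >= seg$from & times < seg$to
    for (tf in names(seg$levels)) lev[sel, tf] <- seg$levels[[tf]]
  }
  structure(list(times = times, levels = lev, params_id = "toy"),
            class = "ttf_trajectory")
}

# Deterministic RNG scope
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(code)
}
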