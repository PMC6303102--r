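#' In-silico perturbations
#'
#' One perturbation at a time: `deletion` zeroes the target TTF's production
#' and basal rates; `constitutive` fixes every term regulating the target's
#' production at 1 (including the external Hb input gate); `remove_link`
#' fixes a single interaction's regulation term at 1; `none` is the identity.
#'
#' @param kind One of `"none"`, `"deletion"`, `"constitutive"`,
#'   `"remove_link"`.
#' @param target TTF name (deletion/constitutive) or interaction id such as
#'   `"Hb-|Pdm"` (remove_link).
#' @return A `ttf_perturbation`.
#' @export
perturbation <- function(kind = c("none", "deletion", "constitutive",
                                  "remove_link"), target = NULL) {
  kind <- match.arg(kind)
  if (kind == "none") {
    if (!is.null(target)) stop("perturbation 'none' takes no target")
  } else if (is.null(target) || length(target) != 1L) {
    stop("perturbation '", kind, "' needs exactly one target")
  }
  structure(list(kind = kind, target = target), class = "ttf_perturbation")
}

#' @rdname perturbation
#' @export
pert_none <- function() perturbation("none")

#' @export
print.ttf_perturbation <- function(x, ...) {
  cat("perturbation:", x$kind,
      if (x$kind != "none") paste0("(", x$target, ")"), "\n")
  invisible(x)
}

#' Apply a perturbation to (params, topology)
#'
#' Returns the modified parameter set and the list of interactions whose
#' regulation terms remain active; inputs are unmodified. This is the single
#' place where the perturbation semantics live; [rhs()] and
#' [simulate_circuit()] both consume its output.
#'
#' @param params A `ttf_params`.
#' @param topology A `ttf_topology`.
#' @param pert A `ttf_perturbation`.
#' @return List with `params`, `active` (logical per interaction row),
#'   `gated` (logical per TTF: external-input gate still applies).
#' @export
apply_perturbation <- function(params, topology, pert = pert_none()) {
  stopifnot(inherits(pert, "ttf_perturbation"))
  ints <- topology$interactions
  active <- rep(TRUE, nrow(ints))
  gated <- topology$ttfs == "Hb"   # only Hb production is externally gated
  names(gated) <- topology$ttfs
  p <- unclass(params)
  if (pert$kind == "deletion") {
    tf <- pert$target
    if (!tf %in% topology$ttfs) stop("unknown TTF: ", tf)
    p[paste0("beta_", tf)] <- 0
    b0 <- paste0("beta0_", tf)
    if (b0 %in% names(p)) p[b0] <- 0
  } else if (pert$kind == "constitutive") {
    tf <- pert$target
    if (!tf %in% topology$ttfs) stop("unknown TTF: ", tf)
    active[ints$target == tf] <- FALSE
    gated[tf] <- FALSE
  } else if (pert$kind == "remove_link") {
    hit <- which(ints$id == pert$target)
    if (!length(hit)) stop("unknown interaction: ", pert$target)
    active[hit] <- FALSE
  }
  list(params = p, active = active, gated = gated)
}

hill_act_r <- function(y, T, n) {
  z <- (pmax(y, 0) / T)^n
  z / (1 + z)
}

#' Right-hand side of the TTF circuit ODEs
#'
#' Per TTF X: `dX/dt = (beta_X * gate_X(t) * prod A(Y;T) + beta0_X) *
#' prod R(Y;T) - alpha_X * X` with Hill activation
#' `A(Y;T) = (Y/T)^n / (1 + (Y/T)^n)` and repression `R = 1 - A`. Hb has no
#' upstream activator; its production is gated by the external input
#' indicator `t < t_off`. Dimensionless regulation terms lie in `[0, 1)` and
#' depend only on `Y/T` ratios. Pure R reference implementation; the compiled
#' integrator evaluates the identical expression.
#'
#' @param levels Named (or topology-ordered) non-negative TTF levels.
#' @param t Time (min).
#' @param params A `ttf_params`.
#' @param topology A `ttf_topology`.
#' @param pert A `ttf_perturbation`.
#' @param constants Structural constants.
#' @return Named derivative vector.
#' @export
rhs <- function(levels, t, params, topology = build_default_topology(),
                pert = pert_none(), constants = model_constants()) {
  ap <- apply_perturbation(params, topology, pert)
  rhs_applied(levels, t, ap, topology, constants)
}

rhs_applied <- function(levels, t, ap, topology, constants) {
  ttfs <- topology$ttfs
  x <- setNames(as.numeric(levels), ttfs)
  p <- ap$params
  ints <- topology$interactions
  n <- constants$hill_n
  act <- setNames(rep(1, length(ttfs)), ttfs)
  rep_ <- act
  for (i in seq_len(nrow(ints))) {
    if (!ap$active[i]) next
    a <- hill_act_r(x[ints$source[i]], p[paste0("T_", ints$source[i],
                                                ints$target[i])], n)
    if (ints$sign[i] == "activation") act[ints$target[i]] <- act[ints$target[i]] * a
    else rep_[ints$target[i]] <- rep_[ints$target[i]] * (1 - a)
  }
  beta <- p[paste0("beta_", ttfs)]
  beta0 <- setNames(numeric(length(ttfs)), ttfs)
  for (tf in ttfs) {
    b0 <- paste0("beta0_", tf)
    if (b0 %in% names(p)) beta0[tf] <- p[b0]
  }
  gate <- ifelse(ap$gated, as.numeric(t < constants$t_off), 1)
  alpha <- p[paste0("alpha_", ttfs)]
  setNames((beta * gate * act + beta0) * rep_ - alpha * x, ttfs)
}

# Flatten a perturbed model into the argument set of the compiled integrator.
model_spec <- function(params, topology, pert, constants) {
  ap <- apply_perturbation(params, topology, pert)
  ttfs <- topology$ttfs
  p <- ap$params
  ints <- topology$interactions[ap$active, , drop = FALSE]
  beta0 <- setNames(numeric(length(ttfs)), ttfs)
  for (tf in ttfs) {
    b0 <- paste0("beta0_", tf)
    if (b0 %in% names(p)) beta0[tf] <- p[b0]
  }
  list(
    beta = unname(p[paste0("beta_", ttfs)]),
    beta0 = unname(beta0),
    alpha = unname(p[paste0("alpha_", ttfs)]),
    gated = as.integer(ap$gated),
    etype = as.integer(ints$sign == "repression"),
    esrc = match(ints$source, ttfs) - 1L,
    etgt = match(ints$target, ttfs) - 1L,
    eT = unname(p[paste0("T_", ints$source, ints$target)])
  )
}

#' Simulate a TTF circuit
#'
#' Integrates the circuit ODEs from zero initial conditions on
#' `[0, horizon]` with a 1-min output grid. The default engine is the
#' package's compiled fixed-step RK4 (the screen performs ~1e5 solves); the
#' `"lsoda"` engine routes the identical right-hand side through
#' [deSolve::ode()] and is used for cross-checks.
#'
#' @param params A `ttf_params`.
#' @param topology A `ttf_topology`.
#' @param pert A `ttf_perturbation`.
#' @param constants Structural constants.
#' @param engine `"rk4"` (compiled) or `"lsoda"` (deSolve).
#' @param params_id Optional provenance tag carried on the trajectory.
#' @return A `ttf_trajectory`: list with `times` (min), `levels` (matrix,
#'   one column per TTF, non-negative), `params_id`.
#' @export
simulate_circuit <- function(params, topology = build_default_topology(),
                             pert = pert_none(),
                             constants = model_constants(),
                             engine = c("rk4", "lsoda"), params_id = NA) {
  engine <- match.arg(engine)
  if (pert$kind == "deletion" || pert$kind == "constitutive") {
    # reject stacked perturbations encoded as already-perturbed params
    if (pert$kind == "constitutive" &&
        params[[paste0("beta_", pert$target)]] == 0)
      stop("cannot apply 'constitutive' to a deleted TTF (one perturbation at a time)")
  }
  times <- seq(0, constants$horizon, by = constants$dt_out)
  if (engine == "rk4") {
    sp <- model_spec(params, topology, pert, constants)
    lev <- rk4_simulate(sp$beta, sp$beta0, sp$alpha, sp$gated,
                        constants$t_off, constants$hill_n,
                        sp$etype, sp$esrc, sp$etgt, sp$eT,
                        times, constants$substeps,
                        numeric(length(topology$ttfs)))
  } else {
    ap <- apply_perturbation(params, topology, pert)
    f <- function(t, y, parms) list(unname(rhs_applied(y, t, ap, topology,
                                                       constants)))
    sol <- try(deSolve::ode(
      y = setNames(numeric(length(topology$ttfs)), topology$ttfs),
      times = times, func = f, parms = NULL, method = "lsoda",
      events = list(func = function(t, y, parms) y, time = constants$t_off),
      rtol = 1e-8, atol = 1e-10), silent = TRUE)
    if (inherits(sol, "try-error"))
      stop("ODE solver failure for params_id=", params_id, ": ",
           attr(sol, "condition")$message)
    lev <- unname(as.matrix(sol[, -1, drop = FALSE]))
  }
  if (any(!is.finite(lev)))
    stop("ODE solver failure (non-finite levels) for params_id=", params_id)
  lev[lev < 0 & lev > -1e-9] <- 0
  lev[lev < 0] <- 0
  colnames(lev) <- topology$ttfs
  structure(list(times = times, levels = lev, params_id = params_id),
            class = "ttf_trajectory")
}

#' @export
print.ttf_trajectory <- function(x, ...) {
  cat("TTF trajectory: ", ncol(x$levels), " species, t = [",
      min(x$times), ", ", max(x$times), "] min, step ",
      x$times[2] - x$times[1], " min\n", sep = "")
  invisible(x)
}
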