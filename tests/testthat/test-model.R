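topo <- build_default_topology()
cons <- model_constants()

test_that("rhs implements the Hill-product form", {
  p <- make_params()
  # pure decay: all production off
  p0 <- unclass(p)
  p0[grepl("^beta", names(p0))] <- 1e-300
  p0 <- as_ttf_params(p0, topo)
  x <- c(Hb = 2, Kr = 3, Pdm = 1, Cas = 5)
  d <- rhs(x, t = 10, p0, topo)
  expect_equal(unname(d), unname(-0.05 * x), tolerance = 1e-6)

  # half-saturation: Hb exactly at T_HbKr makes Kr's activation term 1/2
  x2 <- c(Hb = unname(p["T_HbKr"]), Kr = 0, Pdm = 0, Cas = 0)
  d2 <- rhs(x2, t = 10, p, topo)
  expect_equal(unname(d2["Kr"]), unname(p["beta_Kr"]) * 0.5, tolerance = 1e-12)

  # Hb steady state during the input window
  xs <- c(Hb = unname(p["beta_Hb"] / p["alpha_Hb"]), Kr = 0, Pdm = 0, Cas = 0)
  expect_equal(unname(rhs(xs, t = 1, p, topo)["Hb"]), 0, tolerance = 1e-12)
  # after shut-off, Hb decays
  expect_lt(rhs(xs, t = cons$t_off + 1, p, topo)["Hb"], 0)
})

test_that("perturbation semantics: deletion, constitutive, link removal", {
  p <- make_params()
  # deletion: zero production + zero initial condition => flat zero
  tr <- simulate_circuit(p, topo, perturbation("deletion", "Hb"), cons)
  expect_true(all(tr$levels[, "Hb"] == 0))

  # constitutive: monotone relaxation to (beta+beta0)/alpha
  trc <- simulate_circuit(p, topo, perturbation("constitutive", "Pdm"), cons)
  pdm <- trc$levels[, "Pdm"]
  expect_true(all(diff(pdm) > -1e-9))
  ss <- (p["beta_Pdm"] + p["beta0_Pdm"]) / p["alpha_Pdm"]
  expect_equal(unname(pdm[length(pdm)]), unname(ss), tolerance = 1e-3)

  # remove_link(Hb-|Pdm): Pdm derivative independent of Hb level
  ap <- apply_perturbation(p, topo, perturbation("remove_link", "Hb-|Pdm"))
  d_lo <- nbtimer:::rhs_applied(c(Hb = 0.1, Kr = 1, Pdm = 1, Cas = 0), 10,
                                ap, topo, cons)
  d_hi <- nbtimer:::rhs_applied(c(Hb = 50, Kr = 1, Pdm = 1, Cas = 0), 10,
                                ap, topo, cons)
  expect_equal(d_lo["Pdm"], d_hi["Pdm"], tolerance = 1e-12)
  # with the link intact they differ
  ap0 <- apply_perturbation(p, topo, pert_none())
  d0_lo <- nbtimer:::rhs_applied(c(Hb = 0.1, Kr = 1, Pdm = 1, Cas = 0), 10,
                                 ap0, topo, cons)
  d0_hi <- nbtimer:::rhs_applied(c(Hb = 50, Kr = 1, Pdm = 1, Cas = 0), 10,
                                 ap0, topo, cons)
  expect_gt(abs(d0_lo["Pdm"] - d0_hi["Pdm"]), 1e-6)

  # identity perturbation leaves everything unchanged
  ap_none <- apply_perturbation(p, topo, pert_none())
  expect_equal(ap_none$params, unclass(p))
  expect_true(all(ap_none$active))

  # unknown targets rejected
  expect_error(apply_perturbation(p, topo, perturbation("deletion", "Svp")),
               "unknown TTF")
  expect_error(apply_perturbation(p, topo,
                                  perturbation("remove_link", "Hb->Cas")),
               "unknown interaction")
  # one perturbation at a time: constitutive on a deleted TTF is rejected
  pdel <- unclass(p); pdel["beta_Kr"] <- 0
  expect_error(as_ttf_params(pdel), "positive")
})

test_that("single-species simulation matches the closed form", {
  p <- make_params()
  cc <- model_constants(t_off = 1e6, horizon = 200)
  tr <- simulate_circuit(p, topo, constants = cc)
  expected <- p["beta_Hb"] / p["alpha_Hb"] *
    (1 - exp(-p["alpha_Hb"] * tr$times))
  err <- abs(tr$levels[, "Hb"] - expected) / pmax(expected, 1e-12)
  expect_lt(max(err[-1]), 1e-6)
})

test_that("compiled RK4 agrees with lsoda on random circuits", {
  for (s in 1:3) {
    with_seed(100 + s, {
      p <- sample_parameter_set()
      a <- simulate_circuit(p, topo, constants = cons, engine = "rk4")
      b <- simulate_circuit(p, topo, constants = cons, engine = "lsoda")
      scale <- max(a$levels)
      # fixed-step RK4 vs adaptive lsoda across sharp Hill-4 switching;
      # well below the level scale that phase calling resolves
      expect_lt(max(abs(a$levels - b$levels)) / scale, 5e-4)
    })
  }
})

test_that("trajectories are non-negative for random parameter draws", {
  with_seed(7, {
    for (i in 1:20) {
      p <- sample_parameter_set()
      tr <- simulate_circuit(p, topo, constants = cons)
      expect_true(all(tr$levels >= 0))
      expect_true(all(diff(tr$times) > 0))
    }
  })
})

test_that("dynamics are invariant to joint rescaling of production and thresholds", {
  with_seed(11, {
    p <- sample_parameter_set()
    pscaled <- unclass(p)
    sc <- grepl("^beta|^T_", names(pscaled))
    pscaled[sc] <- pscaled[sc] * 37.5
    pscaled <- as_ttf_params(pscaled, topo)
    thr <- on_thresholds(p, topo, cons)
    thr2 <- on_thresholds(pscaled, topo, cons)
    ph1 <- trajectory_to_phases(simulate_circuit(p, topo, constants = cons),
                                thr, cons$min_phase)
    ph2 <- trajectory_to_phases(simulate_circuit(pscaled, topo,
                                                 constants = cons),
                                thr2, cons$min_phase)
    expect_equal(ph1$on_set, ph2$on_set)
    expect_equal(ph1$start, ph2$start, tolerance = 1e-6)
  })
})
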