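test_that("induction time requires a sustained upcrossing", {
  # monotone rise crossing threshold at t = 120
  ramp <- toy_trajectory(list(list(from = 120, to = 301,
                                   levels = list(Pdm = 10))), horizon = 300)
  expect_equal(induction_time(ramp, "Pdm", 5), 120)
  # 5-min transient at t = 10 is discounted; sustained rise at 150 wins
  tran <- toy_trajectory(list(
    list(from = 10, to = 15, levels = list(Pdm = 10)),
    list(from = 150, to = 301, levels = list(Pdm = 10))), horizon = 300)
  expect_equal(induction_time(tran, "Pdm", 5, sustain = 10), 150)
  # flat zero: never induced
  expect_identical(induction_time(toy_trajectory(list(), horizon = 300),
                                  "Pdm", 5), NOT_INDUCED)
})

test_that("induction shift formula, capping, and error on inconsistent WT", {
  expect_equal(delta_t_ind(100, 200)$delta_pct, -50)
  expect_false(delta_t_ind(100, 200)$capped)
  expect_equal(delta_t_ind(200, 200)$delta_pct, 0)
  capped <- delta_t_ind(NOT_INDUCED, 200, horizon = 400)
  expect_true(capped$capped)
  expect_equal(capped$delta_pct, 100)
  expect_error(delta_t_ind(100, NOT_INDUCED), "consistent")
})

test_that("link removal of the relay delays Pdm on the reference circuit", {
  ref <- fixture_circuit("consistent")
  sh <- induction_shifts(ref)
  expect_true(is.finite(sh$t_wt_Pdm))
  # removing Kr->Pdm (the relay into Pdm) cannot advance Pdm induction
  expect_gte(sh$pdm_rm_relay, 0)
  # removing Hb-|Pdm (the decay gate) cannot delay Pdm induction
  expect_lte(sh$pdm_rm_decay, 0)
})

mk_records <- function(df) {
  df$consistent <- rep(1, nrow(df))
  df$failed <- rep(0, nrow(df))
  df$params_id <- seq_len(nrow(df))
  df
}

test_that("significance scores normalize by the ensemble maximum", {
  rec <- mk_records(data.frame(
    pdm_rm_decay = c(0, -50, -100), cas_rm_decay = c(0, 25, 50),
    pdm_rm_relay = c(0, 10, 20), cas_rm_relay = c(0, 5, 10)))
  out <- significance_scores(rec)
  # zero shifts give zero significance
  expect_equal(out$decay_significance[1], 0)
  expect_equal(out$relay_significance[1], 0)
  # the record attaining the ensemble max on both components scores 100
  expect_equal(out$decay_significance[3], 100)
  expect_equal(out$relay_significance[3], 100)
  expect_equal(out$decay_significance[2], 50)
  expect_error(significance_scores(mk_records(data.frame(
    pdm_rm_decay = numeric(0), cas_rm_decay = numeric(0),
    pdm_rm_relay = numeric(0), cas_rm_relay = numeric(0)))), "consistent")
})

test_that("significance uses link shifts only; deletion sensitivity uses deletions only", {
  base <- data.frame(
    pdm_rm_decay = c(-50, -20), cas_rm_decay = c(-30, -10),
    pdm_rm_relay = c(5, 40), cas_rm_relay = c(2, 30),
    pdm_del_hb = c(-60, -25), pdm_del_kr = c(3, 45),
    pdm_del_hb_capped = FALSE, pdm_del_kr_capped = FALSE,
    cas_del_kr = c(-20, -5), cas_del_pdm = c(4, 35))
  rec <- mk_records(base)
  s1 <- significance_scores(rec)
  # mutating deletion columns must not move the significance coordinates
  rec2 <- rec
  rec2$pdm_del_hb <- rec2$pdm_del_hb * 10
  s2 <- significance_scores(rec2)
  expect_equal(s1$decay_significance, s2$decay_significance)
  expect_equal(s1$relay_significance, s2$relay_significance)
  # and mutating link columns must not move the deletion coordinates
  d1 <- deletion_sensitivity(rec)
  rec3 <- rec
  rec3$pdm_rm_decay <- rec3$pdm_rm_decay * 10
  d3 <- deletion_sensitivity(rec3)
  expect_equal(d1$hb_deletion_shift, d3$hb_deletion_shift)
  expect_equal(d1$kr_deletion_shift, d3$kr_deletion_shift)
  # insensitive record sits at the origin
  rec0 <- mk_records(data.frame(
    pdm_del_hb = 0, pdm_del_kr = 0, pdm_del_hb_capped = FALSE,
    pdm_del_kr_capped = FALSE))
  expect_equal(deletion_sensitivity(rec0)$hb_deletion_shift, 0)
})

test_that("deletion-vs-link correlations handle identity and degenerate cases", {
  n <- 12
  x <- seq(-60, -5, length.out = n)
  rec <- mk_records(data.frame(
    pdm_del_hb = x, pdm_rm_decay = x,          # identical by construction
    pdm_del_kr = seq_len(n), pdm_rm_relay = 7, # degenerate variance
    cas_del_kr = x, cas_rm_decay = rev(x),
    cas_del_pdm = seq_len(n), cas_rm_relay = seq_len(n)^2,
    robustness_score = rep(c(90, 10), n / 2)))
  out <- deletion_vs_link_correlation(rec)
  expect_equal(out$r_all[out$pair == "pdm_hb"], 1)
  expect_true(is.na(out$r_all[out$pair == "pdm_kr"]))
  expect_equal(out$n_robust[1], 6)
  expect_error(deletion_vs_link_correlation(rec[1:5, ]), "at least 10")
})

test_that("density maps conserve counts and mark empty bins as absent", {
  dm <- density_map(c(10), c(90), bins = 20)
  expect_equal(sum(dm$counts, na.rm = TRUE), 1)
  expect_equal(sum(!is.na(dm$counts)), 1)
  with_seed(4, {
    x <- runif(200, 0, 100); y <- runif(200, 0, 100)
    dm2 <- density_map(x, y, values = rep(5, 200))
    expect_equal(sum(dm2$counts, na.rm = TRUE), 200)
    expect_true(all(dm2$means[!is.na(dm2$means)] == 5))
  })
})
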