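#!/usr/bin/env Rscript
# Mints the fixture circuits frozen in inst/extdata/fixture_circuits.csv.
#
# Procedure: a default-range screen locates consistent circuits. The
# "consistent" reference is its first consistent draw. Among the
# stage-compatible consistent circuits — WT Pdm induction inside S11E
# (100-160 min) and WT Cas induction after 160 min on the default stage
# table, so the induction-stage caller is well-posed for data generated
# from them — the top scorer seeds a local screen (ranges +/-1.4-fold),
# whose stage-compatible members reach robustness scores well above the
# robust cutoff; the two top scorers become "robust" and "decay_dominant"
# (decay-dominant by construction in this model). A relay-dominant fixture
# is not shipped: no consistent circuit with relay > decay significance
# was found (0 of 476 in 3e5 default-range draws).
#
# Runtime: the global screen dominates (~35 min at n = 3e5 on one CPU).

library(nbtimer)

n_global <- 3e5
seed_global <- 202
seed_local <- 402

topo <- build_default_topology()
rec <- run_screen(n_global, seed = seed_global, verbose = TRUE,
                  chunk = 50000)
rec <- score_records(rec)
idx <- which(rec$consistent == 1 & rec$failed == 0)
stopifnot(length(idx) > 0)

first_i <- idx[which.min(rec$params_id[idx])]
p_cons <- nbtimer:::record_params(rec, first_i)

compat <- function(r, i) r$t_ind_Pdm[i] > 100 & r$t_ind_Pdm[i] < 160 &
  r$t_ind_Cas[i] > 160 & r$t_ind_Cas[i] < 340
ok <- idx[compat(rec, idx)]
seed_p <- nbtimer:::record_params(rec, ok[which.max(rec$robustness_score[ok])])

loc <- run_screen(1500, ranges = ranges_around(seed_p, 1.4),
                  seed = seed_local)
li <- which(loc$consistent == 1 & compat(loc, seq_len(nrow(loc))))
loc <- score_records(loc)
ordl <- li[order(-loc$robustness_score[li])]
p_rob <- nbtimer:::record_params(loc, ordl[1])
p_dd <- nbtimer:::record_params(loc, ordl[2])
stopifnot(robustness_score(p_rob) > 80, robustness_score(p_dd) > 80)

df <- rbind(
  data.frame(name = "consistent", seed = seed_global,
             params_id = rec$params_id[first_i], t(unclass(p_cons))),
  data.frame(name = "robust", seed = seed_local,
             params_id = loc$params_id[ordl[1]], t(unclass(p_rob))),
  data.frame(name = "decay_dominant", seed = seed_local,
             params_id = loc$params_id[ordl[2]], t(unclass(p_dd))))
write.csv(df, "inst/extdata/fixture_circuits.csv", row.names = FALSE)
cat("fixtures written\n")
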