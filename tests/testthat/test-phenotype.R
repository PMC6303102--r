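thr_toy <- c(Hb = 5, Kr = 5, Pdm = 5, Cas = 5)

test_that("trajectory discretization handles toy and degenerate cases", {
  # all levels below thresholds: single empty phase
  flat <- toy_trajectory(list(), horizon = 50)
  ph <- trajectory_to_phases(flat, thr_toy)
  expect_equal(nrow(ph), 1)
  expect_equal(ph$on_set, "")

  # square wave: Hb high then Kr high
  sq <- toy_trajectory(list(
    list(from = 0, to = 40, levels = list(Hb = 10)),
    list(from = 40, to = 101, levels = list(Kr = 10))))
  ph <- trajectory_to_phases(sq, thr_toy)
  expect_equal(ph$on_set[ph$on_set != ""], c("Hb", "Kr"))

  # sub-min_phase blip is absorbed
  blip <- toy_trajectory(list(
    list(from = 0, to = 50, levels = list(Hb = 10)),
    list(from = 20, to = 21, levels = list(Hb = 10, Pdm = 10)),
    list(from = 50, to = 101, levels = list(Kr = 10))))
  ph <- trajectory_to_phases(blip, thr_toy, min_phase = 2)
  expect_false("Hb+Pdm" %in% ph$on_set)

  expect_error(trajectory_to_phases(
    structure(list(times = 0, levels = matrix(0, 1, 4,
                                              dimnames = list(NULL, names(thr_toy))),
                   params_id = NA), class = "ttf_trajectory"), thr_toy),
    "empty")
})

test_that("identity merging joins same-fate phases and is idempotent", {
  ph <- structure(data.frame(
    on_set = c("Hb", "Hb+Kr", "Kr", "Kr+Pdm", "Pdm", "Pdm+Cas", "Cas"),
    start = c(0, 40, 60, 80, 100, 150, 170),
    end = c(40, 60, 80, 100, 150, 170, 400),
    stringsAsFactors = FALSE), class = c("ttf_phases", "data.frame"))
  m <- merge_identity_phases(ph)
  # Hb-only followed by Hb+Kr is a single phase (same early fates)
  expect_equal(m$identity[1], "U1/U2")
  expect_equal(m$start[1], 0)
  expect_equal(m$end[1], 60)
  # Kr+Pdm and Pdm share the U4 fate in the default map
  expect_equal(sum(m$identity == "U4"), 1)
  expect_equal(m$end[m$identity == "U4"], 150)
  # idempotent
  expect_equal(merge_identity_phases(m)$start, m$start)

  # three consecutive same-identity phases collapse to one
  ph3 <- structure(data.frame(on_set = c("Kr+Pdm", "Pdm", "Kr+Pdm"),
                              start = c(0, 10, 30), end = c(10, 30, 50),
                              stringsAsFactors = FALSE),
                   class = c("ttf_phases", "data.frame"))
  m3 <- merge_identity_phases(ph3)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$end - m3$start, 50)

  # unmapped on-set is an error naming the set
  ph_bad <- structure(data.frame(on_set = "Hb+Cas", start = 0, end = 10,
                                 stringsAsFactors = FALSE),
                      class = c("ttf_phases", "data.frame"))
  expect_error(merge_identity_phases(ph_bad), "Hb\\+Cas")
})

test_that("consistency is exact sequence equality, durations ignored", {
  tab <- default_phenotype_table()
  mk <- function(sets, scale = 1) {
    n <- length(sets)
    structure(data.frame(on_set = sets, start = scale * (seq_len(n) - 1) * 10,
                         end = scale * seq_len(n) * 10,
                         stringsAsFactors = FALSE),
              class = c("ttf_phases", "data.frame"))
  }
  seqs <- lapply(tab, function(g) mk(g$expected))
  expect_true(check_consistency(seqs, tab)$consistent)

  # durations rescaled x3: still consistent (only the sequence counts)
  seqs3 <- lapply(tab, function(g) mk(g$expected, scale = 3))
  expect_true(check_consistency(seqs3, tab)$consistent)

  # missing {Pdm,Cas} phase in WT: inconsistent at WT
  wt_sets <- tab$WT$expected
  seqs_bad <- seqs
  seqs_bad$WT <- mk(wt_sets[wt_sets != "Pdm+Cas"])
  res <- check_consistency(seqs_bad, tab)
  expect_false(res$consistent)
  expect_equal(res$genotype, "WT")

  # empty on-sets (gaps) are ignored in the comparison
  seqs_gap <- seqs
  seqs_gap$WT <- mk(c("", tab$WT$expected))
  expect_true(check_consistency(seqs_gap, tab)$consistent)

  expect_error(check_consistency(seqs[-1], tab), "WT")
})

test_that("progeny identities read the trajectory at division times", {
  sq <- toy_trajectory(list(
    list(from = 0, to = 40, levels = list(Hb = 10)),
    list(from = 40, to = 101, levels = list(Kr = 10))))
  ids <- progeny_identities(sq, c(20, 65), default_identity_map(), thr_toy)
  expect_equal(ids, c("U1/U2", "U3"))
  # level exactly at threshold counts as on
  tr_tie <- toy_trajectory(list(list(from = 0, to = 101,
                                     levels = list(Cas = 5))))
  expect_equal(progeny_identities(tr_tie, 50, default_identity_map(),
                                  thr_toy), "interneuron")
  # nothing above threshold: identity "none"
  expect_equal(progeny_identities(toy_trajectory(list(), horizon = 50), 25,
                                  default_identity_map(), thr_toy), "none")
})
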