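test_that("observed diversity counts distinct accepted species per stage", {
  ts <- geologic_timescale()
  tab <- data.frame(
    species = c("X", "X", "Y", "Z"),
    clade = "Cavolinioidea",
    stage = c("Ypresian", "Rupelian", "Ypresian", "Recent"),
    status = "accepted", stringsAsFactors = FALSE)
  d <- observed_diversity(tab, ts)
  expect_equal(unname(d["Ypresian"]), 2L)
  expect_equal(unname(d["Rupelian"]), 1L)
  expect_equal(unname(d["Recent"]), 1L)
  expect_equal(sum(d), 4L)
  # empty table: all-zero curve
  expect_true(all(observed_diversity(tab[0, ], ts) == 0))
  # unknown stage errors
  bad <- tab; bad$stage[1] <- "Noachian"
  expect_error(observed_diversity(bad, ts), "binning-error")
})

test_that("synonym and doubtful records never change counts", {
  ts <- geologic_timescale()
  tab <- data.frame(species = c("X", "Y"), clade = "other",
                    stage = "Ypresian", status = "accepted",
                    stringsAsFactors = FALSE)
  extra <- data.frame(species = c("X2", "Y2", "Z2"), clade = "other",
                      stage = c("Ypresian", "Thanetian", "Recent"),
                      status = c("synonym", "doubtful", "synonym"),
                      stringsAsFactors = FALSE)
  expect_identical(observed_diversity(rbind(tab, extra), ts),
                   observed_diversity(tab, ts))
  expect_identical(range_through_diversity(rbind(tab, extra), ts),
                   range_through_diversity(tab, ts))
})

test_that("range-through fills gaps and dominates observed counts", {
  ts <- geologic_timescale()
  # X seen Ypresian and Rupelian: the intervening Lutetian-Priabonian filled
  tab <- data.frame(species = c("X", "X", "Y"), clade = "other",
                    stage = c("Ypresian", "Rupelian", "Chattian"),
                    status = "accepted", stringsAsFactors = FALSE)
  rt <- range_through_diversity(tab, ts)
  expect_equal(unname(rt["Lutetian"]), 1L)
  expect_equal(unname(rt["Priabonian"]), 1L)
  obs <- observed_diversity(tab, ts)
  expect_true(all(rt >= obs))
  # single occurrence: identical to observed
  solo <- tab[3, , drop = FALSE]
  expect_identical(range_through_diversity(solo, ts),
                   observed_diversity(solo, ts))
  # property on random synthetic records
  for (seed in 1:5) {
    rec <- sim_fossil_record(c(a = 10, b = 8), ts, preservation = 0.4,
                             seed = seed)
    expect_true(all(range_through_diversity(rec, ts) >=
                    observed_diversity(rec, ts)))
  }
})

test_that("stage spans expand to one record per spanned stage", {
  ts <- geologic_timescale()
  tab <- data.frame(species = "P", clade = "Pseudothecosomata",
                    stage = "Chattian-Burdigalian", status = "accepted",
                    stringsAsFactors = FALSE)
  d <- observed_diversity(tab, ts)
  expect_equal(unname(d[c("Chattian", "Aquitanian", "Burdigalian")]),
               c(1L, 1L, 1L))
})

test_that("interval summaries implement median/total/mean", {
  counts <- c(Aquitanian = 30, Burdigalian = 33)
  expect_equal(interval_summary(counts, names(counts), "median"), 31.5)
  expect_equal(interval_summary(counts, names(counts), "total"), 63)
  expect_equal(interval_summary(counts, "Aquitanian", "mean"), 30)
  expect_error(interval_summary(counts, character(0)), "value-error")
  expect_error(interval_summary(counts, "Ypresian"), "value-error")
})

test_that("diversity report pools clades and respects the partition", {
  ts <- geologic_timescale()
  rec <- sim_fossil_record(c(Cavolinioidea = 12, Gymnosomata = 9), ts,
                           preservation = 0.5, seed = 4)
  rep <- diversity_report(rec, ts)
  expect_equal(nrow(rep), nrow(ts) * 3)  # 2 clades + pooled
  pooled <- rep[rep$clade == "pooled", "observed"]
  split_sum <- rep[rep$clade == "Cavolinioidea", "observed"] +
    rep[rep$clade == "Gymnosomata", "observed"]
  expect_equal(pooled, split_sum)
  # preservation 0 pre-Recent: flat-zero pooled curve before Recent
  rec0 <- sim_fossil_record(c(Gymnosomata = 10), ts, preservation = 0,
                            seed = 5)
  rep0 <- diversity_report(rec0, ts)
  pre <- rep0$clade == "pooled" & rep0$stage != "Recent"
  expect_true(all(rep0$observed[pre] == 0))
})

test_that("bundled timescale is ordered and anchored at the Recent", {
  ts <- geologic_timescale()
  expect_true(all(diff(ts$older) < 0))
  expect_equal(ts$younger[nrow(ts)], 0)
  expect_true(all(c("Thanetian", "Ypresian", "Campanian", "Pleistocene",
                    "Recent") %in% ts$stage))
})
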