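test_that("enrichment ratio follows the max-over-lane-mates convention", {
  tab <- data.frame(
    transcript_id = c("T1", "T1", "T1", "T2", "T3", "T3"),
    dataset_id    = c("d1", "d2", "d3", "d1", "d1", "d4"),
    lane_id       = c("L1", "L1", "L1", "L1", "L1", "L2"),
    est_count     = 5,
    tpm           = c(10, 30, 5, 7, 0, 2),
    stringsAsFactors = FALSE)
  expect_equal(enrichment_ratio("T1", "d1", tab), 3.0)
  expect_equal(enrichment_ratio("T2", "d1", tab), 0)       # no mate has it
  expect_equal(enrichment_ratio("T3", "d1", tab), 0)       # mate in other lane
  tab$tpm[5] <- 0; tab$dataset_id[6] <- "d2"; tab$lane_id[6] <- "L1"
  expect_equal(enrichment_ratio("T3", "d1", tab), Inf)     # 2 / 0
  expect_error(enrichment_ratio("T9", "d1", tab), "lookup-error")
})

test_that("the documented toy partition is reproduced exactly", {
  rep <- apply_contamination_filter(toy_transcripts())
  d1 <- rep$decisions[rep$decisions$dataset_id == "d1", ]
  dec <- stats::setNames(d1$decision, d1$transcript_id)
  expect_equal(dec[["T1"]], "excluded_by_enrichment")  # ratio 3 > 2
  expect_equal(dec[["T2"]], "excluded_by_count")       # count 1 < 2
  expect_equal(dec[["T3"]], "kept")                    # ratio 0.5, count 9
})

test_that("vectorized filter agrees with the per-transcript ratio", {
  tab <- random_transcript_table(4, 25, seed = 7)
  rep <- apply_contamination_filter(tab)
  idx <- sample(nrow(tab), 20)
  for (i in idx) {
    r <- enrichment_ratio(tab$transcript_id[i], tab$dataset_id[i], tab)
    expect_equal(rep$decisions$ratio[i], r)
  }
})

test_that("filter invariants hold on random tables", {
  for (seed in 1:12) {
    tab <- random_transcript_table(sample(2:5, 1), sample(10:40, 1), seed)
    rep <- apply_contamination_filter(tab)
    # partition property per dataset
    for (d in unique(tab$dataset_id)) {
      nd <- sum(tab$dataset_id == d)
      dd <- rep$decisions[rep$decisions$dataset_id == d, ]
      expect_equal(sum(dd$decision == "kept") +
                   sum(dd$decision == "excluded_by_enrichment") +
                   sum(dd$decision == "excluded_by_count"), nd)
    }
    # monotonicity: raising the fold threshold never adds enrichment exclusions
    rep2 <- apply_contamination_filter(tab, fold_threshold = 4)
    was_kept <- rep$decisions$decision != "excluded_by_enrichment"
    now_excl <- rep2$decisions$decision == "excluded_by_enrichment"
    expect_false(any(was_kept & now_excl))
    # disabled filter keeps everything
    rep0 <- apply_contamination_filter(tab, fold_threshold = Inf, min_count = 0)
    expect_true(all(rep0$decisions$decision == "kept"))
  }
})

test_that("no enrichment exclusions without contamination", {
  tab <- sim_contaminated_expression(list(c("d1", "d2"), c("d3", "d4")),
                                     n_transcripts = 150, contamination = 0,
                                     seed = 13)
  rep <- apply_contamination_filter(tab)
  expect_equal(sum(rep$decisions$decision == "excluded_by_enrichment"), 0)
})

test_that("filter recovers injected contaminants on synthetic lanes", {
  tab <- sim_contaminated_expression(list(c("d1", "d2", "d3")),
                                     n_transcripts = 400,
                                     contamination = 0.05,
                                     library_size = 2e5, seed = 17)
  rep <- apply_contamination_filter(tab)
  dec <- merge(rep$decisions, tab[c("transcript_id", "dataset_id",
                                    "is_contaminant")],
               by = c("transcript_id", "dataset_id"))
  excl <- dec$decision != "kept"
  recall <- mean(excl[dec$is_contaminant])
  precision <- mean(dec$is_contaminant[excl])
  expect_gt(recall, 0.9)
  expect_gt(precision, 0.6)
})

test_that("exclusion medians summarize across datasets", {
  mk <- function(f1, f2) structure(list(
    fractions = data.frame(dataset_id = "d", criterion1 = f1, criterion2 = f2)),
    class = "filter_report")
  out <- summarize_exclusions(list(mk(0.10, 0.3), mk(0.20, 0.2), mk(0.30, 0.1)))
  expect_equal(unname(out["median_frac_criterion1"]), 0.20)
  expect_equal(unname(out["median_frac_criterion2"]), 0.2)
  single <- summarize_exclusions(mk(0.4, 0.1))
  expect_equal(unname(single), c(0.4, 0.1))
  expect_error(summarize_exclusions(list()), "value-error")
})
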