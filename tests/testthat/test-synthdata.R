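test_that("chronogram simulator hits the requested size and age, deterministically", {
  tr <- sim_chronogram(2, root_age = 120, seed = 9)
  expect_equal(n_tips(tr), 2L)
  expect_equal(root_age(tr), 120)
  t1 <- sim_chronogram(28, seed = 4)
  t2 <- sim_chronogram(28, seed = 4)
  expect_identical(ape::write.tree(t1$phy), ape::write.tree(t2$phy))
  expect_equal(n_tips(t1), 28L)
})

test_that("pure-birth node ages match the order-statistic construction", {
  # Independent oracle: the Yule split times are sums of Exp(k*lambda)
  # waiting times from 2..n lineages, stopped uniformly inside the interval
  # in which the n-th lineage exists; node-age fractions follow.
  lam <- 1; n <- 6; B <- 1500
  set.seed(31)
  oracle <- replicate(B, {
    waits <- stats::rexp(n - 2, lam * (2:(n - 1)))
    s <- c(0, cumsum(waits))
    t_stop <- s[n - 1] + stats::runif(1) * stats::rexp(1, lam * n)
    (t_stop - s) / t_stop
  })
  sim <- sapply(seq_len(B), function(i) {
    tr <- sim_chronogram(n, lambda = lam, mu = 0, root_age = 1, seed = 1e6 + i)
    sort(node_ages(tr)[(n + 1):(2 * n - 1)], decreasing = TRUE)
  })
  # fractions share the root-age denominator, so per-depth means carry
  # correlated Monte-Carlo error; compare with an absolute band
  for (k in 1:(n - 1)) {
    expect_lt(abs(mean(sim[k, ]) - mean(sort_rows_desc(oracle)[k, ])), 0.015)
  }
  expect_gt(stats::ks.test(as.vector(sim[-1, ]),
                           as.vector(sort_rows_desc(oracle)[-1, ]))$p.value,
            1e-4)
})

test_that("branch-rate processes have the stated moments", {
  tr <- sim_chronogram(10, seed = 2)
  # UGAM with zero variance collapses to the mean
  r0 <- sim_branch_rates(tr, clock_model("ugam", nu = 0), seed = 1)
  expect_true(all(r0$branch[tr$phy$edge[, 2]] == 0.005))
  # CIR stationary variance sigma2 * mu / (2 theta)
  ck <- clock_model("cir", mean_rate = 1, sigma2 = 1, theta = 1)
  draws <- vapply(1:4000, function(i)
    sim_branch_rates(tr, ck, seed = i)$node[11], 0)  # root: stationary draw
  expect_equal(mean(draws), 1, tolerance = 0.05)
  expect_equal(stats::var(draws), 0.5, tolerance = 0.1)
  # lognormal increments: mean -sigma2 dt / 2, variance sigma2 dt
  ckl <- clock_model("lognormal_ac", sigma2 = 0.04)
  incs <- unlist(lapply(1:300, function(i) {
    r <- sim_branch_rates(tr, ckl, seed = i)$node
    e <- tr$phy$edge
    dt <- node_ages(tr)[e[, 1]] - node_ages(tr)[e[, 2]]
    (log(r[e[, 2]]) - log(r[e[, 1]])) / sqrt(dt) # standardized by sqrt(dt)
  }))
  dts <- rep(node_ages(tr)[tr$phy$edge[, 1]] - node_ages(tr)[tr$phy$edge[, 2]], 300)
  expect_lt(abs(mean(incs + 0.04 * sqrt(dts) / 2)), 0.01)
  expect_equal(stats::var(incs), 0.04, tolerance = 0.05)
})

test_that("sequence simulation matches the 20-state closed form", {
  # P(same residue) = 1/20 + (19/20) exp(-20 nu / 19) at distance nu
  tr2 <- dated_tree(ape::read.tree(text = "(A:50,B:50);"))
  rates <- rep(NA_real_, 3); rates[1:2] <- 0.005  # nu = 0.5 total
  al <- sim_alignments(tr2, list(branch = rates), n_genes = 1,
                       len_range = c(10000, 10000), p_missing = 0,
                       gamma_shape = Inf, gamma_categories = 1L, seed = 8)
  m <- al[[1]]$mat
  p_same <- mean(m["A", ] == m["B", ])
  nu <- 0.5
  expect_equal(p_same, 1 / 20 + (19 / 20) * exp(-20 * nu / 19),
               tolerance = 0.015)
  # zero branch lengths: all sequences identical
  al0 <- sim_alignments(tr2, list(branch = c(0, 0, NA)), n_genes = 1,
                        len_range = c(50, 50), p_missing = 0, seed = 9)
  expect_true(all(al0[[1]]$mat["A", ] == al0[[1]]$mat["B", ]))
  # missing probability 0: every gene has all taxa
  tr <- sim_chronogram(6, seed = 3)
  rr <- sim_branch_rates(tr, clock_model("ugam"), seed = 1)
  al1 <- sim_alignments(tr, rr, n_genes = 4, len_range = c(20, 30),
                        p_missing = 0, seed = 2)
  expect_true(all(vapply(al1, function(g) nrow(g$mat), 0L) == 6L))
})

test_that("contaminated expression tables carry the documented structure", {
  lanes <- list(c("d1", "d2"), "d3")
  tab <- sim_contaminated_expression(lanes, n_transcripts = 200,
                                     contamination = 0.05, seed = 3)
  # TPMs sum to 1e6 per dataset
  sums <- tapply(tab$tpm, tab$dataset_id, sum)
  expect_true(all(abs(sums - 1e6) < 1e-6 * 1e6))
  # contaminants only between lane-mates
  cont <- tab[tab$is_contaminant, ]
  expect_true(all(cont$dataset_id %in% c("d1", "d2")))
  expect_true(all(cont$origin_dataset != cont$dataset_id))
  # c = 0: nothing leaks; single dataset in lane untouched
  tab0 <- sim_contaminated_expression(lanes, n_transcripts = 100,
                                      contamination = 0, seed = 4)
  expect_false(any(tab0$is_contaminant))
  expect_true(all(tab[tab$dataset_id == "d3", "is_contaminant"] == FALSE))
  # determinism
  tabr <- sim_contaminated_expression(lanes, n_transcripts = 200,
                                      contamination = 0.05, seed = 3)
  expect_identical(tab, tabr)
})

test_that("fossil record generator obeys preservation probabilities", {
  ts <- geologic_timescale()
  rec1 <- sim_fossil_record(c(cladeA = 20), ts, preservation = 1, seed = 5)
  truth <- attr(rec1, "truth")
  obs <- observed_diversity(rec1, ts, "cladeA")
  expect_equal(unname(obs), unname(truth["cladeA", ]))
  # preservation 0 before Recent: flat zero curve pre-Recent
  rec0 <- sim_fossil_record(c(cladeA = 30), ts, preservation = 0, seed = 6)
  obs0 <- observed_diversity(rec0, ts, "cladeA")
  expect_true(all(obs0[-length(obs0)] == 0))
  # intermediate preservation: observed ~ Binomial(true, p) on average
  p <- 0.3
  tot_obs <- 0; tot_true <- 0
  for (i in 1:30) {
    rec <- sim_fossil_record(c(cladeA = 15), ts, preservation = p, seed = i)
    pre <- seq_len(nrow(ts) - 1L)  # exclude the certain Recent bin
    tot_obs <- tot_obs + sum(observed_diversity(rec, ts)[pre])
    tot_true <- tot_true + sum(attr(rec, "truth")[, pre])
  }
  expect_equal(tot_obs / tot_true, p, tolerance = 0.03)
})
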