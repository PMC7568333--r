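test_that("prior-only sampling matches the closed form on 3 taxa", {
  # detailed-balance smoke test: inner age | root ~ Uniform(0, root), root
  # ~ gamma(150, 70); compare MCMC output to the direct generative sampler
  tr <- toy_tree3()
  ch <- run_mcmc(NULL, tr, clock_model("cir"), age_prior("uniform"),
                 iterations = 20000, burn_in = 1000, thinning = 1, seed = 3)
  u <- ch$ages[, "age_5"] / ch$ages[, "age_4"]
  expect_lt(stats::ks.test(u, "punif")$statistic, 0.02)
  expect_equal(mean(ch$ages[, "age_4"]), 150, tolerance = 0.03)
  expect_equal(stats::sd(ch$ages[, "age_4"]), 70, tolerance = 0.05)
})

test_that("chains are reproducible given the seed", {
  tr <- sim_chronogram(8, seed = 2)
  rr <- sim_branch_rates(tr, clock_model("ugam"), seed = 3)
  al <- sim_alignments(tr, rr, n_genes = 2, len_range = c(60, 60), seed = 4)
  sm <- concatenate_alignments(al, tr$phy$tip.label)
  run <- function() run_mcmc(sm, tr, clock_model("ugam"),
                             age_prior("uniform"), iterations = 60,
                             burn_in = 30, seed = 5, gamma_categories = 2L)
  c1 <- run(); c2 <- run()
  expect_identical(c1$ages, c2$ages)
  expect_identical(c1$scalars, c2$scalars)
})

test_that("every sampled state respects the node-age ordering", {
  tr <- pteropod_example_tree()
  cs <- build_calibration_set("s2", tr, pteropod_clade_defs())
  ch <- run_mcmc(NULL, tr, clock_model("cir"), age_prior("birth_death"),
                 calset = cs, iterations = 1500, burn_in = 300, seed = 8)
  st <- pterochron:::tree_structure(tr)
  ages <- matrix(0, nrow(ch$ages), st$n_tip + st$n_node)
  ages[, as.integer(sub("age_", "", colnames(ch$ages)))] <- ch$ages
  for (v in st$postorder) for (k in st$children[[v]])
    expect_true(all(ages[, k] <= ages[, v]))
})

test_that("posterior summaries behave on known input", {
  tr <- toy_tree3()
  fake <- structure(list(
    ages = cbind(age_4 = stats::rnorm(10000, 100, 10),
                 age_5 = rep(50, 10000)),
    scalars = data.frame(mu_r = stats::rnorm(10000, 1, 0.1), varpar = 1,
                         alpha = 1, lambda = 1, bd_mu = 0, loglik = 0,
                         logprior = 0),
    tree = tr, prior_only = TRUE), class = "mcmc_chain")
  s <- summarize_chain(fake, 0)
  r4 <- s[s$parameter == "age_4", ]
  expect_equal(r4$mean, 100, tolerance = 0.01)
  expect_equal(r4$lower, stats::qnorm(0.025, 100, 10), tolerance = 0.01)
  expect_equal(r4$upper, stats::qnorm(0.975, 100, 10), tolerance = 0.01)
  # constant series: degenerate interval, zero ESS
  r5 <- s[s$parameter == "age_5", ]
  expect_equal(r5$lower, r5$upper)
  expect_equal(r5$ess, 0)
  expect_error(summarize_chain(fake, 1), "value-error")
  # mean tree is a valid chronogram
  mt <- attr(s, "mean_tree")
  expect_s3_class(mt, "dated_tree")
  # a flat root-age trace trips the convergence warning
  fake2 <- fake
  fake2$ages[, "age_4"] <- 120
  expect_warning(summarize_chain(fake2, 0), "convergence-warning")
})

test_that("cross-validation is deterministic and handles leave-one-out", {
  tr <- sim_chronogram(6, seed = 11)
  rr <- sim_branch_rates(tr, clock_model("ugam", nu = 1), seed = 12)
  genes <- sim_alignments(tr, rr, n_genes = 4, len_range = c(50, 50),
                          p_missing = 0, seed = 13)
  configs <- list(ugam = list(clock = clock_model("ugam"),
                              prior = age_prior("uniform")),
                  ln = list(clock = clock_model("lognormal_ac"),
                            prior = age_prior("uniform")))
  cv1 <- cross_validate(genes, tr, configs, k = 4, iterations = 60,
                        burn_in = 30, seed = 14, gamma_categories = 1L)
  cv2 <- cross_validate(genes, tr, configs, k = 4, iterations = 60,
                        burn_in = 30, seed = 14, gamma_categories = 1L)
  expect_identical(cv1$total, cv2$total)
  expect_equal(nrow(cv1), 2L)
  expect_true(all(is.finite(cv1$total)))
  expect_false(any(cv1$failed))
  expect_error(cross_validate(genes, tr, configs, k = 10), "config-error")
})
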