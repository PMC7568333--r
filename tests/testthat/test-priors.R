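test_that("root gamma prior is moment-matched", {
  p <- age_prior("uniform", root_mean = 150, root_sd = 70)
  expect_equal(p$root_shape, (150 / 70)^2, tolerance = 1e-12)
  expect_equal(p$root_rate, 150 / 70^2, tolerance = 1e-12)
  expect_equal(p$root_shape, 4.5918, tolerance = 1e-4)
  expect_equal(p$root_rate, 0.030612, tolerance = 1e-5)
})

test_that("log-prior rejects ordering violations and matches the sampler", {
  tr <- toy_tree3()
  p <- age_prior("uniform")
  good <- c(0, 0, 0, 2, 1)
  bad <- c(0, 0, 0, 2, 3)          # child older than root
  expect_true(is.finite(log_prior_node_ages(good, tr, p)))
  expect_equal(log_prior_node_ages(bad, tr, p), -Inf)
  # on the 3-taxon tree: inner age | root ~ Uniform(0, root)
  S <- sample_age_prior(tr, p, n = 4000, seed = 2)
  u <- S[, 5] / S[, 4]
  expect_gt(stats::ks.test(u, "punif")$p.value, 1e-3)
  # density value: root gamma * 1/root
  a <- c(0, 0, 0, 120, 40)
  expect_equal(log_prior_node_ages(a, tr, p),
               stats::dgamma(120, p$root_shape, p$root_rate, log = TRUE) -
                 log(120), tolerance = 1e-12)
})

test_that("direct prior draws honour every calibration's soft mass", {
  tr <- pteropod_example_tree()
  cd <- pteropod_clade_defs()
  for (id in c("s1", "s4", "s6")) {
    cs <- build_calibration_set(id, tr, cd)
    S <- sample_age_prior(tr, age_prior("uniform"), cs, n = 8000,
                          seed = 100 + match(id, paste0("s", 1:6)))
    for (i in seq_len(nrow(cs))) {
      p_below <- mean(S[, cs$node[i]] < cs$min_age[i])
      expect_lt(abs(p_below - cs$soft_mass[i]), 0.01)
    }
    # ordering always valid
    st <- pterochron:::tree_structure(tr)
    for (v in st$postorder) for (ch in st$children[[v]])
      expect_true(all(S[, ch] <= S[, v]))
  }
})

test_that("birth-death node-age kernel shifts ages young as lambda grows", {
  # mu = 0 (Yule): f(t | T) proportional to exp(-lambda t); conditioning on
  # few survivors of an explosive process pushes split times toward the
  # present, so the mean age decreases with lambda
  tr <- sim_chronogram(8, seed = 6)
  means <- vapply(c(0.01, 0.05, 0.2), function(lam) {
    S <- sample_age_prior(tr, age_prior("birth_death", lambda = lam,
                                        mu = 0), n = 3000, seed = 7)
    mean(S[, 10:15])   # non-root internal nodes
  }, 0)
  expect_true(all(diff(means) < 0))
  # and matches direct i.i.d. sampling from the closed-form kernel
  lam <- 0.05
  S <- sample_age_prior(tr, age_prior("birth_death", lambda = lam, mu = 0),
                        n = 6000, seed = 8)
  # compare the marginal of one cherry-parent node against the kernel
  # conditioned on its parent, via quantile-quantile agreement
  bd <- list(lambda = lam, mu = 0, rho = 1)
  st <- pterochron:::tree_structure(tr)
  leafish <- st$postorder[1]      # deepest internal node in postorder
  pa <- st$parent[leafish]
  u <- stats::runif(6000)
  ref <- vapply(seq_len(6000), function(i) {
    Vp <- pterochron:::bd_kernel_V(S[i, pa], bd)
    pterochron:::bd_kernel_quantile(u[i] * Vp, bd)
  }, 0)
  expect_gt(stats::ks.test(S[, leafish], ref)$p.value, 1e-3)
})

test_that("rate priors reproduce their defining identities", {
  tr <- sim_chronogram(6, seed = 3)
  # UGAM density equals the sum of gamma log-densities
  ck <- clock_model("ugam", mean_rate = 0.01, nu = 0.5)
  rr <- sim_branch_rates(tr, ck, seed = 4)
  manual <- sum(stats::dgamma(rr$branch[tr$phy$edge[, 2]], 2,
                              rate = 2 / 0.01, log = TRUE))
  expect_equal(log_prior_rates(rr, tr, ck), manual, tolerance = 1e-12)
  # lognormal with sigma2 = 0 forces child = parent
  ckl0 <- clock_model("lognormal_ac", sigma2 = 0)
  r_const <- list(node = rep(0.005, 11),
                  branch = rep(0.005, 11))
  expect_equal(log_prior_rates(r_const, tr, ckl0), Inf)
  # CIR transition density integrates to 1 across time steps
  ckc <- clock_model("cir", mean_rate = 1, sigma2 = 1, theta = 1)
  for (dt in c(0.1, 1, 10)) {
    I <- stats::integrate(function(x)
      pterochron:::dcir_transition(x, 0.7, dt, ckc, log = FALSE),
      0, Inf, rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
  expect_error(clock_model("cir", mean_rate = 0.005, sigma2 = 1, theta = 0.05),
               "parameter-error")
})
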