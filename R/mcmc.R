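# Metropolis-within-Gibbs sampler for divergence times on a fixed topology.
# Node ages move by reflected slides inside their (children, parent) bracket,
# the root by a multiplier; relaxed-clock rates move per branch/node; two
# joint scale moves (all ages; ages vs rates trade-off) fix the slow
# rate-time mixing direction. Step sizes adapt during burn-in only, then
# freeze, preserving detailed balance afterwards.

HYPERPRIORS <- list(
  mu_r_meanlog = log(0.005), mu_r_sdlog = 2,  # substitutions/site/Myr
  nu_rate = 1,          # Exp(mean 1) on the UGAM multiplier variance
  sigma2_rate = 100,    # Exp(mean 0.01 /Myr) on the lognormal diffusion
  # CIR: the sampled variance parameter is z = sigma2/(2 theta mu_r), the
  # stationary squared coefficient of variation, Uniform(0,1); this keeps
  # the positivity constraint 2 theta mu_r >= sigma2 satisfied by
  # construction and decouples it from the mean rate.
  alpha_rate = 1,       # Exp(mean 1) on the gamma shape
  bd_rate = 100)        # Exp(mean 0.01 /Myr) on birth/death rates

#' Bayesian relaxed-clock dating by MCMC
#'
#' Samples node ages, branch/node rates and hyperparameters on the fixed
#' topology of `tree`, targeting likelihood x rate-process prior x
#' calibrated node-age prior. With `prior_only = TRUE` (or `sm = NULL`) the
#' likelihood is constant and the sampler draws from the calibrated age
#' prior - the mode used to verify soft-bound and root-prior contracts.
#'
#' @param sm a `supermatrix` (or `NULL` for prior-only sampling).
#' @param tree a [dated_tree()] fixing the topology (its ages are only used
#'   as a reference for initialization bounds).
#' @param clock a [clock_model()].
#' @param prior an [age_prior()].
#' @param calset optional calibration set from [build_calibration_set()].
#' @param iterations number of MCMC sweeps after burn-in.
#' @param burn_in adaptation sweeps discarded before recording.
#' @param thinning record every `thinning`-th sweep.
#' @param seed integer seed (mandatory).
#' @param model substitution model for the likelihood (`"poisson"`, `"lg"`).
#' @param gamma_categories,gamma_shape site-rate mixture settings.
#' @param sample_alpha sample the gamma shape? (ignored in prior-only mode)
#' @param sample_hyper sample clock hyperparameters (`mu_r` and the
#'   variance parameter)? If `FALSE` they stay at the values in `clock`.
#' @param prior_only force prior-only sampling.
#' @return object of class `mcmc_chain`: `ages` (samples x internal nodes
#'   matrix), `scalars` (`data.frame` of hyperparameters, log-likelihood and
#'   log-prior), `mean_edge_len`, `tree`, `calset`, `clock`, `prior`,
#'   `acceptance` rates and the resolved settings.
#' @export
run_mcmc <- function(sm, tree, clock, prior = age_prior("uniform"),
                     calset = NULL, iterations = 2000, burn_in = 500,
                     thinning = 1, seed = 1L, model = "poisson",
                     gamma_categories = 4L, gamma_shape = 0.8,
                     sample_alpha = TRUE, sample_hyper = TRUE,
                     prior_only = is.null(sm)) {
  stopifnot(iterations > 0, burn_in >= 0, thinning >= 1)
  if (is.null(seed)) stop("config-error: seed is mandatory")
  set.seed(as.integer(seed))
  cb <- calibration_bounds(tree, calset)
  st <- cb$st
  ntip <- st$n_tip
  nn <- ntip + st$n_node
  ints <- (ntip + 1L):nn
  nonroot <- setdiff(ints, st$root)
  edge_child <- tree$phy$edge[, 2L]
  clk <- clock

  # ---- initial state ----
  ages <- as.vector(sample_age_prior(tree, prior, calset, 1L))
  use_rates <- !prior_only
  if (use_rates) {
    r0 <- sim_branch_rates(set_node_ages(tree, ages), clk,
                           seed = sample.int(1e8, 1L))
    nrate <- r0$node
    brate <- r0$branch
  }
  bd <- list(lambda = prior$lambda, mu = prior$mu, rho = prior$rho)
  alpha <- gamma_shape

  prior_now <- function() {
    p <- prior; p$lambda <- bd$lambda; p$mu <- bd$mu; p
  }
  branch_rate <- function(ch) {
    if (clk$kind == "ugam") brate[ch]
    else (nrate[st$parent[ch]] + nrate[ch]) / 2
  }

  # ---- prior caches ----
  age_lp <- rep(0, nn)
  refresh_age_lp <- function(nodes = ints) {
    p <- prior_now()
    for (v in nodes) {
      age_lp[v] <<- if (v == st$root) root_lp(ages[v], p, cb)
        else age_cond_lp(v, ages[v], ages[st$parent[v]], p, cb)
    }
  }
  rate_lp <- rep(0, nn)      # indexed by child node of each edge
  root_rate_lp <- 0
  refresh_rate_lp <- function(chs = edge_child) {
    if (!use_rates) return(invisible())
    if (clk$kind == "ugam") {
      shape <- 1 / clk$nu
      rate_lp[chs] <<- stats::dgamma(brate[chs], shape,
                                     rate = shape / clk$mean_rate, log = TRUE)
    } else {
      for (ch in chs)
        rate_lp[ch] <<- rate_transition_lp(nrate[ch], nrate[st$parent[ch]],
                                           ages[st$parent[ch]] - ages[ch], clk)
      if (clk$kind == "cir") {
        a <- 2 * clk$theta * clk$mean_rate / clk$sigma2
        root_rate_lp <<- stats::dgamma(nrate[st$root], a,
                                       rate = 2 * clk$theta / clk$sigma2,
                                       log = TRUE)
      }
    }
  }
  hyper_lp <- function() {
    lp <- 0
    if (use_rates && sample_hyper) {
      lp <- lp + stats::dlnorm(clk$mean_rate, HYPERPRIORS$mu_r_meanlog,
                               HYPERPRIORS$mu_r_sdlog, log = TRUE)
      vp <- if (clk$kind == "ugam") clk$nu else clk$sigma2
      vr <- if (clk$kind == "ugam") HYPERPRIORS$nu_rate else HYPERPRIORS$sigma2_rate
      lp <- lp + stats::dexp(vp, vr, log = TRUE)
    }
    if (use_rates && sample_alpha)
      lp <- lp + stats::dexp(alpha, HYPERPRIORS$alpha_rate, log = TRUE)
    if (prior$kind == "birth_death")
      lp <- lp + stats::dexp(bd$lambda, HYPERPRIORS$bd_rate, log = TRUE) +
        stats::dexp(bd$mu, HYPERPRIORS$bd_rate, log = TRUE)
    lp
  }
  refresh_age_lp()
  refresh_rate_lp()

  # ---- likelihood engine ----
  edge_len <- rep(0, nn)
  lik <- NULL
  ll <- 0
  if (!prior_only) {
    lik <- make_pruning_likelihood(sm, tree, model, gamma_categories, alpha)
    for (ch in edge_child)
      edge_len[ch] <- branch_rate(ch) * (ages[st$parent[ch]] - ages[ch])
    ll <- plik_full(lik, edge_len, alpha)
  }

  # proposal step sizes (relative), adapted during burn-in
  steps <- new.env()
  steps$age <- rep(0.3, nn)     # fraction of the (lo, hi) bracket
  steps$root <- 0.2
  steps$rate <- rep(0.4, nn)
  steps$scalar <- c(age_scale = 0.15, tradeoff = 0.15, subtree = 0.15,
                    mu_r = 0.4, varpar = 0.6, alpha = 0.4,
                    lambda = 0.6, mu = 0.6)
  acc <- new.env(); tries <- new.env()
  bump <- function(name, hit) {
    acc[[name]] <- (acc[[name]] %||% 0) + hit
    tries[[name]] <- (tries[[name]] %||% 0) + 1
  }

  mh <- function(log_ratio) is.finite(log_ratio) && log(stats::runif(1L)) < log_ratio

  propose_edges <- function(chs, new_len) {
    el <- edge_len
    el[chs] <- new_len
    list(el = el, ll = plik_propose(lik$ptr, el))
  }

  # ---- individual moves (each returns nothing; mutates state on accept) ----
  move_age <- function(v) {
    kids <- st$children[[v]]
    lo <- max(ages[kids])
    is_root <- v == st$root
    hi <- if (is_root) Inf else ages[st$parent[v]]
    p <- prior_now()
    if (is_root) {
      u <- stats::runif(1L, -steps$root, steps$root)
      a_new <- ages[v] * exp(u)
      hast <- u
    } else {
      if (hi - lo <= 0) return(invisible())
      w <- steps$age[v] * (hi - lo)
      a_new <- reflect(ages[v] + stats::runif(1L, -w, w), lo, hi)
      hast <- 0
    }
    if (a_new <= lo || a_new >= hi) return(invisible())
    new_self <- if (is_root) root_lp(a_new, p, cb)
      else age_cond_lp(v, a_new, ages[st$parent[v]], p, cb)
    if (!is.finite(new_self)) { bump(if (is_root) "root" else "age", 0); return(invisible()) }
    d <- new_self - age_lp[v]
    ikids <- kids[kids > ntip]
    new_kid <- vapply(ikids, function(ch)
      age_cond_lp(ch, ages[ch], a_new, p, cb), 0)
    d <- d + sum(new_kid) - sum(age_lp[ikids])
    new_rlp <- NULL
    touched <- if (is_root) kids else c(v, kids)
    new_dt <- function(ch) {
      if (ch == v) ages[st$parent[v]] - a_new else a_new - ages[ch]
    }
    if (use_rates && clk$kind != "ugam") {
      new_rlp <- vapply(touched, function(ch)
        rate_transition_lp(nrate[ch], nrate[st$parent[ch]], new_dt(ch), clk), 0)
      d <- d + sum(new_rlp) - sum(rate_lp[touched])
    }
    if (prior$kind == "dirichlet" && prior$conc != 1) {
      ages2 <- ages; ages2[v] <- a_new
      d <- d + dirichlet_tilt(ages2, p, st) - dirichlet_tilt(ages, p, st)
    }
    pe <- NULL
    if (!prior_only) {
      new_len <- vapply(touched, function(ch) branch_rate(ch) * new_dt(ch), 0)
      pe <- propose_edges(touched, new_len)
      d <- d + pe$ll - ll
    }
    nm <- if (is_root) "root" else "age"
    if (mh(d + hast)) {
      ages[v] <<- a_new
      age_lp[v] <<- new_self
      age_lp[ikids] <<- new_kid
      if (!is.null(new_rlp)) rate_lp[touched] <<- new_rlp
      if (!is.null(pe)) { edge_len <<- pe$el; ll <<- pe$ll; plik_accept(lik$ptr, pe$ll) }
      bump(nm, 1)
    } else bump(nm, 0)
  }

  move_rate_ugam <- function(ch) {
    u <- stats::runif(1L, -steps$rate[ch], steps$rate[ch])
    r_new <- brate[ch] * exp(u)
    shape <- 1 / clk$nu
    new_lp <- stats::dgamma(r_new, shape, rate = shape / clk$mean_rate,
                            log = TRUE)
    d <- new_lp - rate_lp[ch] + u
    pe <- NULL
    if (!prior_only) {
      pe <- propose_edges(ch, r_new * (ages[st$parent[ch]] - ages[ch]))
      d <- d + pe$ll - ll
    }
    if (mh(d)) {
      brate[ch] <<- r_new
      rate_lp[ch] <<- new_lp
      if (!is.null(pe)) { edge_len <<- pe$el; ll <<- pe$ll; plik_accept(lik$ptr, pe$ll) }
      bump("rate", 1)
    } else bump("rate", 0)
  }

  move_rate_node <- function(x) {
    # autocorrelated models: node rate at x (tip, internal or root)
    if (x == st$root && clk$kind == "lognormal_ac") return(invisible())
    u <- stats::runif(1L, -steps$rate[x], steps$rate[x])
    r_new <- nrate[x] * exp(u)
    d <- u
    new_self <- NULL; new_root_lp <- NULL
    if (x != st$root) {
      new_self <- rate_transition_lp(r_new, nrate[st$parent[x]],
                                     ages[st$parent[x]] - ages[x], clk)
      d <- d + new_self - rate_lp[x]
    } else {
      a <- 2 * clk$theta * clk$mean_rate / clk$sigma2
      new_root_lp <- stats::dgamma(r_new, a, rate = 2 * clk$theta / clk$sigma2,
                                   log = TRUE)
      d <- d + new_root_lp - root_rate_lp
    }
    kids <- if (x > ntip) st$children[[x]] else integer(0)
    new_kid <- vapply(kids, function(ch)
      rate_transition_lp(nrate[ch], r_new, ages[x] - ages[ch], clk), 0)
    d <- d + sum(new_kid) - sum(rate_lp[kids])
    pe <- NULL
    if (!prior_only) {
      chs <- c(if (x != st$root) x, kids)
      new_len <- vapply(chs, function(ch) {
        ra <- if (ch == x) (nrate[st$parent[x]] + r_new) / 2
              else (r_new + nrate[ch]) / 2
        ra * (ages[st$parent[ch]] - ages[ch])
      }, 0)
      pe <- propose_edges(chs, new_len)
      d <- d + pe$ll - ll
    }
    if (mh(d)) {
      nrate[x] <<- r_new
      if (!is.null(new_self)) rate_lp[x] <<- new_self
      if (!is.null(new_root_lp)) root_rate_lp <<- new_root_lp
      rate_lp[kids] <<- new_kid
      if (!is.null(pe)) { edge_len <<- pe$el; ll <<- pe$ll; plik_accept(lik$ptr, pe$ll) }
      bump("rate", 1)
    } else bump("rate", 0)
  }

  # generic scalar hyperparameter multiplier move; `apply_fun(value)` must
  # return a list(delta_prior, pe) given the proposal, with caches refreshed
  # by `commit_fun()` on acceptance.
  move_scalar <- function(name, get, set, lp_terms) {
    u <- stats::runif(1L, -steps$scalar[name], steps$scalar[name])
    old <- get()
    new <- old * exp(u)
    res <- lp_terms(new)
    if (is.null(res)) { bump(name, 0); return(invisible()) }
    if (mh(res$delta + u)) {
      set(new)
      res$commit()
      bump(name, 1)
    } else {
      if (!is.null(res$rollback)) res$rollback()
      bump(name, 0)
    }
  }

  sum_rate_lp <- function() sum(rate_lp[edge_child]) + root_rate_lp

  move_mu_r <- function() move_scalar("mu_r", function() clk$mean_rate,
    function(v) NULL, function(new_mu) {
      clk2 <- clk; clk2$mean_rate <- new_mu
      if (clk$kind == "cir")   # hold z = sigma2/(2 theta mu_r) fixed
        clk2$sigma2 <- clk$sigma2 * new_mu / clk$mean_rate
      old_sum <- sum_rate_lp()
      old_prior <- stats::dlnorm(clk$mean_rate, HYPERPRIORS$mu_r_meanlog,
                                 HYPERPRIORS$mu_r_sdlog, log = TRUE)
      new_prior <- stats::dlnorm(new_mu, HYPERPRIORS$mu_r_meanlog,
                                 HYPERPRIORS$mu_r_sdlog, log = TRUE)
      # recompute rate prior under the new mean
      saved_clk <- clk; saved_rlp <- rate_lp; saved_rootlp <- root_rate_lp
      saved_nrate <- if (clk$kind != "ugam") nrate
      clk <<- clk2
      pe <- NULL; dll <- 0
      if (clk$kind == "lognormal_ac") {
        nrate[st$root] <<- new_mu
        kids <- st$children[[st$root]]
        refresh_rate_lp(edge_child)
        if (!prior_only) {
          new_len <- vapply(kids, function(ch)
            (new_mu + nrate[ch]) / 2 * (ages[st$root] - ages[ch]), 0)
          pe <- propose_edges(kids, new_len)
          dll <- pe$ll - ll
        }
      } else refresh_rate_lp(edge_child)
      delta <- sum_rate_lp() - old_sum + new_prior - old_prior + dll
      list(delta = delta,
           commit = function() {
             if (!is.null(pe)) { edge_len <<- pe$el; ll <<- pe$ll; plik_accept(lik$ptr, pe$ll) }
           },
           rollback = function() {
             clk <<- saved_clk; rate_lp <<- saved_rlp; root_rate_lp <<- saved_rootlp
             if (!is.null(saved_nrate)) nrate <<- saved_nrate
           })
    })

  move_varpar <- function() {
    if (clk$kind == "cir") {
      # reflected walk on z = sigma2 / (2 theta mu_r) in (0, 1), flat prior
      z <- clk$sigma2 / (2 * clk$theta * clk$mean_rate)
      z_new <- reflect(z + stats::runif(1L, -steps$scalar["varpar"],
                                        steps$scalar["varpar"]), 0, 1)
      old_sum <- sum_rate_lp()
      saved_clk <- clk; saved_rlp <- rate_lp; saved_rootlp <- root_rate_lp
      clk$sigma2 <<- z_new * 2 * clk$theta * clk$mean_rate
      refresh_rate_lp(edge_child)
      if (mh(sum_rate_lp() - old_sum)) bump("varpar", 1)
      else {
        clk <<- saved_clk; rate_lp <<- saved_rlp; root_rate_lp <<- saved_rootlp
        bump("varpar", 0)
      }
      return(invisible())
    }
    move_scalar("varpar",
      function() if (clk$kind == "ugam") clk$nu else clk$sigma2,
      function(v) NULL, function(new_v) {
        clk2 <- clk
        if (clk$kind == "ugam") clk2$nu <- new_v else clk2$sigma2 <- new_v
        vr <- if (clk$kind == "ugam") HYPERPRIORS$nu_rate else HYPERPRIORS$sigma2_rate
        old_v <- if (clk$kind == "ugam") clk$nu else clk$sigma2
        old_sum <- sum_rate_lp()
        saved_clk <- clk; saved_rlp <- rate_lp; saved_rootlp <- root_rate_lp
        clk <<- clk2
        refresh_rate_lp(edge_child)
        delta <- sum_rate_lp() - old_sum +
          stats::dexp(new_v, vr, log = TRUE) - stats::dexp(old_v, vr, log = TRUE)
        list(delta = delta, commit = function() {},
             rollback = function() {
               clk <<- saved_clk; rate_lp <<- saved_rlp; root_rate_lp <<- saved_rootlp
             })
      })
  }

  move_alpha <- function() move_scalar("alpha", function() alpha,
    function(v) NULL, function(new_a) {
      ll_new <- plik_full(lik, edge_len, new_a)
      delta <- ll_new - ll +
        stats::dexp(new_a, HYPERPRIORS$alpha_rate, log = TRUE) -
        stats::dexp(alpha, HYPERPRIORS$alpha_rate, log = TRUE)
      list(delta = delta,
           commit = function() { alpha <<- new_a; ll <<- ll_new },
           rollback = function() plik_full(lik, edge_len, alpha))
    })

  move_bd <- function(which_par) move_scalar(which_par,
    function() bd[[which_par]], function(v) NULL, function(new_v) {
      bd2 <- bd; bd2[[which_par]] <- new_v
      if (!(bd2$lambda > bd2$mu && bd2$mu >= 0)) return(NULL)
      old_v <- bd[[which_par]]
      old_sum <- sum(age_lp[ints])
      saved_bd <- bd; saved_alp <- age_lp
      bd <<- bd2
      refresh_age_lp()
      delta <- sum(age_lp[ints]) - old_sum +
        stats::dexp(new_v, HYPERPRIORS$bd_rate, log = TRUE) -
        stats::dexp(old_v, HYPERPRIORS$bd_rate, log = TRUE)
      list(delta = delta, commit = function() {},
           rollback = function() { bd <<- saved_bd; age_lp <<- saved_alp })
    })

  move_age_scale <- function() {
    u <- stats::runif(1L, -steps$scalar["age_scale"], steps$scalar["age_scale"])
    cc <- exp(u)
    ages2 <- ages; ages2[ints] <- ages[ints] * cc
    p <- prior_now()
    saved_alp <- age_lp; saved_rlp <- rate_lp; saved_ages <- ages
    ages <<- ages2
    refresh_age_lp()
    if (use_rates && clk$kind != "ugam") refresh_rate_lp(edge_child)
    d <- sum(age_lp[ints]) - sum(saved_alp[ints]) +
      sum_rate_lp() - (sum(saved_rlp[edge_child]) + root_rate_lp) +
      length(ints) * u
    if (prior$kind == "dirichlet" && prior$conc != 1)
      d <- d + dirichlet_tilt(ages, p, st) - dirichlet_tilt(saved_ages, p, st)
    pe <- NULL
    if (!prior_only) {
      pe <- propose_edges(edge_child, edge_len[edge_child] * cc)
      d <- d + pe$ll - ll
    }
    if (mh(d)) {
      if (!is.null(pe)) { edge_len <<- pe$el; ll <<- pe$ll; plik_accept(lik$ptr, pe$ll) }
      bump("age_scale", 1)
    } else {
      ages <<- saved_ages; age_lp <<- saved_alp; rate_lp <<- saved_rlp
      bump("age_scale", 0)
    }
  }

  # descendants (internal, inclusive) and subtree edge children per node
  desc_int <- vector("list", nn)
  desc_edges <- vector("list", nn)
  for (v in st$postorder) {
    di <- v; de <- integer(0)
    for (ch in st$children[[v]]) {
      de <- c(de, ch)
      if (ch > ntip) { di <- c(di, desc_int[[ch]]); de <- c(de, desc_edges[[ch]]) }
    }
    desc_int[[v]] <- di
    desc_edges[[v]] <- de
  }

  move_subtree_scale <- function(v) {
    # scale every internal age in the subtree rooted at v by a common factor
    sub <- desc_int[[v]]
    u <- stats::runif(1L, -steps$scalar["subtree"], steps$scalar["subtree"])
    cc <- exp(u)
    if (ages[v] * cc >= ages[st$parent[v]]) { bump("subtree", 0); return(invisible()) }
    ages2 <- ages
    ages2[sub] <- ages[sub] * cc
    p <- prior_now()
    # conditionals that change: the scaled nodes and their internal children
    affect <- unique(c(sub, unlist(st$children[sub])))
    affect <- affect[affect > ntip]
    new_alp <- vapply(affect, function(w)
      age_cond_lp(w, ages2[w], ages2[st$parent[w]], p, cb), 0)
    d <- sum(new_alp) - sum(age_lp[affect]) + length(sub) * u
    # edges whose duration changes: v's parent edge and the whole subtree
    chs <- c(v, desc_edges[[v]])
    new_rlp <- NULL
    if (use_rates && clk$kind != "ugam") {
      new_rlp <- vapply(chs, function(ch)
        rate_transition_lp(nrate[ch], nrate[st$parent[ch]],
                           ages2[st$parent[ch]] - ages2[ch], clk), 0)
      d <- d + sum(new_rlp) - sum(rate_lp[chs])
    }
    if (prior$kind == "dirichlet" && prior$conc != 1)
      d <- d + dirichlet_tilt(ages2, p, st) - dirichlet_tilt(ages, p, st)
    pe <- NULL
    if (!prior_only) {
      new_len <- vapply(chs, function(ch)
        branch_rate(ch) * (ages2[st$parent[ch]] - ages2[ch]), 0)
      pe <- propose_edges(chs, new_len)
      d <- d + pe$ll - ll
    }
    if (mh(d)) {
      ages <<- ages2
      age_lp[affect] <<- new_alp
      if (!is.null(new_rlp)) rate_lp[chs] <<- new_rlp
      if (!is.null(pe)) { edge_len <<- pe$el; ll <<- pe$ll; plik_accept(lik$ptr, pe$ll) }
      bump("subtree", 1)
    } else bump("subtree", 0)
  }

  move_tradeoff <- function() {
    # ages * c, rates / c, mu_r / c: likelihood invariant
    if (!use_rates || !sample_hyper) return(invisible())
    u <- stats::runif(1L, -steps$scalar["tradeoff"], steps$scalar["tradeoff"])
    cc <- exp(u)
    saved <- list(ages = ages, alp = age_lp, rlp = rate_lp,
                  rootlp = root_rate_lp, clk = clk,
                  brate = if (clk$kind == "ugam") brate,
                  nrate = if (clk$kind != "ugam") nrate,
                  el = edge_len)
    n_rates <- if (clk$kind == "ugam") length(edge_child)
      else if (clk$kind == "cir") nn else nn - 1L
    old_sum <- sum(age_lp[ints]) + sum_rate_lp() +
      stats::dlnorm(clk$mean_rate, HYPERPRIORS$mu_r_meanlog,
                    HYPERPRIORS$mu_r_sdlog, log = TRUE)
    ages[ints] <<- ages[ints] * cc
    clk$mean_rate <<- clk$mean_rate / cc
    if (clk$kind == "cir") clk$sigma2 <<- clk$sigma2 / cc  # z held fixed
    if (clk$kind == "ugam") brate <<- brate / cc else nrate <<- nrate / cc
    refresh_age_lp()
    refresh_rate_lp(edge_child)
    new_sum <- sum(age_lp[ints]) + sum_rate_lp() +
      stats::dlnorm(clk$mean_rate, HYPERPRIORS$mu_r_meanlog,
                    HYPERPRIORS$mu_r_sdlog, log = TRUE)
    d <- new_sum - old_sum + (length(ints) - n_rates - 1L) * u
    if (mh(d)) {
      bump("tradeoff", 1)
    } else {
      ages <<- saved$ages; age_lp <<- saved$alp; rate_lp <<- saved$rlp
      root_rate_lp <<- saved$rootlp; clk <<- saved$clk
      if (!is.null(saved$brate)) brate <<- saved$brate
      if (!is.null(saved$nrate)) nrate <<- saved$nrate
      bump("tradeoff", 0)
    }
  }

  # ---- main loop ----
  total <- burn_in + iterations
  keep <- floor(iterations / thinning)
  rec_ages <- matrix(NA_real_, nrow = keep, ncol = length(ints),
                     dimnames = list(NULL, paste0("age_", ints)))
  rec <- data.frame(iter = integer(keep), mu_r = NA_real_, varpar = NA_real_,
                    alpha = NA_real_, lambda = NA_real_, bd_mu = NA_real_,
                    loglik = NA_real_, logprior = NA_real_)
  sum_edge_len <- rep(0, nn); n_rec <- 0L
  adapt_every <- 25L

  for (it in seq_len(total)) {
    move_age(st$root)
    for (v in nonroot) move_age(v)
    move_age_scale()
    n_sub <- if (prior_only) 2L else 8L   # local moves mix the prior well
    picks <- nonroot[sample.int(length(nonroot), min(n_sub, length(nonroot)))]
    for (v in picks) move_subtree_scale(v)
    if (use_rates) {
      if (clk$kind == "ugam") {
        for (ch in edge_child) move_rate_ugam(ch)
      } else {
        for (x in seq_len(nn)) move_rate_node(x)
      }
      move_tradeoff()
      if (sample_hyper) { move_mu_r(); move_varpar() }
      if (sample_alpha && !prior_only) move_alpha()
    }
    if (prior$kind == "birth_death") { move_bd("lambda"); move_bd("mu") }

    if (it <= burn_in && it %% adapt_every == 0L) {
      for (nm in c("root", "age", "rate", names(steps$scalar))) {
        tr <- tries[[nm]] %||% 0
        if (tr > 0) {
          rate_acc <- (acc[[nm]] %||% 0) / tr
          f <- exp(1.2 * (rate_acc - 0.3))
          if (nm == "age") steps$age <- pmin(1, pmax(1e-3, steps$age * f))
          else if (nm == "rate") steps$rate <- pmin(4, pmax(1e-3, steps$rate * f))
          else if (nm == "root") steps$root <- min(2, max(1e-3, steps$root * f))
          else steps$scalar[nm] <- min(2, max(1e-4, steps$scalar[nm] * f))
          acc[[nm]] <- 0; tries[[nm]] <- 0
        }
      }
    }
    if (it > burn_in && (it - burn_in) %% thinning == 0L) {
      n_rec <- n_rec + 1L
      rec_ages[n_rec, ] <- ages[ints]
      rec$iter[n_rec] <- it
      rec$mu_r[n_rec] <- clk$mean_rate
      rec$varpar[n_rec] <- if (clk$kind == "ugam") clk$nu else clk$sigma2
      rec$alpha[n_rec] <- alpha
      rec$lambda[n_rec] <- bd$lambda
      rec$bd_mu[n_rec] <- bd$mu
      rec$loglik[n_rec] <- ll
      rec$logprior[n_rec] <- sum(age_lp[ints]) +
        (if (use_rates) sum_rate_lp() else 0) + hyper_lp() +
        dirichlet_tilt(ages, prior_now(), st)
      sum_edge_len <- sum_edge_len + edge_len
    }
  }
  acc_rates <- vapply(ls(tries), function(nm)
    (acc[[nm]] %||% 0) / max(1, tries[[nm]]), 0)
  structure(list(ages = rec_ages[seq_len(n_rec), , drop = FALSE],
                 scalars = rec[seq_len(n_rec), , drop = FALSE],
                 mean_edge_len = if (n_rec) sum_edge_len / n_rec else NULL,
                 tree = tree, calset = calset, clock = clock, prior = prior,
                 acceptance = acc_rates, prior_only = prior_only,
                 settings = list(iterations = iterations, burn_in = burn_in,
                                 thinning = thinning, seed = seed,
                                 model = model,
                                 gamma_categories = gamma_categories)),
            class = "mcmc_chain")
}

reflect <- function(x, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(lo)
  y <- (x - lo) %% (2 * w)
  if (y < 0) y <- y + 2 * w
  lo + if (y > w) 2 * w - y else y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mcmc_chain <- function(x, ...) {
  cat("mcmc_chain: ", nrow(x$ages), " samples x ", ncol(x$ages),
      " node ages", if (x$prior_only) " (prior-only)", "\n", sep = "")
  invisible(x)
}

#' Posterior summaries of an MCMC chain
#'
#' Per internal node and per scalar parameter: mean, the 95% credibility
#' interval (2.5 and 97.5 percentiles) and an effective sample size from
#' the autocorrelation time. An additional fraction of the retained samples
#' can be discarded as extra burn-in. A root-age ESS below 50 triggers a
#' convergence warning (not an error).
#'
#' @param chain an `mcmc_chain` from [run_mcmc()].
#' @param burn_in_fraction extra fraction of retained samples to drop
#'   (default 0.25; must be < 1).
#' @return `data.frame` with `parameter`, `mean`, `lower`, `upper`, `ess`;
#'   the posterior-mean chronogram (ages clipped to respect ordering) is
#'   attached as `attr(, "mean_tree")`.
#' @export
summarize_chain <- function(chain, burn_in_fraction = 0.25) {
  if (burn_in_fraction >= 1 || burn_in_fraction < 0)
    stop("value-error: burn_in_fraction must be in [0, 1)")
  n <- nrow(chain$ages)
  from <- floor(burn_in_fraction * n) + 1L
  if (from > n) stop("value-error: chain shorter than burn-in")
  A <- chain$ages[from:n, , drop = FALSE]
  S <- chain$scalars[from:n, , drop = FALSE]
  cols <- cbind(A, as.matrix(S[c("mu_r", "varpar", "alpha", "loglik")]))
  out <- data.frame(parameter = colnames(cols),
                    mean = colMeans(cols),
                    lower = apply(cols, 2, stats::quantile, 0.025),
                    upper = apply(cols, 2, stats::quantile, 0.975),
                    ess = apply(cols, 2, ess_acf),
                    row.names = NULL)
  root_col <- paste0("age_", n_tips(chain$tree) + 1L)
  ess_root <- out$ess[out$parameter == root_col]
  if (length(ess_root) && is.finite(ess_root) && ess_root < 50)
    warning("convergence-warning: root-age ESS ", round(ess_root), " < 50")
  # posterior-mean chronogram, durations clipped at zero
  ages <- node_ages(chain$tree)
  ages[as.integer(sub("age_", "", colnames(A)))] <- colMeans(A)
  st <- tree_structure(chain$tree)
  for (v in rev(st$postorder)) for (ch in st$children[[v]])
    if (ch > st$n_tip && ages[ch] > ages[v]) ages[ch] <- ages[v]
  attr(out, "mean_tree") <- set_node_ages(chain$tree, ages)
  out
}

# ESS via the autocorrelation time, truncated at the first negative
# autocorrelation (Geyer-style initial positive window, simplified).
ess_acf <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(if (stats::var(x) == 0) 0 else n)
  ac <- stats::acf(x, lag.max = min(n - 1, 2000), plot = FALSE)$acf[-1]
  cut <- which(ac < 0)[1]
  if (!is.na(cut)) ac <- ac[seq_len(cut - 1)]
  n / (1 + 2 * sum(ac))
}
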