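#' Node-age prior specification
#'
#' Root age gets a gamma prior parameterized by mean and SD (defaults 150
#' and 70 Ma, moment-matched: shape = mean^2/SD^2, rate = mean/SD^2).
#' Non-root internal ages follow, conditionally on their parent, one of
#' three kernels: `"uniform"` (flat), `"birth_death"` (the conditioned
#' reconstructed-process kernel with speciation `lambda`, extinction `mu`
#' and sampling fraction `rho`) or `"dirichlet"` (uniform kernel with a
#' symmetric Dirichlet tilt of concentration `conc` on the proportions of
#' sorted internode gaps; `conc = 1` is identical to `"uniform"`).
#'
#' The joint prior is sequential (root to tips): each node's age is
#' distributed on `(L_v, parent age)` where `L_v` is the largest fossil
#' minimum among the node's calibrated descendants, and calibrated nodes
#' get the soft-bound two-piece density of [calibration_log_factor()] with
#' the kernel as plateau shape. This construction makes the prior mass
#' below each fossil minimum exactly `soft_mass`, per calibration, jointly
#' across nested calibrations.
#'
#' @param kind `"uniform"`, `"birth_death"` or `"dirichlet"`.
#' @param root_mean,root_sd root gamma prior mean and SD in Ma.
#' @param lambda,mu,rho birth-death kernel parameters (used by
#'   `"birth_death"`); `lambda > mu >= 0`, `rho` in (0, 1].
#' @param conc Dirichlet concentration (used by `"dirichlet"`).
#' @return object of class `age_prior`.
#' @export
age_prior <- function(kind = c("uniform", "birth_death", "dirichlet"),
                      root_mean = 150, root_sd = 70,
                      lambda = 0.02, mu = 0.005, rho = 1, conc = 1) {
  kind <- match.arg(kind)
  stopifnot(root_mean > 0, root_sd > 0, rho > 0, rho <= 1, conc > 0)
  if (kind == "birth_death" && !(lambda > mu && mu >= 0))
    stop("parameter-error: birth-death needs lambda > mu >= 0")
  structure(list(kind = kind, root_mean = root_mean, root_sd = root_sd,
                 root_shape = root_mean^2 / root_sd^2,
                 root_rate = root_mean / root_sd^2,
                 lambda = lambda, mu = mu, rho = rho, conc = conc),
            class = "age_prior")
}

# Per-node calibration bookkeeping on a fixed topology: minimum age and
# soft mass per node (NA if uncalibrated) and the support lower bound L_v =
# max fossil minimum among calibrated proper descendants.
calibration_bounds <- function(tree, calset = NULL) {
  st <- tree_structure(tree)
  nn <- st$n_tip + st$n_node
  min_age <- rep(NA_real_, nn)
  soft <- rep(NA_real_, nn)
  if (!is.null(calset) && nrow(calset)) {
    min_age[calset$node] <- calset$min_age
    soft[calset$node] <- calset$soft_mass
  }
  L <- rep(0, nn)
  for (v in st$postorder) {
    kid_bounds <- vapply(st$children[[v]], function(ch)
      max(L[ch], if (is.na(min_age[ch])) 0 else min_age[ch]), 0)
    L[v] <- max(kid_bounds)
  }
  ok <- which(!is.na(min_age))
  bad <- ok[L[ok] >= min_age[ok]]
  if (length(bad))
    stop("mapping-error: calibration minimum at node ", paste(bad, collapse = ","),
         " is not older than its calibrated descendants'")
  list(st = st, min_age = min_age, soft = soft, L = L)
}

# kernel plateau descriptor for a non-root node given its parent age
node_plateau <- function(prior, upper) {
  if (prior$kind == "birth_death")
    list(kind = "bd", upper = upper,
         bd = list(lambda = prior$lambda, mu = prior$mu, rho = prior$rho))
  else list(kind = "uniform", upper = upper)
}

# conditional log-density of internal node v's age given its parent's age
age_cond_lp <- function(v, age_v, parent_age, prior, cb) {
  if (!is.finite(parent_age) || age_v >= parent_age || age_v <= cb$L[v])
    return(-Inf)
  if (is.na(cb$min_age[v])) {
    pl <- node_plateau(prior, parent_age)
    plateau_lp(age_v, cb$L[v], 0, pl)
  } else {
    softbound_lp(age_v, cb$min_age[v], cb$soft[v], cb$L[v],
                 node_plateau(prior, parent_age))
  }
}

# root log-density: gamma prior, truncated to (L_root, Inf), with the
# soft-bound two-piece when the root itself carries a calibration
root_lp <- function(age_root, prior, cb) {
  root <- cb$st$root
  pl <- list(kind = "gamma", shape = prior$root_shape, rate = prior$root_rate)
  if (age_root <= cb$L[root]) return(-Inf)
  if (is.na(cb$min_age[root])) {
    plateau_lp(age_root, cb$L[root], 0, pl)
  } else {
    softbound_lp(age_root, cb$min_age[root], cb$soft[root], cb$L[root], pl)
  }
}

#' Joint log-prior of the node ages
#'
#' Evaluates the sequential calibrated age prior described in
#' [age_prior()]. Returns `-Inf` whenever the ordering constraint
#' (every parent older than each child) or a support bound is violated.
#'
#' @param ages node-age vector (ape numbering; tips 0).
#' @param tree a [dated_tree()] fixing the topology.
#' @param prior an [age_prior()].
#' @param calset optional calibration set from [build_calibration_set()].
#' @return log-density (single number).
#' @export
log_prior_node_ages <- function(ages, tree, prior, calset = NULL) {
  cb <- calibration_bounds(tree, calset)
  lp_prior_from_bounds(ages, prior, cb)
}

lp_prior_from_bounds <- function(ages, prior, cb) {
  st <- cb$st
  lp <- root_lp(ages[st$root], prior, cb)
  for (v in st$postorder) {
    if (v == st$root) next
    lp <- lp + age_cond_lp(v, ages[v], ages[st$parent[v]], prior, cb)
    if (!is.finite(lp)) return(-Inf)
  }
  lp + dirichlet_tilt(ages, prior, st)
}

# symmetric Dirichlet tilt on sorted internode-gap proportions (conc != 1)
dirichlet_tilt <- function(ages, prior, st) {
  if (prior$kind != "dirichlet" || prior$conc == 1) return(0)
  s <- sort(ages[(st$n_tip + 1L):(st$n_tip + st$n_node)], decreasing = TRUE)
  gaps <- -diff(c(s, 0))
  gaps <- pmax(gaps, .Machine$double.xmin)
  (prior$conc - 1) * sum(log(gaps / s[1L]))
}

#' Draw node ages directly from the calibrated prior
#'
#' Sequential top-down ancestral sampling: the exact generative counterpart
#' of [log_prior_node_ages()] (for `dirichlet` only `conc = 1` is
#' supported). Used for MCMC initialization and as the independent check of
#' prior-only MCMC output.
#'
#' @inheritParams log_prior_node_ages
#' @param n number of draws.
#' @param seed integer seed (optional).
#' @return matrix `n` x nodes of sampled age vectors (tips 0).
#' @export
sample_age_prior <- function(tree, prior, calset = NULL, n = 1L, seed = NULL) {
  if (prior$kind == "dirichlet" && prior$conc != 1)
    stop("direct sampling implemented for dirichlet concentration 1 only")
  if (!is.null(seed)) set.seed(as.integer(seed))
  cb <- calibration_bounds(tree, calset)
  st <- cb$st
  nn <- st$n_tip + st$n_node
  out <- matrix(0, nrow = n, ncol = nn)
  pre <- rev(st$postorder)
  root_pl <- list(kind = "gamma", shape = prior$root_shape,
                  rate = prior$root_rate)
  for (i in seq_len(n)) {
    ages <- numeric(nn)
    root <- st$root
    ages[root] <- if (is.na(cb$min_age[root])) {
      softbound_draw(cb$L[root], 0, cb$L[root], root_pl)
    } else {
      softbound_draw(cb$min_age[root], cb$soft[root], cb$L[root], root_pl)
    }
    for (v in pre) {
      if (v == root) next
      tp <- ages[st$parent[v]]
      pl <- node_plateau(prior, tp)
      ages[v] <- if (is.na(cb$min_age[v])) {
        softbound_draw(cb$L[v], 0, cb$L[v], pl)
      } else {
        softbound_draw(cb$min_age[v], cb$soft[v], cb$L[v], pl)
      }
    }
    out[i, ] <- ages
  }
  out
}

#' Log-prior of branch or node rates under a relaxed clock
#'
#' UGAM: i.i.d. gamma densities on branch rates (shape `1/nu`, mean
#' `mean_rate`). Autocorrelated lognormal: node log-rates follow Brownian
#' motion with drift `-sigma2*dt/2` from the root value `mean_rate`. CIR:
#' root rate from the stationary gamma, transitions by the exact
#' noncentral-chi-square density.
#'
#' @param rates result of [sim_branch_rates()] or a compatible list
#'   (`branch` for UGAM; `node` for the autocorrelated models).
#' @param tree a [dated_tree()].
#' @param clock a [clock_model()].
#' @param ages optional node ages overriding `node_ages(tree)`.
#' @return log-density.
#' @export
log_prior_rates <- function(rates, tree, clock, ages = NULL) {
  if (is.null(ages)) ages <- node_ages(tree)
  st <- tree_structure(tree)
  if (clock$kind == "ugam") {
    r <- rates$branch[tree$phy$edge[, 2L]]
    if (any(r <= 0)) return(-Inf)
    if (clock$nu == 0) return(if (all(r == clock$mean_rate)) Inf else -Inf)
    shape <- 1 / clock$nu
    return(sum(stats::dgamma(r, shape, rate = shape / clock$mean_rate,
                             log = TRUE)))
  }
  node <- rates$node
  if (any(node <= 0, na.rm = TRUE)) return(-Inf)
  lp <- 0
  if (clock$kind == "cir") {
    a <- 2 * clock$theta * clock$mean_rate / clock$sigma2
    lp <- stats::dgamma(node[st$root], a, rate = 2 * clock$theta / clock$sigma2,
                        log = TRUE)
  } else {
    if (abs(node[st$root] - clock$mean_rate) > 1e-12 * clock$mean_rate)
      return(-Inf)                    # lognormal process starts at mean_rate
  }
  for (e in seq_len(nrow(tree$phy$edge))) {
    pa <- tree$phy$edge[e, 1L]; ch <- tree$phy$edge[e, 2L]
    dt <- ages[pa] - ages[ch]
    lp <- lp + rate_transition_lp(node[ch], node[pa], dt, clock)
  }
  lp
}

rate_transition_lp <- function(x, x0, dt, clock) {
  if (dt <= 0) dt <- 1e-12
  if (clock$kind == "lognormal_ac") {
    if (clock$sigma2 == 0)
      return(if (abs(x - x0) < 1e-12 * x0) Inf else -Inf)
    stats::dlnorm(x, log(x0) - clock$sigma2 * dt / 2,
                  sqrt(clock$sigma2 * dt), log = TRUE)
  } else {
    dcir_transition(x, x0, dt, clock, log = TRUE)
  }
}
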