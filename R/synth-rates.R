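#' Relaxed-clock model specifications
#'
#' Three rate processes over the tree: `"ugam"` (uncorrelated i.i.d. gamma
#' branch rates), `"lognormal_ac"` (autocorrelated geometric Brownian motion
#' on node rates, drift \eqn{-\sigma^2 \Delta t/2} so the stationary mean is
#' preserved) and `"cir"` (mean-reverting square-root diffusion with gamma
#' stationary law). Units: `mean_rate` in substitutions/site/Myr; `sigma2`
#' per Myr; `theta` per Myr; `nu` is the dimensionless variance of the UGAM
#' rate multiplier.
#'
#' @param kind `"ugam"`, `"lognormal_ac"` or `"cir"`.
#' @param mean_rate stationary mean rate \eqn{\mu_r > 0}.
#' @param nu UGAM multiplier variance (>= 0).
#' @param sigma2 diffusion variance parameter (lognormal, CIR); default
#'   0.005 (lognormal) or 1e-4 (CIR), giving moderate rate variation at
#'   the default mean rate.
#' @param theta CIR reversion rate; requires \eqn{2\theta\mu_r \ge \sigma^2}
#'   (otherwise the process can hit zero).
#' @return object of class `clock_model`.
#' @export
clock_model <- function(kind = c("ugam", "lognormal_ac", "cir"),
                        mean_rate = 0.005, nu = 0.3, sigma2 = NULL,
                        theta = 0.05) {
  kind <- match.arg(kind)
  if (is.null(sigma2))
    sigma2 <- if (kind == "cir") 1e-4 else 0.005
  stopifnot(mean_rate > 0, nu >= 0, sigma2 >= 0, theta > 0)
  if (kind == "cir" && 2 * theta * mean_rate < sigma2)
    stop("parameter-error: CIR requires 2*theta*mean_rate >= sigma2 ",
         "(process can reach zero)")
  structure(list(kind = kind, mean_rate = mean_rate, nu = nu,
                 sigma2 = sigma2, theta = theta), class = "clock_model")
}

#' Simulate branch rates under a relaxed clock
#'
#' UGAM draws i.i.d. gamma rates per branch. The autocorrelated models evolve
#' a rate along root-to-tip paths: node rates follow the Markov process
#' (lognormal: Brownian motion on log rate started at \eqn{\log\mu_r};
#' CIR: stationary start, exact noncentral-chi-square transitions), and each
#' branch's rate is the mean of its endpoint node rates.
#'
#' @param tree a [dated_tree()].
#' @param clock a [clock_model()].
#' @param seed integer seed.
#' @return list with `branch` (rates indexed by child node, `NA` at the
#'   root) and, for autocorrelated models, `node` (rates per node).
#' @export
sim_branch_rates <- function(tree, clock, seed = 1L) {
  set.seed(as.integer(seed))
  st <- tree_structure(tree)
  ages <- node_ages(tree)
  nn <- length(ages)
  if (clock$kind == "ugam") {
    br <- rep(NA_real_, nn)
    idx <- tree$phy$edge[, 2L]
    if (clock$nu == 0) {
      br[idx] <- clock$mean_rate
    } else {
      shape <- 1 / clock$nu
      br[idx] <- stats::rgamma(length(idx), shape = shape,
                               rate = shape / clock$mean_rate)
    }
    return(list(branch = br, node = NULL))
  }
  node <- rep(NA_real_, nn)
  node[st$root] <- if (clock$kind == "cir") {
    a <- 2 * clock$theta * clock$mean_rate / clock$sigma2
    stats::rgamma(1L, shape = a, rate = 2 * clock$theta / clock$sigma2)
  } else clock$mean_rate
  # preorder: parents before children
  for (v in rev(st$postorder)) {
    for (ch in st$children[[v]]) {
      dt <- ages[v] - ages[ch]
      node[ch] <- if (clock$kind == "lognormal_ac") {
        exp(log(node[v]) - clock$sigma2 * dt / 2 +
              stats::rnorm(1L, 0, sqrt(clock$sigma2 * dt)))
      } else {
        rcir_transition(node[v], dt, clock)
      }
    }
  }
  br <- rep(NA_real_, nn)
  idx <- tree$phy$edge[, 2L]
  br[idx] <- (node[tree$phy$edge[, 1L]] + node[idx]) / 2
  list(branch = br, node = node)
}

# Exact CIR transition draw: X(t+dt) | X(t)=x ~ c * chisq(df, ncp) with
# c = sigma2 (1-e^(-theta dt)) / (4 theta), df = 4 theta mu / sigma2,
# ncp = x e^(-theta dt) / c.
rcir_transition <- function(x, dt, clock) {
  if (dt <= 0) return(x)
  c0 <- clock$sigma2 * (1 - exp(-clock$theta * dt)) / (4 * clock$theta)
  df <- 4 * clock$theta * clock$mean_rate / clock$sigma2
  ncp <- x * exp(-clock$theta * dt) / c0
  c0 * stats::rchisq(1L, df = df, ncp = ncp)
}

# CIR transition log-density (noncentral chi-square form); vectorized in x.
dcir_transition <- function(x, x0, dt, clock, log = TRUE) {
  c0 <- clock$sigma2 * (1 - exp(-clock$theta * dt)) / (4 * clock$theta)
  df <- 4 * clock$theta * clock$mean_rate / clock$sigma2
  ncp <- x0 * exp(-clock$theta * dt) / c0
  out <- stats::dchisq(x / c0, df = df, ncp = ncp, log = TRUE) - log(c0)
  if (log) out else exp(out)
}
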