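# Amino-acid substitution models: 20-state equal-exchangeability ("Poisson")
# and LG, both with empirical or equal frequencies, normalized to one expected
# substitution per site per unit branch length.

AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Amino-acid substitution model
#'
#' Builds the rate matrix and stationary frequencies for the likelihood
#' engine and the sequence simulator. `"poisson"` is the 20-state equal-rates,
#' equal-frequency chain; `"lg"` uses the LG exchangeabilities and empirical
#' frequencies (taken from phangorn's model tables). Q is scaled so that the
#' expected number of substitutions per site per unit branch length is 1.
#'
#' @param model `"poisson"` or `"lg"`.
#' @return list with `name`, `Q` (20x20 rate matrix, rows = `AA_STATES`),
#'   `pi` (stationary frequencies).
#' @export
subst_model <- function(model = c("poisson", "lg")) {
  model <- match.arg(model)
  if (model == "poisson") {
    pi <- rep(1 / 20, 20)
    ex <- matrix(1, 20, 20)
  } else {
    lg <- lg_params()
    pi <- lg$bf
    ex <- matrix(0, 20, 20)
    ex[lower.tri(ex)] <- lg$Q
    ex <- ex + t(ex)
  }
  Q <- ex %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(AA_STATES, AA_STATES)
  names(pi) <- AA_STATES
  list(name = model, Q = Q, pi = pi)
}

# LG exchangeabilities (lower triangle, phangorn order a r n d c q e g h i l
# k m f p s t w y v = AA_STATES) and base frequencies from phangorn's
# internal amino-acid model table.
lg_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- utils::getFromNamespace("getModelAA", "phangorn")
      Q <- NULL; bf <- NULL
      f("LG", bf = TRUE, Q = TRUE, has_gap_state = FALSE)
      cache <<- list(Q = Q, bf = unname(bf))
    }
    cache
  }
})

#' Discrete-gamma site-rate categories
#'
#' Mean rates of `ncat` equal-probability bins of a Gamma(shape, shape)
#' distribution (mean 1), the standard discrete approximation to
#' among-site rate variation.
#'
#' @param shape gamma shape parameter (smaller = more heterogeneity).
#' @param ncat number of categories (default 4).
#' @return numeric vector of `ncat` relative rates with mean 1.
#' @export
gamma_site_rates <- function(shape, ncat = 4L) {
  if (ncat == 1L || !is.finite(shape)) return(rep(1, ncat))
  stopifnot(shape > 0)
  q <- stats::qgamma(seq(0, 1, length.out = ncat + 1L), shape, shape)
  # mean within each bin via the incomplete-gamma identity
  p <- stats::pgamma(q, shape + 1, shape)
  r <- ncat * diff(p)
  r / mean(r)
}

# Eigen-decomposition of a reversible Q for fast P(t): with D = diag(pi),
# B = D^{1/2} Q D^{-1/2} is symmetric; P(t) = A exp(L t) Ainv.
model_eigen <- function(model) {
  s <- sqrt(model$pi)
  B <- diag(s) %*% model$Q %*% diag(1 / s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       A = diag(1 / s) %*% e$vectors,
       Ainv = t(e$vectors) %*% diag(s))
}

# Transition probability matrix for branch length t (expected subs/site).
transition_matrix <- function(eig, t) {
  P <- eig$A %*% (exp(eig$values * t) * eig$Ainv)
  P[P < 0] <- 0
  P / rowSums(P)
}
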