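#' Fossil calibration constraints
#'
#' A calibration constrains the age of the most recent common ancestor of a
#' taxon set to lie above a fossil minimum age, softly: a small prior mass
#' (`soft_mass`, default 0.05) is allowed below the bound.
#'
#' @param label short label (Table-style letters `a`..`i`).
#' @param clade clade name, resolved to a taxon set via `clade_defs`.
#' @param min_age fossil minimum age in Ma (> 0).
#' @param soft_mass prior mass allowed below the bound, in (0, 0.5).
#' @return one-row `data.frame`.
#' @export
calibration <- function(label, clade, min_age, soft_mass = 0.05) {
  stopifnot(min_age > 0, soft_mass > 0, soft_mass < 0.5)
  data.frame(label = label, clade = clade, min_age = min_age,
             soft_mass = soft_mass, stringsAsFactors = FALSE)
}

#' The pteropod fossil calibration table
#'
#' The eight pteropod minimum-age calibrations plus the aplysiidan outgroup
#' calibration: Diacria 7.2 Ma (Tortonian), Cavolinia+Diacavolinia+Diacria
#' 28.1 Ma (Rupelian), Cavolinia+Diacavolinia 16 Ma (late Burdigalian),
#' Cavolinioidea 47.8 Ma (Ypresian), Limacina 47.8 Ma (Ypresian), the oldest
#' pteropod (a Campanian coiled shell) 72.1 Ma on either Limacinoidea or
#' Euthecosomata, Pseudothecosomata 16 Ma, Gymnosomata 23 Ma (Chattian), and
#' Akera on Pteropoda+Aplysia at 133 or 163.1 Ma depending on which fossil
#' record of the genus is trusted.
#'
#' @param soft_mass soft-bound mass (default 0.05).
#' @return `data.frame` of the eight ingroup calibrations (`a`..`h`), with
#'   the movable `f` clade left as `"__heliconoides__"` to be resolved by
#'   the scheme.
#' @export
pteropod_calibration_table <- function(soft_mass = 0.05) {
  rbind(
    calibration("a", "Diacria", 7.2, soft_mass),
    calibration("b", "Cavolinia_Diacavolinia_Diacria", 28.1, soft_mass),
    calibration("c", "Cavolinia_Diacavolinia", 16, soft_mass),
    calibration("d", "Cavolinioidea", 47.8, soft_mass),
    calibration("e", "Limacina", 47.8, soft_mass),
    calibration("f", "__heliconoides__", 72.1, soft_mass),
    calibration("g", "Pseudothecosomata", 16, soft_mass),
    calibration("h", "Gymnosomata", 23, soft_mass))
}

#' Calibration schemes s1-s6
#'
#' The six combinations of the Akera outgroup calibration (163.1 Ma, 133 Ma
#' or omitted) and the placement of the oldest pteropod fossil (oldest
#' Euthecosomata vs oldest Limacinoidea).
#'
#' @param id one of `"s1"`..`"s6"`.
#' @return list with `id`, `akera_age` (`NA` = omitted), `heliconoides_node`.
#' @export
calibration_scheme <- function(id = c("s1", "s2", "s3", "s4", "s5", "s6")) {
  id <- match.arg(id)
  grid <- list(
    s1 = list(akera_age = 163.1, heliconoides_node = "Euthecosomata"),
    s2 = list(akera_age = 133,   heliconoides_node = "Euthecosomata"),
    s3 = list(akera_age = 163.1, heliconoides_node = "Limacinoidea"),
    s4 = list(akera_age = 133,   heliconoides_node = "Limacinoidea"),
    s5 = list(akera_age = NA,    heliconoides_node = "Euthecosomata"),
    s6 = list(akera_age = NA,    heliconoides_node = "Limacinoidea"))
  c(list(id = id), grid[[id]])
}

#' Resolve a calibration scheme on a tree
#'
#' Maps each calibration clade to its crown (MRCA) node and emits the final
#' calibration set: the eight pteropod calibrations, with the movable one
#' attached per the scheme, plus the Akera calibration on Pteropoda+Aplysia
#' when the scheme includes it (9 calibrations for s1-s4, 8 for s5-s6).
#'
#' @param scheme a [calibration_scheme()] (or its id string).
#' @param tree a [dated_tree()].
#' @param clade_defs named list: clade name -> character vector of tips.
#'   Must resolve every clade used by the scheme.
#' @param soft_mass soft-bound mass (default 0.05).
#' @return `data.frame` with columns `label`, `clade`, `node` (ape node id),
#'   `min_age`, `soft_mass`.
#' @export
build_calibration_set <- function(scheme, tree, clade_defs,
                                  soft_mass = 0.05) {
  if (is.character(scheme)) scheme <- calibration_scheme(scheme)
  if (length(clade_defs) == 0L) stop("mapping-error: empty clade definitions")
  tab <- pteropod_calibration_table(soft_mass)
  tab$clade[tab$label == "f"] <- scheme$heliconoides_node
  if (!is.na(scheme$akera_age))
    tab <- rbind(tab, calibration("i", "Pteropoda_Aplysia",
                                  scheme$akera_age, soft_mass))
  miss <- setdiff(tab$clade, names(clade_defs))
  if (length(miss))
    stop("mapping-error: unresolved clade(s): ", paste(miss, collapse = ", "))
  tab$node <- vapply(tab$clade, function(cl)
    mrca_node(tree, clade_defs[[cl]]), 0L)
  if (anyDuplicated(tab$node))
    stop("mapping-error: two calibrations attach to the same node")
  tab[c("label", "clade", "node", "min_age", "soft_mass")]
}

#' Soft minimum-bound log-density
#'
#' The two-piece calibration density on an admissible age range
#' `(lower, upper)`: a constant plateau on `[min_age, upper)` carrying mass
#' `1 - soft_mass`, and an exponential ramp on `(lower, min_age)` carrying
#' mass `soft_mass`, continuous at the bound. By construction a node whose
#' prior is this density violates its fossil minimum with probability
#' exactly `soft_mass`. (When the plateau is so wide that a continuous ramp
#' cannot carry the required mass, the ramp degrades to a uniform slab with
#' the same mass.)
#'
#' @param age evaluation age(s), Ma.
#' @param cal one-row calibration (from [calibration()]).
#' @param lower,upper admissible age range, e.g. `(0, root age)`.
#' @return log-density value(s).
#' @export
calibration_log_factor <- function(age, cal, lower = 0, upper = 200) {
  vapply(age, function(a)
    softbound_lp(a, m = cal$min_age, q = cal$soft_mass, L = lower,
                 plateau = list(kind = "uniform", upper = upper)),
    0)
}

# ---- two-piece soft-bound machinery ---------------------------------------
# plateau: list(kind = "uniform"|"gamma"|"bd", ...) describing the density
# shape at/above the bound, normalized to carry mass (1 - q) there.

plateau_lp <- function(x, m, q, plateau) {
  switch(plateau$kind,
    uniform = log1p(-q) - log(plateau$upper - m),
    gamma = log1p(-q) +
      stats::dgamma(x, plateau$shape, plateau$rate, log = TRUE) -
      stats::pgamma(m, plateau$shape, plateau$rate, lower.tail = FALSE,
                    log.p = TRUE),
    bd = log1p(-q) + bd_kernel_lp(x, plateau$bd) -
      log(bd_kernel_V(plateau$upper, plateau$bd) - bd_kernel_V(m, plateau$bd)))
}

# density value (not log) of the plateau at its left edge, for continuity
plateau_at_m <- function(m, q, plateau) exp(plateau_lp(m, m, q, plateau))

# solve the ramp scale s: v * s * (1 - exp(-(m-L)/s)) = q
ramp_scale <- function(v, m, L, q) {
  width <- m - L
  if (v * width <= q) return(NA_real_)  # continuity infeasible -> uniform slab
  f <- function(logs) {
    s <- exp(logs)
    v * s * (1 - exp(-width / s)) - q
  }
  exp(stats::uniroot(f, lower = log(q / v) - 30, upper = log(1e6 * width),
                     tol = 1e-12)$root)
}

ramp_lp <- function(x, m, L, q, v) {
  s <- ramp_scale(v, m, L, q)
  if (is.na(s)) return(log(q) - log(m - L))       # uniform slab fallback
  log(v) + (x - m) / s
}

# full two-piece log-density at x, support (L, upper-of-plateau)
softbound_lp <- function(x, m, q, L, plateau) {
  up <- if (plateau$kind == "gamma") Inf else plateau$upper
  if (x <= L || x >= up) return(-Inf)
  if (up <= m) {
    # admissible range entirely below the bound (transient MCMC state when a
    # parent dips under a descendant minimum): uniform on what remains
    return(-log(up - L))
  }
  if (m <= L) {
    # bound below the support: the minimum is vacuous, plateau-only density
    return(plateau_lp(x, L, 0, plateau))
  }
  if (x >= m) return(plateau_lp(x, m, q, plateau))
  ramp_lp(x, m, L, q, plateau_at_m(m, q, plateau))
}

# draw one value from the two-piece density
softbound_draw <- function(m, q, L, plateau) {
  up <- if (plateau$kind == "gamma") Inf else plateau$upper
  if (m <= L) { m <- L; q <- 0 }
  if (stats::runif(1L) < q) {
    v <- plateau_at_m(m, q, plateau)
    s <- ramp_scale(v, m, L, q)
    p <- stats::runif(1L)
    if (is.na(s)) return(L + p * (m - L))
    m + s * log(p * q / (v * s) + exp((L - m) / s))
  } else {
    p <- stats::runif(1L)
    switch(plateau$kind,
      uniform = m + p * (plateau$upper - m),
      gamma = {
        pm <- stats::pgamma(m, plateau$shape, plateau$rate)
        stats::qgamma(pm + p * (1 - pm), plateau$shape, plateau$rate)
      },
      bd = {
        Vm <- bd_kernel_V(m, plateau$bd)
        Vu <- bd_kernel_V(plateau$upper, plateau$bd)
        bd_kernel_quantile(Vm + p * (Vu - Vm), plateau$bd)
      })
  }
}

# ---- birth-death kernel ----------------------------------------------------
# Conditioned reconstructed-process node-age kernel with sampling fraction
# rho: V'(t) = rho r^2 exp(-rt) / D(t)^2, D(t) = rho*lambda +
# (lambda(1-rho) - mu) exp(-rt), r = lambda - mu. V is its antiderivative
# with V(0) = 0; node ages given the root age T are i.i.d. with density
# V'(t)/V(T) on (0, T).

bd_kernel_V <- function(t, bd) {
  r <- bd$lambda - bd$mu
  if (abs(r) < 1e-10) r <- 1e-10
  e <- exp(-r * t)
  bd$rho * (1 - e) / (bd$rho * bd$lambda + (bd$lambda * (1 - bd$rho) - bd$mu) * e)
}

bd_kernel_lp <- function(t, bd) {
  r <- bd$lambda - bd$mu
  if (abs(r) < 1e-10) r <- 1e-10
  e <- exp(-r * t)
  D <- bd$rho * bd$lambda + (bd$lambda * (1 - bd$rho) - bd$mu) * e
  log(bd$rho) + 2 * log(abs(r)) - r * t - 2 * log(D)
}

bd_kernel_quantile <- function(V, bd) {
  r <- bd$lambda - bd$mu
  if (abs(r) < 1e-10) r <- 1e-10
  beta <- bd$lambda * (1 - bd$rho) - bd$mu
  y <- bd$rho * (1 - V * bd$lambda) / (bd$rho + V * beta)
  -log(y) / r
}
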