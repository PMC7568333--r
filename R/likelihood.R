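# R-side wrapper around the C++ pruning engine.

#' Build a reusable pruning-likelihood engine
#'
#' Compresses the supermatrix into unique site patterns and sets up cached
#' conditional likelihoods on the given topology. The returned engine is used
#' by [log_likelihood()], [run_mcmc()] and [cross_validate()]; branch lengths
#' are supplied later as expected substitutions per site, indexed by the
#' child node of each branch (ape node numbering).
#'
#' @param sm a `supermatrix` (or a [gene_alignment()], treated as one gene).
#' @param tree a [dated_tree()] carrying the fixed topology. Every supermatrix
#'   taxon must be a tip; tips missing from the matrix get all-unknown rows.
#' @param model `"poisson"` or `"lg"` (see [subst_model()]).
#' @param gamma_categories discrete-gamma categories (default 4).
#' @param gamma_shape initial shape for the site-rate categories.
#' @return object of class `pruning_likelihood`.
#' @export
make_pruning_likelihood <- function(sm, tree, model = "poisson",
                                    gamma_categories = 4L, gamma_shape = 0.8) {
  if (inherits(sm, "gene_alignment"))
    sm <- concatenate_alignments(list(sm), alignment_taxa(sm))
  tips <- tree$phy$tip.label
  extra <- setdiff(rownames(sm$mat), tips)
  if (length(extra))
    stop("roster-error: matrix taxa not on tree: ", paste(extra, collapse = ", "))
  n <- length(tips)
  states <- matrix(-1L, nrow = ncol(sm$mat), ncol = n)
  for (i in seq_len(n)) {
    if (tips[i] %in% rownames(sm$mat)) {
      s <- match(sm$mat[tips[i], ], AA_STATES) - 1L
      s[is.na(s)] <- -1L
      states[, i] <- s
    }
  }
  key <- apply(states, 1L, paste, collapse = ",")
  upat <- !duplicated(key)
  wts <- as.numeric(table(factor(key, levels = key[upat])))
  states <- states[upat, , drop = FALSE]
  mod <- subst_model(model)
  eig <- model_eigen(mod)
  ptr <- plik_build(tree$phy$edge, n, states, wts, unname(mod$pi),
                    eig$values, eig$A, eig$Ainv, as.integer(gamma_categories))
  structure(list(ptr = ptr, n_tip = n, n_node = n + tree$phy$Nnode,
                 edge = tree$phy$edge, model = model,
                 gamma_categories = as.integer(gamma_categories),
                 gamma_shape = gamma_shape, n_sites = ncol(sm$mat),
                 n_patterns = nrow(states)),
            class = "pruning_likelihood")
}

#' @export
print.pruning_likelihood <- function(x, ...) {
  cat("pruning_likelihood: ", x$n_tip, " taxa, ", x$n_sites, " sites (",
      x$n_patterns, " patterns), ", x$model, "+G", x$gamma_categories,
      "\n", sep = "")
  invisible(x)
}

# full recompute; edge_len indexed by child node id, gamma shape optional
plik_full <- function(lik, edge_len, gamma_shape = lik$gamma_shape) {
  rates <- gamma_site_rates(gamma_shape, lik$gamma_categories)
  plik_set(lik$ptr, edge_len, rates)
}

#' Phylogenetic log-likelihood of a supermatrix
#'
#' Felsenstein pruning over unique site patterns with a discrete-gamma
#' site-rate mixture, on the fixed topology of `tree` with branch expected
#' substitutions = branch rate x branch duration.
#'
#' @inheritParams make_pruning_likelihood
#' @param rates positive branch rates (substitutions/site/Myr) indexed by the
#'   child node of each branch; entries for the root are ignored.
#' @param ages optional node-age vector overriding `node_ages(tree)`.
#' @return log-likelihood (single number).
#' @export
log_likelihood <- function(sm, tree, rates, model = "poisson",
                           gamma_categories = 4L, gamma_shape = 0.8,
                           ages = NULL) {
  if (is.null(ages)) ages <- node_ages(tree)
  durs <- branch_durations(tree, ages)
  if (any(durs < -1e-12, na.rm = TRUE))
    stop("domain-error: negative branch duration")
  lik <- make_pruning_likelihood(sm, tree, model, gamma_categories, gamma_shape)
  el <- durs * rates
  el[is.na(el)] <- 0
  plik_full(lik, el)
}

# durations indexed by child node (root entry NA)
branch_durations <- function(tree, ages = node_ages(tree)) {
  durs <- rep(NA_real_, length(ages))
  durs[tree$phy$edge[, 2L]] <- ages[tree$phy$edge[, 1L]] - ages[tree$phy$edge[, 2L]]
  durs
}
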