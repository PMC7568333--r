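#' Simulate gene alignments along a chronogram
#'
#' Evolves amino-acid sites down the tree under the chosen substitution model
#' with discrete-gamma site-rate heterogeneity; branch expected substitutions
#' are `branch rate x duration`. Per gene, a length is drawn uniformly in
#' `len_range` and whole taxa are deleted independently with probability
#' `p_missing` (resampled if a deletion would empty the gene), emulating the
#' patchy taxon occupancy of transcriptome-derived orthologs.
#'
#' @param tree a [dated_tree()].
#' @param rates result of [sim_branch_rates()] (or a plain branch-rate vector
#'   indexed by child node).
#' @param n_genes number of genes.
#' @param len_range integer vector `c(min, max)` of gene lengths.
#' @param p_missing per-gene, per-taxon deletion probability in `[0, 1)`.
#' @param model `"poisson"` or `"lg"`.
#' @param gamma_shape site-rate gamma shape (default 0.8); `Inf` disables.
#' @param gamma_categories discrete categories (default 4).
#' @param seed integer seed.
#' @return named list of [gene_alignment()] objects (`g001`, `g002`, ...).
#' @export
sim_alignments <- function(tree, rates, n_genes = 20, len_range = c(300, 300),
                           p_missing = 0.2, model = "poisson",
                           gamma_shape = 0.8, gamma_categories = 4L,
                           seed = 1L) {
  stopifnot(p_missing >= 0, p_missing < 1)
  set.seed(as.integer(seed))
  br <- if (is.list(rates)) rates$branch else rates
  durs <- branch_durations(tree)
  el <- br * durs                       # expected subs per site, by child node
  mod <- subst_model(model)
  eig <- model_eigen(mod)
  st <- tree_structure(tree)
  tips <- tree$phy$tip.label
  cat_rates <- gamma_site_rates(gamma_shape, gamma_categories)
  out <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    len <- if (len_range[1] == len_range[2]) len_range[1] else
      sample(len_range[1]:len_range[2], 1L)
    site_cat <- sample.int(length(cat_rates), len, replace = TRUE)
    states <- matrix(0L, nrow = length(st$parent), ncol = len)
    states[st$root, ] <- sample.int(20L, len, replace = TRUE, prob = mod$pi)
    for (v in rev(st$postorder)) for (ch in st$children[[v]]) {
      states[ch, ] <- evolve_sites(states[v, ], el[ch] * cat_rates[site_cat], eig)
    }
    repeat {
      keep <- stats::runif(length(tips)) >= p_missing
      if (any(keep)) break
    }
    m <- matrix(AA_STATES[states[seq_along(tips), , drop = FALSE]],
                nrow = length(tips), dimnames = list(tips, NULL))
    out[[g]] <- gene_alignment(sprintf("g%03d", g), m[keep, , drop = FALSE])
  }
  stats::setNames(out, vapply(out, function(x) x$gene_id, ""))
}

# Draw child states site-by-site; sites are grouped by (parent state,
# rounded branch length class) cheaply: here lengths vary per site through
# the gamma category, so group by (state, category length value).
evolve_sites <- function(parent_states, site_len, eig) {
  child <- integer(length(parent_states))
  for (lv in unique(site_len)) {
    P <- transition_matrix(eig, lv)
    idx_l <- which(site_len == lv)
    for (s in unique(parent_states[idx_l])) {
      idx <- idx_l[parent_states[idx_l] == s]
      child[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[s, ])
    }
  }
  child
}
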