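# Brute-force likelihood oracle: sums over all internal-state assignments.
# Independent of the C++ pruning engine (uses only the model matrices).
brute_force_loglik <- function(g, tree, rates, model, ncat, shape) {
  mod <- pterochron:::subst_model(model)
  eig <- pterochron:::model_eigen(mod)
  crates <- gamma_site_rates(shape, ncat)
  phy <- tree$phy
  n <- length(phy$tip.label)
  durs <- pterochron:::branch_durations(tree)
  el <- rates * durs
  nint <- phy$Nnode
  states <- lapply(phy$tip.label, function(tx)
    match(g$mat[tx, ], pterochron:::AA_STATES))
  nsite <- ncol(g$mat)
  grid <- as.matrix(expand.grid(rep(list(1:20), nint)))
  total <- 0
  for (s in seq_len(nsite)) {
    Lsite <- 0
    for (k in seq_along(crates)) {
      P <- lapply(seq_len(n + nint), function(v)
        if (!is.na(el[v])) pterochron:::transition_matrix(eig, el[v] * crates[k]))
      tipstate <- vapply(states, `[[`, 0L, s)
      vals <- apply(grid, 1L, function(int_states) {
        assign <- c(tipstate, int_states)
        v <- mod$pi[int_states[1L]]
        for (e in seq_len(nrow(phy$edge))) {
          pa <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
          xc <- assign[ch]
          v <- v * if (ch <= n && is.na(xc)) 1 else P[[ch]][assign[pa], xc]
        }
        v
      })
      Lsite <- Lsite + sum(vals) / length(crates)
    }
    total <- total + log(Lsite)
  }
  total
}
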