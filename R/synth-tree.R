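#' Simulate a birth-death chronogram
#'
#' Forward constant-rate birth-death simulation, rejected and rerun until the
#' process is alive with exactly `n_taxa` extant lineages at the stopping
#' time, then uniformly rescaled so the root (first split) age equals
#' `root_age`. Deterministic given the seed.
#'
#' @param n_taxa number of extant tips (>= 2).
#' @param lambda birth rate (events/lineage/Myr).
#' @param mu death rate (< lambda).
#' @param root_age target root age in Ma.
#' @param seed integer seed.
#' @param tip_prefix tip label prefix.
#' @return a [dated_tree()].
#' @export
sim_chronogram <- function(n_taxa, lambda = 0.1, mu = 0.03, root_age = 150,
                           seed = 1L, tip_prefix = "t") {
  stopifnot(n_taxa >= 2, lambda > mu, mu >= 0, root_age > 0)
  set.seed(as.integer(seed))
  repeat {
    phy <- bd_forward(n_taxa, lambda, mu)
    if (!is.null(phy)) break
  }
  phy$tip.label <- paste0(tip_prefix, seq_len(n_taxa))
  tr <- dated_tree(phy)
  ages <- node_ages(tr) * (root_age / root_age(tr))
  set_node_ages(tr, ages)
}

# One forward pass: start from the root split (2 lineages), run until the
# n-th extant lineage appears, and stop the tree at that moment minus a
# uniform fraction of the waiting time to the next event (so tip count is
# exactly n at the sampling time). Returns NULL if the clade dies or the
# simulation stalls.
bd_forward <- function(n, lambda, mu) {
  # live lineages: rows (id, parent_node, t_start); events build an edge list
  max_events <- 200L * n
  # node bookkeeping: we assemble edges as (parent, child, t_parent, t_child)
  edges <- matrix(numeric(0), ncol = 4L)
  next_id <- 3L                       # 1 = root's first child, 2 = second
  live_id <- c(1L, 2L)
  live_t0 <- c(0, 0)                  # lineage start times (root split at 0)
  t <- 0
  for (ev in seq_len(max_events)) {
    k <- length(live_id)
    if (k == 0L) return(NULL)
    rate <- k * (lambda + mu)
    wait <- stats::rexp(1L, rate)
    if (k == n) {
      # stop inside this waiting interval: all live lineages become tips
      t_stop <- t + stats::runif(1L, 0, wait)
      for (i in seq_len(k))
        edges <- rbind(edges, c(live_id[i], NA, live_t0[i], t_stop))
      return(assemble_phylo(edges, t_stop))
    }
    t <- t + wait
    i <- sample.int(k, 1L)
    if (stats::runif(1L) < lambda / (lambda + mu)) {
      # speciation: lineage i ends, two children start
      edges <- rbind(edges, c(live_id[i], next_id, live_t0[i], t),
                     c(live_id[i], next_id + 1L, live_t0[i], t))
      # the two child lineages replace the parent
      live_id <- c(live_id[-i], next_id, next_id + 1L)
      live_t0 <- c(live_t0[-i], t, t)
      next_id <- next_id + 2L
    } else {
      # extinction: the lineage disappears without leaving a record; its
      # ancestors are spliced or rejected during assembly
      live_id <- live_id[-i]
      live_t0 <- live_t0[-i]
    }
  }
  NULL
}

# Build an ape phylo from lineage records. Each internal lineage id appears
# as the parent of exactly two child records; extinct lineages left no
# record and are pruned implicitly because only survivor paths reach tips.
assemble_phylo <- function(edges, t_stop) {
  tip_rows <- which(is.na(edges[, 2L]))
  n <- length(tip_rows)
  if (n < 2L) return(NULL)
  kids <- split(seq_len(nrow(edges)), edges[, 1L])
  # condition on both root children leaving extant descendants
  s1 <- tryCatch(newick_survivor(1L, 0, edges, kids, t_stop), error = function(e) NULL)
  s2 <- tryCatch(newick_survivor(2L, 0, edges, kids, t_stop), error = function(e) NULL)
  if (is.null(s1) || is.null(s2)) return(NULL)
  phy <- ape::read.tree(text = sprintf("(%s,%s);", s1, s2))
  if (length(phy$tip.label) != n) return(NULL)
  phy
}

# Newick for the surviving part of the subtree rooted at lineage id; error
# (caught above) if the whole subtree is extinct. A lineage with exactly one
# surviving child is spliced out (its duration merges with the child's).
newick_survivor <- function(id, t0, edges, kids, t_stop) {
  rows <- kids[[as.character(id)]]
  child_rows <- rows[!is.na(edges[rows, 2L])]
  tip_row <- rows[is.na(edges[rows, 2L])]
  if (length(tip_row)) {
    return(sprintf("L%d:%.10f", id, t_stop - t0))
  }
  if (length(child_rows) == 0L) stop("extinct")
  t_split <- edges[child_rows[1L], 4L]
  subs <- list()
  for (r in child_rows) {
    s <- tryCatch(newick_survivor(edges[r, 2L], t_split, edges, kids, t_stop),
                  error = function(e) NULL)
    if (!is.null(s)) subs <- c(subs, s)
  }
  if (length(subs) == 0L) stop("extinct")
  if (length(subs) == 1L) {
    # splice: extend the child's pendant duration by (t_split - t0)
    s <- subs[[1L]]
    # bump the outermost branch length
    m <- regmatches(s, regexpr(":[0-9.eE+-]+$", s))
    len <- as.numeric(substring(m, 2)) + (t_split - t0)
    return(sub(":[0-9.eE+-]+$", sprintf(":%.10f", len), s))
  }
  sprintf("(%s,%s):%.10f", subs[[1L]], subs[[2L]], t_split - t0)
}
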