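#' Dated ultrametric trees
#'
#' A `dated_tree` wraps a rooted, binary `ape::phylo` object whose branch
#' lengths are durations in Myr, together with the vector of node ages (Ma)
#' implied by those durations. All tips are extant (age 0), so the tree is
#' ultrametric; ages are derived from durations with root age = maximum
#' tip-to-root path length.
#'
#' @param phy a rooted binary `phylo` with branch lengths in Myr.
#' @param tol relative ultrametricity tolerance (fraction of root age).
#' @return object of class `dated_tree` with elements `phy` (the `phylo`) and
#'   `ages` (numeric, indexed by ape node number: tips `1..n`, then internals).
#' @export
dated_tree <- function(phy, tol = 1e-9) {
  if (!inherits(phy, "phylo")) stop("tree-error: not a phylo object")
  if (is.null(phy$edge.length)) stop("tree-error: no branch lengths")
  if (!ape::is.rooted(phy)) stop("tree-error: tree must be rooted")
  if (!ape::is.binary(phy)) stop("tree-error: tree must be binary (no polytomies)")
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)   # root-to-node path lengths
  root_age <- max(depth[seq_len(n)])
  if (root_age <= 0) stop("tree-error: root age must be > 0")
  if (max(depth[seq_len(n)]) - min(depth[seq_len(n)]) > tol * root_age)
    stop("tree-error: tree is not ultrametric (tip depths differ by ",
         format(max(depth[seq_len(n)]) - min(depth[seq_len(n)])), " Myr)")
  ages <- root_age - depth
  ages[seq_len(n)] <- 0
  structure(list(phy = phy, ages = ages), class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("dated_tree: ", length(x$phy$tip.label), " tips, root age ",
      format(root_age(x), digits = 6), " Ma\n", sep = "")
  invisible(x)
}

#' @rdname dated_tree
#' @param tree a `dated_tree`.
#' @export
node_ages <- function(tree) tree$ages

#' @rdname dated_tree
#' @export
root_age <- function(tree) tree$ages[length(tree$phy$tip.label) + 1L]

#' @rdname dated_tree
#' @export
n_tips <- function(tree) length(tree$phy$tip.label)

#' Rebuild a dated tree from a node-age vector
#'
#' Keeps the topology of `tree` and sets branch durations to
#' `age(parent) - age(child)`.
#'
#' @param tree a [dated_tree()].
#' @param ages numeric vector of node ages indexed like `node_ages(tree)`.
#' @export
set_node_ages <- function(tree, ages) {
  phy <- tree$phy
  durs <- ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]]
  if (any(durs < 0)) stop("tree-error: a parent is younger than its child")
  phy$edge.length <- durs
  out <- tree
  out$phy <- phy
  out$ages <- ages
  out
}

#' Read a dated tree from Newick
#'
#' Branch lengths are interpreted as durations in Myr; node ages are
#' reconstructed (root age = maximum tip-to-root path) and ultrametricity is
#' verified to a relative tolerance of `tol` times the root age.
#'
#' @inheritParams dated_tree
#' @param path Newick file path.
#' @return a [dated_tree()].
#' @export
read_newick_dated <- function(path, tol = 1e-9) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("tree-error: could not parse Newick file")
  dated_tree(phy, tol = tol)
}

#' Write a dated tree to Newick
#'
#' Branch lengths are durations in Myr. With `labels = TRUE`, internal node
#' labels (e.g. clade names or posterior-mean annotations set on
#' `tree$phy$node.label`) are emitted.
#'
#' @param tree a [dated_tree()].
#' @param path output path.
#' @param labels emit internal node labels?
#' @param digits significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_newick_dated <- function(tree, path, labels = FALSE, digits = 12) {
  phy <- tree$phy
  if (!labels) phy$node.label <- NULL
  ape::write.tree(phy, file = path, digits = digits)
  invisible(path)
}

#' Most recent common ancestor
#'
#' @param tree a [dated_tree()].
#' @param taxa character vector of tip labels (nonempty subset of the tips).
#' @return ape node number of the MRCA; for a single taxon, the tip itself.
#' @export
mrca_node <- function(tree, taxa) {
  tips <- tree$phy$tip.label
  unknown <- setdiff(taxa, tips)
  if (length(unknown))
    stop("lookup-error: unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) == 0L) stop("lookup-error: empty taxon set")
  if (length(taxa) == 1L) return(match(taxa, tips))
  ape::getMRCA(tree$phy, taxa)
}

# parent vector indexed by node (root = NA), and children list, postorder of
# internal nodes (children before parents). Shared by the prior/MCMC code.
tree_structure <- function(tree) {
  phy <- tree$phy
  n <- length(phy$tip.label)
  m <- phy$Nnode
  nn <- n + m
  parent <- rep(NA_integer_, nn)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  children <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge)))
    children[[phy$edge[i, 1L]]] <- c(children[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  # postorder over internal nodes
  po <- integer(0)
  stack <- n + 1L
  seen <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    kids <- children[[v]]
    stack <- c(stack, kids[kids > n])
  }
  po <- rev(seen)
  list(n_tip = n, n_node = m, parent = parent, children = children,
       postorder = po, root = n + 1L)
}
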