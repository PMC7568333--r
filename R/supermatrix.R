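#' Ortholog occupancy filtering
#'
#' Keeps genes represented by at least `min_outgroup` outgroup taxa and at
#' least `ceiling(min_ingroup_frac * n_ingroup)` ingroup taxa, the occupancy
#' rule used to assemble the phylogenomic matrix. Genes with any taxon at
#' copy number > 1 are assumed excluded upstream (single-copy orthologs).
#'
#' @param genes named list of [gene_alignment()] objects (names = gene ids),
#'   or a presence `data.frame` with columns `gene_id`, `taxon`.
#' @param ingroup,outgroup character vectors of taxon names (disjoint).
#' @param min_outgroup minimum number of outgroup taxa present (default 1).
#' @param min_ingroup_frac minimum fraction of ingroup taxa present
#'   (default 0.5, i.e. "at least half"; the threshold count is the ceiling).
#' @return character vector of kept gene ids.
#' @export
select_single_copy <- function(genes, ingroup, outgroup,
                               min_outgroup = 1, min_ingroup_frac = 0.5) {
  if (length(ingroup) == 0L && length(outgroup) == 0L)
    stop("config-error: empty taxon roster")
  if (length(intersect(ingroup, outgroup)))
    stop("config-error: ingroup and outgroup overlap")
  need_in <- ceiling(min_ingroup_frac * length(ingroup))
  pres <- gene_presence(genes)
  keep <- vapply(pres, function(tx) {
    sum(tx %in% outgroup) >= min_outgroup && sum(tx %in% ingroup) >= need_in
  }, logical(1))
  names(pres)[keep]
}

# named list gene_id -> taxa present
gene_presence <- function(genes) {
  if (is.data.frame(genes)) {
    split(genes$taxon, genes$gene_id)
  } else {
    nm <- names(genes)
    if (is.null(nm)) nm <- vapply(genes, function(g) g$gene_id, "")
    stats::setNames(lapply(genes, alignment_taxa), nm)
  }
}

#' Trim poorly supported alignment columns
#'
#' Two passes, mirroring gap/similarity alignment trimming: first drop
#' columns whose non-gap fraction is below `min_nongap_frac`, then drop
#' columns whose conservation score (frequency of the modal residue among
#' non-gap residues) is below `min_similarity`. Column order is preserved;
#' an alignment whose columns are all removed is returned empty with a
#' warning.
#'
#' @param aln a [gene_alignment()].
#' @param min_nongap_frac minimum fraction of non-gap residues (default 0.15).
#' @param min_similarity minimum modal-residue frequency (default 0.001).
#' @return trimmed [gene_alignment()].
#' @export
trim_columns <- function(aln, min_nongap_frac = 0.15, min_similarity = 0.001) {
  m <- aln$mat
  nongap <- colMeans(m != "-")
  m <- m[, nongap >= min_nongap_frac, drop = FALSE]
  if (ncol(m)) {
    sim <- apply(m, 2L, function(col) {
      res <- col[col != "-"]
      if (!length(res)) return(0)
      max(tabulate(factor(res, levels = unique(res)))) / length(res)
    })
    m <- m[, sim >= min_similarity, drop = FALSE]
  }
  if (ncol(m) == 0L) {
    warning("all columns removed from gene ", aln$gene_id)
    m <- matrix(character(0), nrow = nrow(aln$mat), ncol = 0,
                dimnames = list(rownames(aln$mat), NULL))
  }
  out <- aln
  out$mat <- m
  out
}

#' Concatenate gene alignments into a supermatrix
#'
#' Taxa absent from a gene are padded with `-` across that gene's partition.
#' The missing-data fraction counts both padded cells and within-alignment
#' gaps (`-`), over taxa x total columns.
#'
#' @param genes named list of [gene_alignment()] objects with unique ids.
#' @param taxa full taxon roster (every gene's taxa must be a subset).
#' @return object of class `supermatrix`: `mat` (character matrix taxa x
#'   columns), `partitions` (`data.frame` of `gene_id`, `start`, `end`,
#'   0-based half-open), `missing_fraction`.
#' @export
concatenate_alignments <- function(genes, taxa) {
  ids <- vapply(genes, function(g) g$gene_id, "")
  if (anyDuplicated(ids)) stop("format-error: duplicate gene ids")
  total <- sum(vapply(genes, alignment_length, 0L))
  mat <- matrix("-", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  start <- integer(length(genes)); end <- integer(length(genes))
  at <- 0L
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    extra <- setdiff(alignment_taxa(g), taxa)
    if (length(extra))
      stop("roster-error: taxa not in roster: ", paste(extra, collapse = ", "))
    w <- alignment_length(g)
    start[i] <- at; end[i] <- at + w
    mat[alignment_taxa(g), (at + 1L):(at + w)] <- g$mat
    at <- at + w
  }
  sm <- structure(list(mat = mat,
                       partitions = data.frame(gene_id = ids, start = start,
                                               end = end),
                       missing_fraction = NA_real_),
                  class = "supermatrix")
  sm$missing_fraction <- missing_fraction(sm)
  sm
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix: ", nrow(x$mat), " taxa x ", ncol(x$mat), " positions, ",
      nrow(x$partitions), " partitions, ",
      sprintf("%.2f%%", 100 * x$missing_fraction), " missing\n", sep = "")
  invisible(x)
}

#' Missing-data fraction of a supermatrix
#'
#' Recomputed from the matrix: the proportion of cells that are gaps
#' (including absent-taxon padding).
#'
#' @param sm a `supermatrix`.
#' @export
missing_fraction <- function(sm) {
  if (length(sm$mat) == 0L) return(0)
  mean(sm$mat == "-")
}

#' Write a supermatrix as relaxed PHYLIP plus a partition map
#'
#' @param sm a `supermatrix`.
#' @param path output PHYLIP path; the partition CSV goes to
#'   `paste0(path, ".partitions.csv")` with 1-based inclusive coordinates.
#' @export
write_supermatrix <- function(sm, path) {
  aln <- gene_alignment("supermatrix", sm$mat)
  write_alignment(aln, path, dialect = "phylip")
  parts <- transform(sm$partitions, start = start + 1L, end = end)
  utils::write.csv(parts, paste0(path, ".partitions.csv"), row.names = FALSE)
  invisible(path)
}

#' Per-gene bootstrap informativeness scores
#'
#' For each gene with at least four taxa: build a neighbor-joining tree from
#' pairwise distances corrected under the 20-state equal-rates model,
#' bootstrap alignment columns `n_boot` times, and score the gene by the mean
#' bootstrap percentage over the internal edges of the original tree. Genes
#' with fewer than four taxa are returned unscored (`NA`).
#'
#' @param genes named list of [gene_alignment()] objects.
#' @param n_boot bootstrap replicates (default 100).
#' @param seed integer seed for the bootstrap resampling.
#' @return `data.frame` with `gene_id`, `score` (percent, `NA` if unscored),
#'   `n_taxa`.
#' @export
gene_support_scores <- function(genes, n_boot = 100, seed = 1L) {
  ids <- vapply(genes, function(g) g$gene_id, "")
  res <- data.frame(gene_id = ids,
                    score = NA_real_,
                    n_taxa = vapply(genes, function(g) nrow(g$mat), 0L))
  set.seed(seed)
  for (i in seq_along(genes)) {
    m <- genes[[i]]$mat
    if (nrow(m) < 4L) next
    d <- aa_distance(m)
    tr <- ape::nj(d)
    counts <- ape::boot.phylo(tr, m, function(x) ape::nj(aa_distance(x)),
                              B = n_boot, rooted = FALSE, quiet = TRUE)
    # first element is the trivial all-taxa bipartition
    internal <- counts[-1L]
    if (length(internal))
      res$score[i] <- mean(internal) / n_boot * 100
  }
  res
}

# Pairwise distances corrected under the 20-state equal-rates chain:
# d = -(19/20) log(1 - (20/19) p), capped when p approaches saturation.
aa_distance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-" | m == "X"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) { d[i, j] <- d[j, i] <- 10; next }
    p <- mean(m[i, ok] != m[j, ok])
    d[i, j] <- d[j, i] <- if (p >= 0.94) 10 else -(19 / 20) * log(1 - 20 * p / 19)
  }
  stats::as.dist(d)
}

#' Select the top-scoring genes
#'
#' Top `k` by score; ties broken by larger taxon count, then lexicographic
#' gene id, so the result is deterministic and independent of input order.
#'
#' @param scores `data.frame` from [gene_support_scores()].
#' @param k number of genes to keep (default 200).
#' @return character vector of gene ids.
#' @export
select_top_genes <- function(scores, k = 200) {
  sc <- scores[!is.na(scores$score), , drop = FALSE]
  if (nrow(sc) < k) {
    warning("only ", nrow(sc), " scored genes available (asked for ", k, ")")
    k <- nrow(sc)
  }
  ord <- order(-sc$score, -sc$n_taxa, sc$gene_id)
  sc$gene_id[ord][seq_len(k)]
}
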