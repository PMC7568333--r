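test_that("occupancy selection applies the outgroup/ingroup thresholds", {
  ingroup <- paste0("in", 1:28)
  outgroup <- c("out1", "out2", "out3")
  mk <- function(id, taxa) gene_alignment(id, stats::setNames(
    rep("MK", length(taxa)), taxa))
  genes <- list(
    ok   = mk("ok", c(ingroup[1:14], "out1")),     # 14 = ceil(0.5*28), 1 out
    few  = mk("few", c(ingroup[1:13], outgroup)),  # 13 ingroup: dropped
    noout = mk("noout", ingroup[1:20]))            # no outgroup: dropped
  keep <- select_single_copy(genes, ingroup, outgroup)
  expect_identical(keep, "ok")
  # the same selection works from a presence table
  pres <- do.call(rbind, lapply(names(genes), function(id)
    data.frame(gene_id = id, taxon = alignment_taxa(genes[[id]]),
               copy_number = 1L)))
  expect_identical(select_single_copy(pres, ingroup, outgroup), "ok")
  all_keep <- select_single_copy(genes, ingroup, outgroup,
                                 min_outgroup = 0, min_ingroup_frac = 0)
  expect_setequal(all_keep, names(genes))
  # monotone: raising thresholds never adds genes
  for (mo in 0:2) for (fr in c(0, 0.25, 0.5, 0.75)) {
    k1 <- select_single_copy(genes, ingroup, outgroup, mo, fr)
    k2 <- select_single_copy(genes, ingroup, outgroup, mo + 1, fr)
    k3 <- select_single_copy(genes, ingroup, outgroup, mo, min(1, fr + 0.25))
    expect_true(all(k2 %in% k1) && all(k3 %in% k1))
  }
})

test_that("column trimming drops sparse and unconserved columns, idempotently", {
  m <- rbind(A = c("M", "K", "-", "A"),
             B = c("M", "-", "-", "C"),
             C = c("M", "-", "-", "D"),
             D = c("M", "-", "-", "E"),
             E = c("M", "-", "-", "F"),
             F = c("M", "-", "-", "G"),
             G = c("M", "-", "-", "H"),
             H = c("M", "-", "-", "I"),
             I = c("M", "-", "-", "K"),
             J = c("M", "-", "-", "L"))
  a <- gene_alignment("g", m)
  tr <- trim_columns(a)   # col2: 0.10 non-gap < 0.15; col3 all-gap
  expect_equal(alignment_length(tr), 2L)
  expect_identical(tr$mat[, 1], m[, 1])
  # all-identical alignment: nothing dropped
  ident <- gene_alignment("h", matrix("M", 4, 6,
            dimnames = list(letters[1:4], NULL)))
  expect_equal(alignment_length(trim_columns(ident)), 6L)
  # idempotence on random alignments
  set.seed(3)
  for (i in 1:8) {
    mm <- matrix(sample(c(pterochron:::AA_STATES, rep("-", 25)),
                        8 * 30, TRUE), nrow = 8,
                 dimnames = list(paste0("t", 1:8), NULL))
    a1 <- suppressWarnings(trim_columns(gene_alignment("r", mm),
                                        min_nongap_frac = 0.4,
                                        min_similarity = 0.3))
    a2 <- suppressWarnings(trim_columns(a1, min_nongap_frac = 0.4,
                                        min_similarity = 0.3))
    expect_identical(a1$mat, a2$mat)
  }
})

test_that("concatenation bookkeeping matches the hand-counted fixture", {
  sm <- concatenate_alignments(toy_genes_2x3(), c("A", "B", "C"))
  expect_equal(ncol(sm$mat), 12L)
  expect_equal(sm$partitions$start, c(0L, 5L))
  expect_equal(sm$partitions$end, c(5L, 12L))
  expect_equal(sm$missing_fraction, 7 / 36)
  expect_equal(missing_fraction(sm), 7 / 36)
  # single complete gapless gene: zero missing, trivial partition
  g <- gene_alignment("solo", c(A = "MKV", B = "MKI"))
  sm1 <- concatenate_alignments(list(g), c("A", "B"))
  expect_equal(sm1$missing_fraction, 0)
  expect_equal(sm1$partitions$end, 3L)
  expect_identical(sm1$mat, g$mat)
  # residue conservation
  total_res <- sum(vapply(toy_genes_2x3(), function(g) sum(g$mat != "-"), 0))
  expect_equal(sum(sm$mat != "-"), total_res)
  expect_error(concatenate_alignments(toy_genes_2x3(), c("A", "B")),
               "roster-error")
})

test_that("supermatrix round-trips through PHYLIP with its partition map", {
  sm <- concatenate_alignments(toy_genes_2x3(), c("A", "B", "C"))
  f <- tempfile(fileext = ".phy")
  write_supermatrix(sm, f)
  back <- read_alignment(f, "phylip")
  expect_identical(back$mat, sm$mat)
  parts <- utils::read.csv(paste0(f, ".partitions.csv"))
  expect_equal(parts$start, c(1L, 6L))
})

test_that("informative genes score high and ranking is deterministic", {
  tr <- dated_tree(ape::read.tree(
    text = "(((A:10,B:10):40,(C:10,D:10):40):50,(E:60,F:60):40);"))
  rr <- list(branch = rep(0.01, 11))
  al <- sim_alignments(tr, rr, n_genes = 1, len_range = c(1000, 1000),
                       p_missing = 0, gamma_shape = Inf,
                       gamma_categories = 1L, seed = 6)
  sc <- gene_support_scores(al, n_boot = 50, seed = 1)
  expect_gte(sc$score[1], 95)
  # <4 taxa: unscored
  small <- gene_alignment("s", c(A = "MKV", B = "MKV", C = "MKV"))
  sc2 <- gene_support_scores(list(s = small), n_boot = 10, seed = 1)
  expect_true(is.na(sc2$score))
  # top-k selection with tie-breaking, invariant to input order
  scores <- data.frame(gene_id = c("g2", "g1", "g3", "g4"),
                       score = c(80, 90, 70, 80), n_taxa = c(6L, 5L, 5L, 8L))
  expect_identical(select_top_genes(scores, 2), c("g1", "g4"))
  perm <- scores[c(3, 1, 4, 2), ]
  expect_identical(select_top_genes(perm, 2), c("g1", "g4"))
  ties <- data.frame(gene_id = c("b", "a"), score = 50, n_taxa = 4L)
  expect_identical(select_top_genes(ties, 1), "a")
  expect_warning(got <- select_top_genes(scores, 10), "only")
  expect_equal(length(got), 4L)
})
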