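test_that("alignment readers parse, normalize and validate", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">tax1", "mkv-x", ">tax2", "MKVLE"), fa)
  a <- read_alignment(fa, "fasta")
  expect_equal(alignment_length(a), 5L)
  expect_equal(unname(apply(a$mat, 1, paste, collapse = "")[1]), "MKV-X")

  ph <- tempfile(fileext = ".phy")
  writeLines(c("2 5", "tax1 MKV.E", "tax2 MKVLE"), ph)
  b <- read_alignment(ph, "phylip")
  expect_equal(unname(b$mat["tax1", 4]), "-")

  expect_error(gene_alignment("g", c(A = "MKVLE", B = "MKVL")),
               "alignment-error")
  expect_error(gene_alignment("g", stats::setNames(c("MK", "MK"), c("A", "A"))),
               "duplicate")
})

test_that("alignment writers round-trip in both dialects", {
  set.seed(5)
  for (dialect in c("fasta", "phylip")) {
    for (rep in 1:3) {
      n <- sample(2:6, 1); len <- sample(3:40, 1)
      m <- matrix(sample(c(pterochron:::AA_STATES, "-", "X"), n * len, TRUE),
                  nrow = n, dimnames = list(paste0("sp", 1:n), NULL))
      a <- gene_alignment("g", m)
      f <- tempfile()
      write_alignment(a, f, dialect)
      b <- read_alignment(f, dialect, gene_id = "g")
      expect_identical(b$mat, a$mat)
    }
  }
})

test_that("dated trees reconstruct ages and enforce ultrametricity", {
  tr <- toy_tree3()
  expect_equal(root_age(tr), 2)
  expect_equal(unname(node_ages(tr)[5]), 1)  # internal (A,B) node
  expect_error(dated_tree(ape::read.tree(text = "((A:1,B:2):1,C:2);")),
               "not ultrametric")
  expect_error(dated_tree(ape::read.tree(text = "(A:1,B:1,C:1);")),
               "tree-error")
  expect_error(dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2,D:2);")),
               "tree-error")
})

test_that("newick writer is the inverse of the reader", {
  set.seed(11)
  for (rep in 1:5) {
    tr <- sim_chronogram(sample(3:12, 1), root_age = stats::runif(1, 50, 200),
                         seed = rep)
    f <- tempfile(fileext = ".nwk")
    write_newick_dated(tr, f)
    tr2 <- read_newick_dated(f)
    expect_equal(sort(node_ages(tr2)), sort(node_ages(tr)), tolerance = 1e-9)
  }
})

test_that("node labels are emitted only on request", {
  tr <- toy_tree3()
  tr$phy$node.label <- c("root", "n1")
  f <- tempfile()
  write_newick_dated(tr, f, labels = TRUE)
  expect_match(readLines(f), "n1")
  write_newick_dated(tr, f, labels = FALSE)
  expect_false(grepl("n1", readLines(f)))
})

test_that("table readers type and validate the fixed schemas", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(toy_transcripts(), f, row.names = FALSE)
  tab <- read_table(f, "transcript")
  expect_equal(nrow(tab), 6L)
  expect_type(tab$tpm, "double")

  bad <- toy_transcripts(); bad$tpm[2] <- -1
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_table(f, "transcript"), "value-error")

  occ <- data.frame(species = "X", clade = "other", stage = "Ypresian",
                    status = "accepted")
  utils::write.csv(occ, f, row.names = FALSE)
  tab2 <- read_table(f, "occurrence")
  expect_equal(tab2$stage, "Ypresian")

  utils::write.csv(occ[c("species", "clade")], f, row.names = FALSE)
  expect_error(read_table(f, "occurrence"), "schema-error")

  orth <- data.frame(gene_id = c("g1", "g1"), taxon = c("in1", "out1"),
                     copy_number = c(1L, 1L))
  utils::write.csv(orth, f, row.names = FALSE)
  expect_equal(nrow(read_table(f, "ortholog_presence")), 2L)
  orth$copy_number[1] <- -1L
  utils::write.csv(orth, f, row.names = FALSE)
  expect_error(read_table(f, "ortholog_presence"), "value-error")
})

test_that("run configs round-trip and enforce invariants", {
  f <- tempfile(fileext = ".cfg")
  write_run_config(list(clock = "cir", iterations = 2000, burn_in = 500,
                        seed = 42), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$clock, "cir")
  expect_equal(cfg$iterations, 2000)
  writeLines(c("iterations = 100", "burn_in = 200", "seed = 1"), f)
  expect_error(read_run_config(f), "config-error")
})
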