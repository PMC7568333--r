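# Shared fixtures built in code; kept tiny so the suite stays fast.

toy_tree3 <- function() dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))

# the worked 2-gene / 3-taxon concatenation example
toy_genes_2x3 <- function() {
  g1 <- gene_alignment("g1", c(A = "MKVLE", B = "MKVLE", C = "MKVIE"))
  g2 <- gene_alignment("g2", c(A = "ACDEFGH", B = "ACDEFGY"))
  list(g1 = g1, g2 = g2)
}

# transcript table with the three documented filter cases
toy_transcripts <- function() {
  data.frame(
    transcript_id = c("T1", "T1", "T2", "T2", "T3", "T3"),
    dataset_id    = c("d1", "d2", "d1", "d2", "d1", "d2"),
    lane_id       = "lane1",
    est_count     = c(9, 50, 1, 4, 9, 4),
    tpm           = c(10, 30, 8, 4, 8, 4),
    stringsAsFactors = FALSE)
}

sort_rows_desc <- function(m) apply(m, 2, sort, decreasing = TRUE)

random_transcript_table <- function(n_datasets = 4, n_tr = 30, seed = 1) {
  set.seed(seed)
  lanes <- split(paste0("d", seq_len(n_datasets)),
                 rep(1:2, length.out = n_datasets))
  sim_contaminated_expression(lanes, n_transcripts = n_tr,
                              contamination = stats::runif(1, 0, 0.1),
                              library_size = 5000, seed = seed)
}
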