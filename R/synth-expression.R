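#' Simulate multi-lane transcript tables with index-hopping contamination
#'
#' For each dataset, true transcript abundances are drawn log-normally and
#' turned into multinomial read counts of size `library_size`. Datasets
#' sharing a sequencing lane then leak a fraction `contamination` of each
#' transcript's reads into every lane-mate (binomial thinning), where the
#' leaked reads appear as distinct spurious rows carrying the origin
#' dataset's transcript id - the way an assembler would recover hopped reads
#' as contaminant transcripts. TPMs are recomputed per dataset from the
#' final counts (transcript lengths are taken equal, so TPM is proportional
#' to count and sums to 1e6). Ground-truth labels are retained for scoring.
#'
#' @param lanes list of character vectors: datasets grouped by lane, e.g.
#'   `list(c("d1", "d2"), c("d3"))`.
#' @param n_transcripts transcripts per dataset.
#' @param contamination leak fraction `c` in `[0, 1)` per lane-mate.
#' @param library_size reads per dataset.
#' @param abund_meanlog,abund_sdlog log-normal abundance parameters
#'   (defaults 1 and 1.5: heavy-tailed expression).
#' @param min_reads_detect minimum number of leaked reads for the assembler
#'   to recover a contaminant transcript (default 10); smaller leaks vanish
#'   into noise rather than producing a spurious transcript row.
#' @param seed integer seed.
#' @return `data.frame` with the transcript schema columns plus ground truth
#'   `origin_dataset` and `is_contaminant`.
#' @export
sim_contaminated_expression <- function(lanes, n_transcripts = 500,
                                        contamination = 0.05,
                                        library_size = 1e5,
                                        abund_meanlog = 1, abund_sdlog = 1.5,
                                        min_reads_detect = 10,
                                        seed = 1L) {
  stopifnot(contamination >= 0, contamination < 1)
  set.seed(as.integer(seed))
  datasets <- unlist(lanes)
  if (anyDuplicated(datasets)) stop("config-error: dataset in two lanes")
  lane_of <- rep(seq_along(lanes), lengths(lanes))
  names(lane_of) <- datasets
  native <- list()
  for (d in datasets) {
    ab <- stats::rlnorm(n_transcripts, abund_meanlog, abund_sdlog)
    counts <- as.numeric(stats::rmultinom(1L, library_size, ab))
    native[[d]] <- data.frame(
      transcript_id = paste0(d, "_tr", seq_len(n_transcripts)),
      dataset_id = d,
      lane_id = paste0("lane", lane_of[[d]]),
      est_count = counts,
      origin_dataset = d,
      is_contaminant = FALSE,
      stringsAsFactors = FALSE)
  }
  rows <- native
  if (contamination > 0) {
    for (d in datasets) for (m in datasets) {
      if (d == m || lane_of[[d]] != lane_of[[m]]) next
      leak <- stats::rbinom(n_transcripts, size = native[[d]]$est_count,
                            prob = contamination)
      keep <- leak >= min_reads_detect
      if (!any(keep)) next
      rows[[paste(d, m)]] <- data.frame(
        transcript_id = native[[d]]$transcript_id[keep],
        dataset_id = m,
        lane_id = paste0("lane", lane_of[[m]]),
        est_count = as.numeric(leak[keep]),
        origin_dataset = d,
        is_contaminant = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  totals <- tapply(tab$est_count, tab$dataset_id, sum)
  tab$tpm <- tab$est_count / as.numeric(totals[tab$dataset_id]) * 1e6
  tab[c("transcript_id", "dataset_id", "lane_id", "est_count", "tpm",
        "origin_dataset", "is_contaminant")]
}
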