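#' Contaminant enrichment ratio of a transcript
#'
#' For a transcript of a focal dataset, the maximum over lane-mate datasets
#' of `TPM(lane-mate) / TPM(focal)`, matched by transcript id. Lane-mates
#' lacking the transcript contribute 0; with no lane-mates the ratio is 0;
#' a focal TPM of 0 against any positive lane-mate TPM yields `Inf`. Taking
#' the worst (maximum) lane-mate is the conservative aggregation when more
#' than one dataset shares the lane.
#'
#' @param transcript transcript id.
#' @param dataset focal dataset id.
#' @param table transcript `data.frame` (schema of [read_table()]).
#' @return non-negative ratio (possibly `Inf`).
#' @export
enrichment_ratio <- function(transcript, dataset, table) {
  focal <- table[table$transcript_id == transcript &
                 table$dataset_id == dataset, , drop = FALSE]
  if (nrow(focal) == 0L)
    stop("lookup-error: transcript ", transcript, " absent from dataset ",
         dataset)
  lane <- focal$lane_id[1]
  mates <- table[table$lane_id == lane & table$dataset_id != dataset &
                 table$transcript_id == transcript, , drop = FALSE]
  if (nrow(mates) == 0L) return(0)
  ratio_vs_focal(max(mates$tpm), focal$tpm[1])
}

ratio_vs_focal <- function(mate_tpm, focal_tpm) {
  if (mate_tpm == 0) return(0)
  if (focal_tpm == 0) return(Inf)
  mate_tpm / focal_tpm
}

#' Cross-contamination filter on a transcript table
#'
#' Applies the two exclusion rules per dataset: criterion 1 excludes
#' transcripts whose contaminant enrichment ratio exceeds `fold_threshold`;
#' criterion 2 excludes transcripts whose estimated count in the original
#' dataset falls strictly below `min_count` (counts are fractional
#' estimates, compared as real numbers). The criteria are applied
#' independently (union exclusion); a transcript failing both is attributed
#' to criterion 1 for reporting, so the three decision lists partition each
#' dataset.
#'
#' @param table transcript `data.frame`.
#' @param fold_threshold enrichment threshold (default 2 = twofold).
#' @param min_count minimum estimated count (default 2).
#' @return object of class `filter_report`: `decisions` (`data.frame` of
#'   `transcript_id`, `dataset_id`, `decision`, `ratio`, `est_count`) and
#'   `fractions` (per-dataset exclusion fractions by criterion).
#' @export
apply_contamination_filter <- function(table, fold_threshold = 2,
                                       min_count = 2) {
  # vectorized max lane-mate TPM per (transcript, dataset)
  key <- paste(table$lane_id, table$transcript_id)
  lane_max <- tapply(table$tpm, key, max)
  lane_n <- tapply(rep(1L, nrow(table)), key, sum)
  mx <- as.numeric(lane_max[key])
  n_in_lane <- as.integer(lane_n[key])
  # max over *other* datasets: if the focal row holds the lane max we need
  # the second maximum; recompute for those rows only
  need2 <- which(table$tpm == mx & n_in_lane > 1L)
  mate_max <- ifelse(n_in_lane == 1L, 0, mx)
  if (length(need2)) {
    second <- tapply(table$tpm, key, function(v)
      if (length(v) == 1L) 0 else sort(v, decreasing = TRUE)[2])
    mate_max[need2] <- as.numeric(second[key[need2]])
  }
  ratio <- ifelse(mate_max == 0, 0,
                  ifelse(table$tpm == 0, Inf, mate_max / table$tpm))
  excl1 <- ratio > fold_threshold
  excl2 <- table$est_count < min_count
  decision <- ifelse(excl1, "excluded_by_enrichment",
                     ifelse(excl2, "excluded_by_count", "kept"))
  decisions <- data.frame(transcript_id = table$transcript_id,
                          dataset_id = table$dataset_id,
                          decision = decision, ratio = ratio,
                          est_count = table$est_count,
                          stringsAsFactors = FALSE)
  ds <- sort(unique(table$dataset_id))
  fractions <- t(vapply(ds, function(d) {
    dd <- decisions[decisions$dataset_id == d, ]
    c(criterion1 = mean(dd$decision == "excluded_by_enrichment"),
      criterion2 = mean(dd$decision == "excluded_by_count"))
  }, c(criterion1 = 0, criterion2 = 0)))
  structure(list(decisions = decisions,
                 fractions = data.frame(dataset_id = ds, fractions,
                                        row.names = NULL),
                 fold_threshold = fold_threshold, min_count = min_count),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report: ", nrow(x$decisions), " transcripts, ",
      nrow(x$fractions), " datasets\n", sep = "")
  cat("  median excluded by enrichment: ",
      sprintf("%.1f%%", 100 * stats::median(x$fractions$criterion1)), "\n",
      "  median excluded by low count:  ",
      sprintf("%.1f%%", 100 * stats::median(x$fractions$criterion2)), "\n",
      sep = "")
  invisible(x)
}

#' Median exclusion fractions across datasets
#'
#' @param reports a `filter_report` or list of them; per-dataset fractions
#'   are pooled before taking medians.
#' @return named vector `c(median_frac_criterion1, median_frac_criterion2)`.
#' @export
summarize_exclusions <- function(reports) {
  if (inherits(reports, "filter_report")) reports <- list(reports)
  if (length(reports) == 0L) stop("value-error: no reports")
  fr <- do.call(rbind, lapply(reports, function(r) r$fractions))
  c(median_frac_criterion1 = stats::median(fr$criterion1),
    median_frac_criterion2 = stats::median(fr$criterion2))
}
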