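#' Geologic timescale bins
#'
#' Loads a stage-resolved timescale: ordered old-to-young intervals with
#' numeric bounds in Ma and a designated Recent bin (younger bound 0). A
#' default table (Jurassic stages through a pooled Pleistocene bin plus
#' Recent, bounds consistent with the international chart) ships with the
#' package; pass a CSV path with columns `stage, older, younger` to replace
#' it.
#'
#' @param path optional CSV path; default uses the bundled table.
#' @return `data.frame` with columns `stage`, `older`, `younger` (and any
#'   extras, e.g. `epoch`), ordered old to young.
#' @export
geologic_timescale <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "geologic_timescale.csv",
                        package = "pterochron")
  ts <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("stage", "older", "younger") %in% names(ts)))
    stop("schema-error: timescale needs columns stage, older, younger")
  ts <- ts[order(-ts$older), , drop = FALSE]
  rownames(ts) <- NULL
  if (any(ts$older <= ts$younger))
    stop("value-error: interval bounds must satisfy older > younger")
  if (any(utils::head(ts$younger, -1) < utils::tail(ts$older, -1) - 1e-9))
    stop("value-error: overlapping intervals")
  if (ts$younger[nrow(ts)] != 0)
    stop("value-error: the youngest (Recent) bin must end at 0")
  ts
}

# Expand records whose stage is a span like "Chattian-Burdigalian" into one
# record per spanned stage; validate stage names against the timescale.
expand_stage_ranges <- function(table, ts) {
  stages <- ts$stage
  span <- grepl("–|—|-", table$stage) & !(table$stage %in% stages)
  if (!any(span)) {
    bad <- setdiff(unique(table$stage), stages)
    if (length(bad))
      stop("binning-error: unknown stage(s): ", paste(bad, collapse = ", "))
    return(table)
  }
  keep <- table[!span, , drop = FALSE]
  ex <- lapply(which(span), function(i) {
    ends <- trimws(strsplit(table$stage[i], "–|—|-")[[1]])
    idx <- match(ends, stages)
    if (anyNA(idx))
      stop("binning-error: unknown stage(s) in span: ", table$stage[i])
    out <- table[rep(i, abs(diff(idx)) + 1L), , drop = FALSE]
    out$stage <- stages[seq(min(idx), max(idx))]
    out
  })
  out <- rbind(keep, do.call(rbind, ex))
  bad <- setdiff(unique(out$stage), stages)
  if (length(bad))
    stop("binning-error: unknown stage(s): ", paste(bad, collapse = ", "))
  out
}

# accepted-only, de-duplicated (species, stage) records, clade-filtered
occurrence_clean <- function(table, ts, clades = NULL) {
  tab <- table[table$status == "accepted", , drop = FALSE]
  if (!is.null(clades)) tab <- tab[tab$clade %in% clades, , drop = FALSE]
  tab$species <- trimws(tab$species)
  tab <- expand_stage_ranges(tab, ts)
  tab[!duplicated(tab[c("species", "stage")]), , drop = FALSE]
}

#' Observed (sampled-in-bin) species diversity through time
#'
#' Counts, per stage, the distinct accepted species with at least one
#' occurrence in that stage. Synonym and doubtful records are excluded;
#' stage spans ("Chattian-Burdigalian") are expanded across the spanned
#' stages first.
#'
#' @param table occurrence `data.frame` (`species`, `clade`, `stage`,
#'   `status`).
#' @param ts timescale from [geologic_timescale()].
#' @param clades optional clade filter (character vector); default all.
#' @return named integer vector of counts, one per timescale stage
#'   (old to young).
#' @export
observed_diversity <- function(table, ts = geologic_timescale(),
                               clades = NULL) {
  tab <- occurrence_clean(table, ts, clades)
  counts <- table(factor(tab$stage, levels = ts$stage))
  stats::setNames(as.integer(counts), ts$stage)
}

#' Range-through species diversity
#'
#' Each species is counted in every stage between its oldest and youngest
#' occurrence inclusive, so single gaps in the sampled record are filled.
#' Always stage-wise greater than or equal to [observed_diversity()].
#'
#' @inheritParams observed_diversity
#' @export
range_through_diversity <- function(table, ts = geologic_timescale(),
                                    clades = NULL) {
  tab <- occurrence_clean(table, ts, clades)
  idx <- match(tab$stage, ts$stage)
  counts <- integer(nrow(ts))
  for (sp in unique(tab$species)) {
    r <- range(idx[tab$species == sp])
    counts[r[1]:r[2]] <- counts[r[1]:r[2]] + 1L
  }
  stats::setNames(counts, ts$stage)
}

#' Summary statistic of diversity over a stage interval
#'
#' @param counts named per-stage counts (from [observed_diversity()] or
#'   [range_through_diversity()]).
#' @param interval character vector of stage names.
#' @param statistic `"median"`, `"total"` or `"mean"`. The median of an even
#'   number of stages is the midpoint average.
#' @return single number.
#' @export
interval_summary <- function(counts, interval,
                             statistic = c("median", "total", "mean")) {
  statistic <- match.arg(statistic)
  if (length(interval) == 0L) stop("value-error: empty interval")
  miss <- setdiff(interval, names(counts))
  if (length(miss))
    stop("value-error: unknown stage(s): ", paste(miss, collapse = ", "))
  x <- as.numeric(counts[interval])
  switch(statistic,
         median = stats::median(x),
         total = sum(x),
         mean = mean(x))
}

#' Per-clade and pooled diversity-through-time report
#'
#' Observed and range-through curves for each clade present in the table and
#' for the pooled record; optionally written as CSV and plotted (step curves
#' against stage midpoint ages, highlighting the Thanetian to Ypresian step
#' when both stages are present).
#'
#' @inheritParams observed_diversity
#' @param csv optional output CSV path.
#' @param plot_file optional output plot path (`.png` or `.svg`).
#' @return long `data.frame`: `clade` (including `"pooled"`), `stage`,
#'   `mid_age`, `observed`, `range_through`.
#' @export
diversity_report <- function(table, ts = geologic_timescale(), csv = NULL,
                             plot_file = NULL) {
  clades <- sort(unique(table$clade[table$status == "accepted"]))
  groups <- c(stats::setNames(as.list(clades), clades), list(pooled = NULL))
  mid <- (ts$older + ts$younger) / 2
  rep_rows <- lapply(names(groups), function(g) {
    data.frame(clade = g, stage = ts$stage, mid_age = mid,
               observed = as.integer(observed_diversity(table, ts, groups[[g]])),
               range_through = as.integer(range_through_diversity(table, ts, groups[[g]])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rep_rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  if (!is.null(plot_file)) {
    if (grepl("\\.svg$", plot_file)) grDevices::svg(plot_file, 7, 5)
    else grDevices::png(plot_file, 700, 500)
    on.exit(grDevices::dev.off())
    pooled <- out[out$clade == "pooled", ]
    graphics::plot(pooled$mid_age, pooled$observed, type = "s",
                   xlim = rev(range(ts$older)), xlab = "Age (Ma)",
                   ylab = "Observed species diversity", lwd = 2)
    cl <- setdiff(names(groups), "pooled")
    for (i in seq_along(cl)) {
      sub <- out[out$clade == cl[i], ]
      graphics::lines(sub$mid_age, sub$observed, type = "s", col = i + 1)
    }
    if (all(c("Thanetian", "Ypresian") %in% ts$stage))
      graphics::abline(v = 56, lty = 2, col = "grey40")
    graphics::legend("topleft", legend = c("pooled", cl), lwd = c(2, rep(1, length(cl))),
                     col = c(1, seq_along(cl) + 1), bty = "n", cex = 0.8)
  }
  out
}
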