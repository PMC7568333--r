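#' Simulate a stage-binned fossil occurrence record
#'
#' Each clade receives `n_species` true species. A species originates in a
#' uniformly drawn stage and persists through a geometric number of
#' consecutive stages (possibly reaching the Recent, in which case it is
#' extant). The species is recorded in each stage of its range independently
#' with that stage's preservation probability; extant species are recorded
#' in the Recent bin with probability 1. The true standing diversity per
#' clade and stage is attached as `attr(, "truth")` so filters and curves
#' can be scored against it.
#'
#' @param n_species named integer vector: true species count per clade.
#' @param timescale a timescale `data.frame` (see [geologic_timescale()]).
#' @param preservation per-stage preservation probability: a single number
#'   or a vector named by stage (the Recent bin is forced to 1).
#' @param mean_range mean range length in stages (geometric; default 3).
#' @param seed integer seed.
#' @return occurrence `data.frame` (`species`, `clade`, `stage`, `status`)
#'   with a `truth` attribute (clade x stage matrix of true diversity).
#' @export
sim_fossil_record <- function(n_species, timescale = geologic_timescale(),
                              preservation = 0.3, mean_range = 3, seed = 1L) {
  set.seed(as.integer(seed))
  stages <- timescale$stage
  ns <- length(stages)
  recent <- which(timescale$younger == 0 & timescale$older == min(timescale$older))
  recent <- ns                         # timescale is ordered old -> young
  pres <- if (length(preservation) == 1L)
    stats::setNames(rep(preservation, ns), stages) else preservation[stages]
  if (any(is.na(pres)) || any(pres < 0) || any(pres > 1))
    stop("value-error: preservation probabilities must cover all stages in [0,1]")
  pres[ns] <- 1
  truth <- matrix(0L, nrow = length(n_species), ncol = ns,
                  dimnames = list(names(n_species), stages))
  rows <- list()
  for (cl in names(n_species)) {
    for (i in seq_len(n_species[[cl]])) {
      sp <- sprintf("%s_sp%03d", cl, i)
      first <- sample.int(ns, 1L)
      len <- 1L + stats::rgeom(1L, 1 / mean_range)
      range <- first:min(ns, first + len - 1L)
      truth[cl, range] <- truth[cl, range] + 1L
      hit <- stats::runif(length(range)) < pres[range]
      for (s in range[hit]) {
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, clade = cl, stage = stages[s], status = "accepted",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), clade = character(0),
               stage = character(0), status = character(0))
  attr(out, "truth") <- truth
  out
}
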