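#' Read a typed CSV table
#'
#' Fixed schemas for the three tables the pipeline consumes. Unknown columns
#' are preserved but ignored. Mandatory columns per schema:
#' \describe{
#'   \item{transcript}{`transcript_id, dataset_id, lane_id, est_count, tpm`}
#'   \item{occurrence}{`species, clade, stage, status`}
#'   \item{ortholog_presence}{`gene_id, taxon, copy_number`}
#' }
#'
#' @param path CSV file path.
#' @param schema one of `"transcript"`, `"occurrence"`, `"ortholog_presence"`.
#' @return a `data.frame` with parsed, validated columns.
#' @export
read_table <- function(path, schema = c("transcript", "occurrence",
                                        "ortholog_presence")) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_table(df, schema)
}

table_schemas <- list(
  transcript = c("transcript_id", "dataset_id", "lane_id", "est_count", "tpm"),
  occurrence = c("species", "clade", "stage", "status"),
  ortholog_presence = c("gene_id", "taxon", "copy_number")
)

validate_table <- function(df, schema) {
  cols <- table_schemas[[schema]]
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema-error: missing column(s): ", paste(miss, collapse = ", "))
  if (schema == "transcript") {
    df$est_count <- as.numeric(df$est_count)
    df$tpm <- as.numeric(df$tpm)
    if (anyNA(df$est_count) || anyNA(df$tpm))
      stop("value-error: non-numeric est_count/tpm")
    if (any(df$est_count < 0) || any(df$tpm < 0))
      stop("value-error: negative est_count/tpm")
    if (anyDuplicated(df[c("transcript_id", "dataset_id")]))
      stop("value-error: duplicated (transcript_id, dataset_id)")
    lane_map <- unique(df[c("dataset_id", "lane_id")])
    if (anyDuplicated(lane_map$dataset_id))
      stop("value-error: a dataset is assigned to more than one lane")
  } else if (schema == "occurrence") {
    ok <- c("accepted", "synonym", "doubtful")
    bad <- setdiff(unique(df$status), ok)
    if (length(bad))
      stop("value-error: unknown status value(s): ", paste(bad, collapse = ", "))
    df$species <- trimws(df$species)
  } else {
    df$copy_number <- as.integer(df$copy_number)
    if (anyNA(df$copy_number) || any(df$copy_number < 0))
      stop("value-error: copy_number must be a non-negative integer")
  }
  df
}

#' Run configuration files
#'
#' Flat `key = value` text files (TOML-style scalars only; `#` comments).
#' Values are parsed as numbers when possible, otherwise kept as strings.
#' [write_run_config()] echoes a fully resolved configuration, which every
#' analysis driver writes next to its outputs for reproducibility.
#'
#' @param path config file path.
#' @return named list of scalar values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  validate_run_config(out)
}

validate_run_config <- function(cfg) {
  if (!is.null(cfg$iterations) && !is.null(cfg$burn_in) &&
      cfg$iterations <= cfg$burn_in)
    stop("config-error: iterations must exceed burn_in")
  if (!is.null(cfg$iterations) && is.null(cfg$seed))
    stop("config-error: seed is mandatory for stochastic runs")
  cfg
}

#' @rdname read_run_config
#' @param cfg named list of scalar values.
#' @export
write_run_config <- function(cfg, path) {
  fmt <- vapply(cfg, function(v)
    if (is.numeric(v)) format(v, digits = 15) else paste0('"', v, '"'), "")
  writeLines(paste(names(cfg), "=", fmt), path)
  invisible(path)
}
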