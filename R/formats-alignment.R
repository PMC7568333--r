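#' Amino-acid gene alignments
#'
#' A `gene_alignment` is a character matrix of single residues with taxa as
#' rows and alignment columns as columns, plus a `gene_id`. Residues are the
#' 20 IUPAC amino-acid codes, `-` for gaps and `X` for unknowns; everything is
#' stored upper-case. Columns are indexed 0-based half-open internally (the
#' convention used by the partition maps); user-facing reports are 1-based.
#'
#' @param gene_id single string naming the gene.
#' @param seqs named character vector of aligned sequences (one string per
#'   taxon), or a character matrix of single residues with taxon rownames.
#' @return object of class `gene_alignment`.
#' @export
gene_alignment <- function(gene_id, seqs) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
      stop("format-error: sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("alignment-error: ragged rows (lengths ", paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat))) stop("format-error: missing taxon names")
  if (anyDuplicated(rownames(mat)))
    stop("format-error: duplicate taxon names")
  if (ncol(mat) < 1L) stop("alignment-error: zero-length alignment")
  mat[] <- normalize_residues(mat)
  structure(list(gene_id = as.character(gene_id), mat = mat),
            class = "gene_alignment")
}

# Upper-case, '.' -> '-', rare ambiguity codes -> 'X'; anything else is an error.
normalize_residues <- function(x) {
  x <- toupper(x)
  x[x == "."] <- "-"
  x[x %in% c("B", "Z", "J", "U", "O", "?", "*")] <- "X"
  bad <- setdiff(unique(as.vector(x)), c(AA_STATES, "X", "-"))
  if (length(bad))
    stop("format-error: unexpected residue(s): ", paste(bad, collapse = " "))
  x
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("gene_alignment '", x$gene_id, "': ", nrow(x$mat), " taxa x ",
      ncol(x$mat), " positions\n", sep = "")
  invisible(x)
}

#' @rdname gene_alignment
#' @param x a `gene_alignment`.
#' @export
alignment_length <- function(x) ncol(x$mat)

#' @rdname gene_alignment
#' @export
alignment_taxa <- function(x) rownames(x$mat)

#' Read an amino-acid alignment
#'
#' Parses FASTA (via Biostrings) or relaxed sequential PHYLIP. Residues are
#' upper-cased and `.` is normalized to `-` on read.
#'
#' @param path file path.
#' @param dialect `"fasta"` or `"phylip"`; default guesses from the extension.
#' @param gene_id gene identifier; default is the file base name.
#' @return a [gene_alignment()].
#' @export
read_alignment <- function(path, dialect = c("auto", "fasta", "phylip"),
                           gene_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(phy|phylip)$", path, ignore.case = TRUE))
      "phylip" else "fasta"
  }
  if (is.null(gene_id))
    gene_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else {
    seqs <- read_phylip_seqs(path)
  }
  gene_alignment(gene_id, seqs)
}

# Relaxed sequential PHYLIP: header "ntax ncols", then one "name sequence"
# record per taxon (whitespace-separated, sequence may continue on following
# lines until ncols residues are read).
read_phylip_seqs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("format-error: bad PHYLIP header")
  ntax <- as.integer(hdr[1]); ncols <- as.integer(hdr[2])
  body <- lines[-1]
  seqs <- character(0)
  i <- 1L
  for (k in seq_len(ntax)) {
    if (i > length(body)) stop("format-error: truncated PHYLIP file")
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    nm <- parts[1]
    sq <- paste(parts[-1], collapse = "")
    i <- i + 1L
    while (nchar(sq) < ncols) {
      if (i > length(body)) stop("format-error: truncated sequence for ", nm)
      sq <- paste0(sq, gsub("\\s", "", body[i]))
      i <- i + 1L
    }
    if (nchar(sq) != ncols)
      stop("alignment-error: sequence for ", nm, " has ", nchar(sq),
           " columns, expected ", ncols)
    seqs[nm] <- sq
  }
  if (anyDuplicated(names(seqs))) stop("format-error: duplicate taxon names")
  seqs
}

#' Write an amino-acid alignment
#'
#' @param aln a [gene_alignment()].
#' @param path output file path.
#' @param dialect `"fasta"` or `"phylip"` (relaxed sequential).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, dialect = c("fasta", "phylip")) {
  dialect <- match.arg(dialect)
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  if (dialect == "fasta") {
    writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  } else {
    writeLines(c(paste(length(seqs), ncol(aln$mat)),
                 paste(names(seqs), seqs)), path)
  }
  invisible(path)
}
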