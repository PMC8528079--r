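#' Read a base-pair probability matrix
#'
#' Accepts either a whitespace-delimited dense `n x n` numeric matrix or
#' sparse triplet lines `i j p` with 0-based indices; triplet input is
#' mirrored to a symmetric matrix. Entries are equilibrium probabilities
#' that positions i and j are paired.
#'
#' @param path Path to the text file.
#' @param n Sequence length (matrix dimension).
#' @return An `n x n` symmetric numeric matrix with zero diagonal,
#'   entries in \[0, 1\].
#' @export
read_bpp <- function(path, n) {
  stopifnot_scalar_string(path, "path")
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) abort("`n` must be a positive integer.")
  tab <- tryCatch(
    read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) abort(sprintf("Cannot parse '%s': %s", path,
                                      conditionMessage(e)))
  )
  if (nrow(tab) == 0L) return(matrix(0, n, n))
  if (ncol(tab) == n && nrow(tab) == n) {
    m <- unname(as.matrix(tab))
  } else if (ncol(tab) == 3L) {
    m <- matrix(0, n, n)
    i <- as.integer(tab[[1]]); j <- as.integer(tab[[2]]); p <- tab[[3]]
    if (any(i < 0L | i >= n | j < 0L | j >= n)) {
      abort("Triplet indices outside [0, n).")
    }
    m[cbind(i + 1L, j + 1L)] <- p
    m[cbind(j + 1L, i + 1L)] <- p
  } else {
    abort(sprintf(
      "bpp input must be a dense %dx%d matrix or 3-column triplets; got %dx%d.",
      n, n, nrow(tab), ncol(tab)))
  }
  validate_bpp(m)
  m
}

validate_bpp <- function(m, tol = 1e-6) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("bpp matrix must be square.")
  }
  if (any(m < -tol | m > 1 + tol)) {
    abort("bpp entries must be probabilities in [0, 1].")
  }
  if (any(abs(m - t(m)) > tol)) abort("bpp matrix must be symmetric.")
  if (any(abs(diag(m)) > tol)) abort("bpp diagonal must be zero.")
  if (any(rowSums(m) > 1 + 1e-3)) {
    abort("bpp row sums exceed 1: not a valid pairing distribution.")
  }
  invisible(m)
}

#' Write a base-pair probability matrix as sparse triplets
#'
#' Emits `i j p` lines (0-based, upper triangle, nonzero entries only),
#' re-readable by [read_bpp()].
#'
#' @param m Symmetric bpp matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bpp <- function(m, path) {
  validate_bpp(m)
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  lines <- sprintf("%d %d %.17g", idx[, 1] - 1L, idx[, 2] - 1L, m[idx])
  writeLines(lines, path)
  invisible(path)
}

#' Read RNA sequences from FASTA
#'
#' DNA-style `T` is transparently mapped to `U` (with a message); any
#' other non-ACGU character is an error. Empty headers are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (full header line minus `>`) and
#'   `sequence` (RNA alphabet).
#' @export
read_fasta_rna <- function(path) {
  stopifnot_scalar_string(path, "path")
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (any(!nzchar(trimws(ids)))) abort("FASTA record with empty header.")
  seqs <- toupper(as.character(set))
  if (any(grepl("T", seqs, fixed = TRUE))) {
    inform("FASTA contains T; mapping T -> U for RNA alphabet.")
    seqs <- gsub("T", "U", seqs, fixed = TRUE)
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    abort(sprintf("Non-ACGU(T) characters in FASTA record '%s'.",
                  ids[which(bad)[1]]))
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write RNA sequences to FASTA
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_rna <- function(records, path) {
  if (any(!nzchar(trimws(records$id)))) abort("Empty FASTA header.")
  if (any(grepl("[^ACGU]", records$sequence))) {
    abort("Sequences must be over A/C/G/U.")
  }
  writeLines(rbind(paste0(">", records$id), records$sequence), path)
  invisible(path)
}

#' Read / write long-format prediction tables
#'
#' Prediction tables are CSV with columns `id`, `position` (1-based
#' nucleotide index), `data_type`, `value`, optionally preceded by
#' `#`-prefixed metadata header lines, which are ignored on read.
#'
#' @param path CSV path.
#' @return A tibble with columns `id`, `position`, `data_type`, `value`.
#' @export
read_predictions <- function(path) {
  tab <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                    colClasses = c("character", "integer", "character",
                                   "numeric"))
  tibble::as_tibble(tab)
}

#' @rdname read_predictions
#' @param predictions Tibble with columns `id`, `position`, `data_type`,
#'   `value`.
#' @param metadata Optional named character vector written as `# key=value`
#'   header lines.
#' @export
write_predictions <- function(predictions, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_metadata_header(con, metadata)
  write.table(predictions[, c("id", "position", "data_type", "value")],
              con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_metadata_header <- function(con, metadata) {
  writeLines(sprintf("# degkit %s", as.character(packageVersion("degkit"))),
             con)
  if (length(metadata)) {
    writeLines(sprintf("# %s=%s", names(metadata), unname(metadata)), con)
  }
}

#' Read probed-window definitions (BED-like)
#'
#' Three whitespace-separated columns: construct id, window start, window
#' end, with 0-based half-open coordinates as in BED. Used to delimit the
#' region of an mRNA captured by reverse-transcription PCR when summing
#' per-linkage degradation rates.
#'
#' @param path Path to the window file.
#' @return Tibble with columns `id`, `start`, `end` (0-based half-open).
#' @export
read_windows_bed <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("id", "start", "end"),
                    colClasses = c("character", "integer", "integer"))
  if (any(tab$start < 0L) || any(tab$end <= tab$start)) {
    abort("Windows must satisfy 0 <= start < end.")
  }
  tibble::as_tibble(tab)
}
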