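#' Read a JSON-lines construct table
#'
#' Reads per-construct records in the JSON-lines dialect used by RNA
#' stability community benchmarks: one JSON object per line with keys
#' `id`, `sequence`, `structure`, `predicted_loop_type`, `seq_length`,
#' `seq_scored`, `signal_to_noise`, `SN_filter`, plus per-nucleotide value
#' arrays for up to five data types (`reactivity`, `deg_Mg_pH10`,
#' `deg_pH10`, `deg_Mg_50C`, `deg_50C`) and their error arrays. A plain
#' JSON array of the same objects is accepted as a fallback dialect.
#'
#' Value/error arrays cover only the scored 5' prefix (`seq_scored`
#' positions). Data types that were not measured are absent, never
#' zero-filled. Unknown keys are preserved in the `extra` list-column.
#'
#' @param path Path to a `.json` / `.jsonl` file.
#' @param error_keys Named character vector mapping each data-type key to
#'   its error-array key; override when a dump version spells error keys
#'   differently. Default: `reactivity -> reactivity_error`,
#'   `deg_Mg_pH10 -> deg_error_Mg_pH10`, and so on.
#' @param validate Check record invariants (default `TRUE`).
#' @return A tibble with one row per construct: character columns
#'   `id`, `sequence`, `structure`, `loop_type`; integer `seq_length`,
#'   `seq_scored`, `SN_filter`; double `signal_to_noise`; one list-column
#'   of numeric vectors per data type present plus its error arrays; and
#'   a list-column `extra` of passthrough fields.
#' @seealso [write_constructs()], [validate_constructs()]
#' @export
read_constructs <- function(path, error_keys = DEFAULT_ERROR_KEYS,
                            validate = TRUE) {
  stopifnot_scalar_string(path, "path")
  if (!file.exists(path)) abort(sprintf("File not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_constructs())

  first <- trimws(lines[[1]])
  if (startsWith(first, "[")) {
    # fallback dialect: a single JSON array of record objects
    objs <- jsonlite::fromJSON(paste(lines, collapse = "\n"),
                               simplifyVector = FALSE)
  } else {
    objs <- lapply(seq_along(lines), function(i) {
      tryCatch(
        jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
        error = function(e) {
          abort(sprintf("Malformed JSON on line %d of '%s': %s",
                        i, path, conditionMessage(e)))
        }
      )
    })
  }
  out <- records_to_tibble(objs, error_keys)
  if (validate) validate_constructs(out)
  out
}

empty_constructs <- function() {
  tibble::tibble(
    id = character(), sequence = character(), structure = character(),
    loop_type = character(), seq_length = integer(), seq_scored = integer(),
    signal_to_noise = double(), SN_filter = integer(), extra = list()
  )
}

records_to_tibble <- function(objs, error_keys) {
  if (length(objs) == 0L) return(empty_constructs())
  known <- c("id", "sequence", "structure", "predicted_loop_type",
             "seq_length", "seq_scored", "signal_to_noise", "SN_filter",
             DATA_TYPES, unname(error_keys))
  grab_chr <- function(o, key, default = NA_character_) {
    v <- o[[key]]
    if (is.null(v)) default else as.character(v)
  }
  num_vec <- function(v) {
    if (is.null(v)) return(NULL)
    vapply(v, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
           numeric(1))
  }
  rows <- lapply(objs, function(o) {
    row <- list(
      id = grab_chr(o, "id"),
      sequence = grab_chr(o, "sequence"),
      structure = grab_chr(o, "structure"),
      loop_type = grab_chr(o, "predicted_loop_type"),
      seq_length = as.integer(o$seq_length %||%
                                nchar(grab_chr(o, "sequence", ""))),
      seq_scored = as.integer(o$seq_scored %||% NA_integer_),
      signal_to_noise = as.numeric(o$signal_to_noise %||% NA_real_),
      SN_filter = as.integer(o$SN_filter %||% NA_integer_)
    )
    for (dt in DATA_TYPES) {
      v <- num_vec(o[[dt]])
      if (!is.null(v)) row[[dt]] <- list(v)
      e <- num_vec(o[[error_keys[[dt]]]])
      if (!is.null(e)) row[[paste0(dt, "_err")]] <- list(e)
    }
    row$extra <- list(o[setdiff(names(o), known)])
    tibble::as_tibble(row)
  })
  dplyr::bind_rows(rows)
}

#' Validate construct records
#'
#' Checks the record invariants: sequence, structure and loop-type strings
#' share `seq_length`; `seq_scored <= seq_length`; every value/error array
#' has length `seq_scored`; error arrays are nonnegative; sequences are
#' over A/C/G/U. Errors name the offending record id.
#'
#' @param constructs A construct tibble as returned by [read_constructs()].
#' @return The input, invisibly.
#' @export
validate_constructs <- function(constructs) {
  for (i in seq_len(nrow(constructs))) {
    r <- constructs[i, ]
    id <- r$id
    fail <- function(msg) {
      abort(sprintf("Invalid construct record '%s': %s", id, msg))
    }
    n <- r$seq_length
    if (is.na(n) || n <= 0L) fail("seq_length must be a positive integer")
    if (nchar(r$sequence) != n) fail("sequence length != seq_length")
    if (grepl("[^ACGU]", r$sequence)) fail("sequence has non-ACGU characters")
    if (!is.na(r$structure) && nchar(r$structure) != n) {
      fail("structure length != sequence length")
    }
    if (!is.na(r$loop_type)) {
      if (nchar(r$loop_type) != n) fail("loop_type length != sequence length")
      if (grepl(sprintf("[^%s]", paste(LOOP_ALPHABET, collapse = "")),
                r$loop_type)) {
        fail("loop_type has characters outside S/M/I/B/H/E/X")
      }
    }
    ns <- r$seq_scored
    if (!is.na(ns) && ns > n) fail("seq_scored > seq_length")
    for (dt in intersect(DATA_TYPES, names(constructs))) {
      v <- r[[dt]][[1]]
      if (is.null(v)) next
      if (!is.na(ns) && length(v) != ns) {
        fail(sprintf("'%s' array has length %d, expected seq_scored = %d",
                     dt, length(v), ns))
      }
      e <- r[[paste0(dt, "_err")]][[1]]
      if (!is.null(e)) {
        if (length(e) != length(v)) fail(sprintf("'%s' error length mismatch", dt))
        if (any(e < 0, na.rm = TRUE)) fail(sprintf("'%s' errors negative", dt))
      }
    }
  }
  invisible(constructs)
}

#' Write constructs as JSON-lines
#'
#' Inverse of [read_constructs()]: one JSON object per line, full numeric
#' precision, absent data types omitted (never zero-filled), passthrough
#' `extra` fields restored.
#'
#' @inheritParams validate_constructs
#' @param path Output file path.
#' @inheritParams read_constructs
#' @return `path`, invisibly.
#' @export
write_constructs <- function(constructs, path,
                             error_keys = DEFAULT_ERROR_KEYS) {
  validate_constructs(constructs)
  lines <- vapply(seq_len(nrow(constructs)), function(i) {
    r <- constructs[i, ]
    o <- list(
      id = r$id, sequence = r$sequence, structure = r$structure,
      predicted_loop_type = r$loop_type, seq_length = r$seq_length,
      seq_scored = r$seq_scored, signal_to_noise = r$signal_to_noise,
      SN_filter = r$SN_filter
    )
    o <- o[!vapply(o, function(x) is.null(x) || all(is.na(x)), logical(1))]
    for (dt in intersect(DATA_TYPES, names(constructs))) {
      v <- r[[dt]][[1]]
      if (!is.null(v)) {
        o[[dt]] <- v
        e <- r[[paste0(dt, "_err")]][[1]]
        if (!is.null(e)) o[[error_keys[[dt]]]] <- e
      }
    }
    ex <- r$extra[[1]]
    if (length(ex)) o <- c(o, ex)
    as.character(jsonlite::toJSON(o, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
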