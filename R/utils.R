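# Internal helpers shared across modules.

# Sequence and loop-type alphabets. Featurization uses the 6-letter loop
# alphabet (X merged into E there, keeping 10 channels per window offset).
NT_ALPHABET <- c("A", "C", "G", "U")
LOOP_ALPHABET <- c("S", "M", "I", "B", "H", "E", "X")
LOOP_CHANNELS <- c("H", "E", "I", "M", "B", "S")

# Canonical data-type names and their error-array keys in the JSON-lines
# dialect. Dump versions disagree on error-key spelling, so readers accept
# an override map with this shape.
DATA_TYPES <- c("reactivity", "deg_Mg_pH10", "deg_pH10", "deg_Mg_50C",
                "deg_50C")
DEFAULT_ERROR_KEYS <- c(
  reactivity  = "reactivity_error",
  deg_Mg_pH10 = "deg_error_Mg_pH10",
  deg_pH10    = "deg_error_pH10",
  deg_Mg_50C  = "deg_error_Mg_50C",
  deg_50C     = "deg_error_50C"
)

# Run code with a locally-seeded RNG, leaving the caller's RNG state alone.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single string.", what))
  }
}

# FNV-1a 32-bit hash of a string, returned as 8 hex digits. Used only to
# stamp config hashes into output metadata headers.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    # 32-bit multiply by the FNV prime 2^24 + 403, kept exact in doubles
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# sample() that never interprets a length-1 vector as 1:n
resample <- function(x, size) x[sample.int(length(x), size)]
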