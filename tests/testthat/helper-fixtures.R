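# Shared fixtures, built in code at test time.

chars_of <- function(x) strsplit(x, "")[[1]]

# A small labelled synthetic dataset memoised per session.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synthetic_dataset(
        synthetic_config(n_constructs = 30, sn_fail_frac = 0, seed = 101)
      )
    }
    cache
  }
})

# Enumerate every nested structure of length n with hairpin loops >= 3 nt.
enumerate_structures <- function(n) {
  memo <- new.env(parent = emptyenv())
  rec <- function(m) {
    key <- as.character(m)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- if (m == 0L) "" else {
      res <- paste0(".", rec(m - 1L))
      if (m >= 5L) {
        for (k in 3:(m - 2L)) {
          for (a in rec(k)) {
            for (b in rec(m - k - 2L)) {
              res <- c(res, paste0("(", a, ")", b))
            }
          }
        }
      }
      res
    }
    memo[[key]] <- out
    out
  }
  rec(as.integer(n))
}

# Breadth-first-search oracle for graph distances, via igraph.
bfs_distance_oracle <- function(partner) {
  n <- length(partner)
  edges <- if (n > 1L) cbind(seq_len(n - 1L), 2:n) else
    matrix(integer(0), 0, 2)
  paired <- which(!is.na(partner) & partner > seq_along(partner))
  if (length(paired)) edges <- rbind(edges, cbind(paired, partner[paired]))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, as.vector(t(edges)))
  unname(igraph::distances(g))
}

# Construct families for split curation: `sizes[i]` near-identical variants
# of a shared random core per family, plus planted singletons.
make_family_constructs <- function(sizes, len = 60L, seed = 1L) {
  withr::with_seed(seed, {
    rows <- list()
    fam <- 0L
    for (s in sizes) {
      fam <- fam + 1L
      base <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
      for (k in seq_len(s)) {
        v <- base
        if (k > 1L) {
          mut <- sample.int(len, 3L)       # 5% divergence within a family
          v[mut] <- sample(c("A", "C", "G", "U"), 3L, replace = TRUE)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = sprintf("fam%02d_%02d", fam, k),
          sequence = paste(v, collapse = ""),
          structure = strrep(".", len),
          loop_type = strrep("E", len),
          seq_length = len, seq_scored = len,
          signal_to_noise = 10, SN_filter = 1L, extra = list(list())
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

# Stack measured scored values of a dataset into a matrix (columns = data
# types) plus the planted noise-free truth in the same layout.
dataset_matrices <- function(ds, data_types) {
  long <- constructs_to_long(ds$constructs, data_types)
  truth <- ds$truth
  key <- paste(long$id, long$position, long$data_type)
  tv <- truth$value[match(key, paste(truth$id, truth$position,
                                     truth$data_type))]
  wide_m <- tidyr::pivot_wider(
    cbind(long, planted = tv),
    id_cols = c("id", "position"), names_from = "data_type",
    values_from = c("value", "planted")
  )
  list(
    measured = as.matrix(wide_m[paste0("value_", data_types)]),
    planted = as.matrix(wide_m[paste0("planted_", data_types)]),
    id = wide_m$id
  )
}
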