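#' Parse dot-bracket notation into a pair table
#'
#' Matches nested parentheses into a partner table. Pseudoknot characters
#' (`[`, `{`, `<` and their mates) are rejected explicitly: this package
#' handles nested-only secondary structures, as produced by MFE folding.
#'
#' @param db Dot-bracket string over `(`, `)`, `.`.
#' @return Integer vector `partner` of the same length: `partner[i]` is
#'   the 1-based index paired with position `i`, or `NA` if unpaired.
#' @examples
#' parse_dotbracket("((...))")
#' @export
parse_dotbracket <- function(db) {
  stopifnot_scalar_string(db, "db")
  cs <- chars(db)
  if (any(cs %in% c("[", "]", "{", "}", "<", ">"))) {
    abort("Pseudoknot brackets found: only nested-only structures ((), .) are supported.")
  }
  bad <- setdiff(unique(cs), c("(", ")", "."))
  if (length(bad)) {
    abort(sprintf("Invalid dot-bracket character(s): %s",
                  paste(bad, collapse = " ")))
  }
  n <- length(cs)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (cs[i] == "(") {
      stack <- c(stack, i)
    } else if (cs[i] == ")") {
      if (length(stack) == 0L) {
        abort(sprintf("Unbalanced ')' at position %d.", i))
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i
      partner[i] <- j
    }
  }
  if (length(stack)) {
    abort(sprintf("Unbalanced '(' at position %d.", stack[1]))
  }
  partner
}

validate_pair_table <- function(partner) {
  n <- length(partner)
  paired <- which(!is.na(partner))
  if (any(partner[paired] < 1L | partner[paired] > n) ||
      any(partner[partner[paired]] != paired) ||
      any(partner[paired] == paired)) {
    abort("Invalid pair table: partner[] is not an involution.")
  }
  invisible(partner)
}

# Loop decomposition shared by assign_loop_types() and extract_motifs().
# Walks every loop of the structure tree. For the loop closed by pair
# (i, j) (or the exterior, closer = NULL) it records the child helices
# (branches) and the unpaired runs between them.
decompose_loops <- function(partner) {
  validate_pair_table(partner)
  n <- length(partner)
  loops <- list()
  # walk the region (l..r) that is the interior of `closer` (or the whole
  # sequence for the exterior loop)
  walk <- function(l, r, closer) {
    branches <- list()   # each: c(start, end) of a child helix-closing pair
    runs <- list()       # unpaired runs, in 5'->3' order
    gap <- integer(0)
    k <- l
    while (k <= r) {
      p <- partner[k]
      if (is.na(p)) {
        gap <- c(gap, k)
        k <- k + 1L
      } else {
        runs[[length(runs) + 1L]] <- gap
        gap <- integer(0)
        branches[[length(branches) + 1L]] <- c(k, p)
        k <- p + 1L
      }
    }
    runs[[length(runs) + 1L]] <- gap
    loops[[length(loops) + 1L]] <<- list(closer = closer,
                                         branches = branches, runs = runs)
    for (b in branches) {
      # descend through the helix: skip stacked pairs, stop at the loop
      i <- b[1]; j <- b[2]
      while (i + 1L <= n && !is.na(partner[i + 1L]) &&
             partner[i + 1L] == j - 1L) {
        i <- i + 1L; j <- j - 1L
      }
      if (i + 1L <= j - 1L) walk(i + 1L, j - 1L, c(i, j))
      else loops[[length(loops) + 1L]] <<- list(closer = c(i, j),
                                                branches = list(),
                                                runs = list(integer(0),
                                                            integer(0)))
    }
  }
  if (n > 0L) walk(1L, n, NULL)
  loops
}

#' Annotate per-nucleotide loop types
#'
#' Assigns each position one of the seven loop-type classes used for
#' degradation featurization: `S` stem (paired), `H` hairpin loop,
#' `I` internal loop (unpaired on both strands between two helices),
#' `B` bulge (one strand only), `M` multiloop (loop with the closing pair
#' plus at least two child helices, i.e. >= 3 enclosed stems), `E`
#' external loop between top-level helices, `X` 5'/3' terminal unpaired
#' runs (dangles) flanking at least one helix. A fully unpaired sequence
#' is labelled `E` throughout.
#'
#' @param partner Pair table from [parse_dotbracket()].
#' @return A string over `S`,`E`,`I`,`B`,`H`,`M`,`X` of the same length.
#' @examples
#' assign_loop_types(parse_dotbracket("(((...)))"))
#' @export
assign_loop_types <- function(partner) {
  n <- length(partner)
  lab <- rep(NA_character_, n)
  lab[!is.na(partner)] <- "S"
  has_stem <- any(!is.na(partner))
  for (lp in decompose_loops(partner)) {
    runs <- lp$runs
    nb <- length(lp$branches)
    if (is.null(lp$closer)) {
      # exterior loop: first/last runs touching the ends are dangles (X)
      # when any helix exists; everything else at top level is E
      for (ri in seq_along(runs)) {
        run <- runs[[ri]]
        if (!length(run)) next
        cls <- "E"
        if (has_stem &&
            ((ri == 1L && run[1] == 1L) ||
             (ri == length(runs) && run[length(run)] == n))) {
          cls <- "X"
        }
        lab[run] <- cls
      }
    } else {
      sizes <- lengths(runs)
      cls <- if (nb == 0L) "H"
             else if (nb >= 2L) "M"
             else if (sizes[1] > 0L && sizes[2] > 0L) "I"
             else "B"
      for (run in runs) if (length(run)) lab[run] <- cls
    }
  }
  paste(lab, collapse = "")
}

#' Graph distances over backbone and base-pair edges
#'
#' Shortest-path lengths on the graph whose edges are the covalent
#' backbone (i, i+1) and the base pairs (i, partner\[i\]) — the distance
#' embedding used to represent nucleotide proximity in structured RNA.
#'
#' @param partner Pair table from [parse_dotbracket()].
#' @return Symmetric integer matrix of shortest-path lengths, zero
#'   diagonal.
#' @export
graph_distance_matrix <- function(partner) {
  validate_pair_table(partner)
  n <- length(partner)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    if (i > 1L) nb <- c(nb, i - 1L)
    if (i < n) nb <- c(nb, i + 1L)
    if (!is.na(partner[i])) nb <- c(nb, partner[i])
    adj[[i]] <- nb
  }
  d <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    lev <- 0L
    while (length(frontier)) {
      lev <- lev + 1L
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- lev
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

#' Per-nucleotide unpaired probability
#'
#' `p_unpaired[i] = max(0, 1 - sum_j bpp[i, j])` — the partition-function
#' probability that position i is unpaired, the classical baseline for
#' in-line hydrolysis propensity. Small negative residues from numerical
#' noise are clipped to zero.
#'
#' @param bpp Base-pair probability matrix (see [read_bpp()]).
#' @return Numeric vector in \[0, 1\], one entry per position.
#' @export
unpaired_probability <- function(bpp) {
  validate_bpp(bpp)
  p <- 1 - rowSums(bpp)
  if (any(p < 0)) {
    inform("Clipping negative unpaired-probability residues to 0.")
    p[p < 0] <- 0
  }
  unname(p)
}

#' Decompose a structure into motifs
#'
#' Complete loop decomposition of a nested structure: maximal helices
#' (stems), hairpin loops (with size; 3 = triloop, 4 = tetraloop),
#' internal loops (with strand lengths and symmetry flag), bulges,
#' multiloops, and exterior/dangle regions. Motif position sets partition
#' the sequence.
#'
#' @param partner Pair table from [parse_dotbracket()].
#' @return A tibble with columns `motif_id`, `kind` (`stem`, `hairpin`,
#'   `internal`, `bulge`, `multiloop`, `exterior`), `positions`
#'   (list-column of 1-based indices), `loop_size` (hairpins),
#'   `left_len`, `right_len`, `symmetric` (internal loops).
#' @export
extract_motifs <- function(partner) {
  validate_pair_table(partner)
  n <- length(partner)
  rows <- list()
  add <- function(kind, positions, loop_size = NA_integer_,
                  left_len = NA_integer_, right_len = NA_integer_,
                  symmetric = NA) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      kind = kind, positions = list(sort(positions)),
      loop_size = as.integer(loop_size), left_len = as.integer(left_len),
      right_len = as.integer(right_len), symmetric = symmetric
    )
  }
  # stems: maximal runs of stacked pairs
  opened <- which(!is.na(partner) & partner > seq_len(n))
  if (length(opened)) {
    visited <- rep(FALSE, n)
    for (i in opened) {
      if (visited[i]) next
      a <- i; b <- partner[i]
      pos <- c(a, b)
      visited[c(a, b)] <- TRUE
      while (a + 1L <= n && !is.na(partner[a + 1L]) &&
             partner[a + 1L] == b - 1L) {
        a <- a + 1L; b <- b - 1L
        pos <- c(pos, a, b)
        visited[c(a, b)] <- TRUE
      }
      add("stem", pos)
    }
  }
  exterior <- integer(0)
  for (lp in decompose_loops(partner)) {
    unp <- unlist(lp$runs, use.names = FALSE)
    nb <- length(lp$branches)
    if (is.null(lp$closer)) {
      exterior <- c(exterior, unp)
    } else if (nb == 0L) {
      if (length(unp)) add("hairpin", unp, loop_size = length(unp))
    } else if (nb >= 2L) {
      if (length(unp)) add("multiloop", unp)
    } else {
      sizes <- lengths(lp$runs)
      if (sizes[1] > 0L && sizes[2] > 0L) {
        add("internal", unp, left_len = sizes[1], right_len = sizes[2],
            symmetric = sizes[1] == sizes[2])
      } else if (sum(sizes) > 0L) {
        add("bulge", unp)
      }
    }
  }
  if (length(exterior) || length(rows) == 0L) {
    add("exterior", if (n > 0L && length(rows) == 0L && !length(exterior))
      seq_len(n) else exterior)
  }
  out <- dplyr::bind_rows(rows)
  out$motif_id <- seq_len(nrow(out))
  out[, c("motif_id", "kind", "positions", "loop_size", "left_len",
          "right_len", "symmetric")]
}
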