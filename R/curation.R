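#' Annotate constructs with the signal/noise filter
#'
#' Applies the three curation criteria: the profile minimum across the
#' degradation data types must exceed `min_value`, the maximum must stay
#' below `max_value`, and the SHAPE-reactivity signal-to-noise ratio
#' (mean of value/error over scored nucleotides) must exceed
#' `sn_threshold`. Records are annotated, never deleted: the returned
#' tibble carries `SN_filter` (1 = passes) and `sn_fail_reason`
#' (`NA` when passing); profile values are untouched. Records missing a
#' required profile are flagged with reason `"missing_profile"`.
#'
#' @param constructs Construct tibble.
#' @param min_value,max_value Profile bounds applied across the available
#'   degradation/reactivity data types (defaults 0.5 and 20).
#' @param sn_threshold SHAPE SN threshold (default 1.0).
#' @return The input tibble with refreshed `SN_filter` and a
#'   `sn_fail_reason` column; the kept set is `SN_filter == 1`.
#' @export
apply_sn_filter <- function(constructs, min_value = 0.5, max_value = 20,
                            sn_threshold = 1.0) {
  dts <- intersect(DATA_TYPES, names(constructs))
  flags <- integer(nrow(constructs))
  reasons <- rep(NA_character_, nrow(constructs))
  for (i in seq_len(nrow(constructs))) {
    r <- constructs[i, ]
    vals <- unlist(lapply(dts, function(dt) r[[dt]][[1]]),
                   use.names = FALSE)
    react <- if ("reactivity" %in% dts) r$reactivity[[1]] else NULL
    rerr <- if ("reactivity_err" %in% names(constructs))
      r$reactivity_err[[1]] else NULL
    if (!length(vals) || is.null(react) || is.null(rerr)) {
      reasons[i] <- "missing_profile"
      next
    }
    if (min(vals, na.rm = TRUE) <= min_value) {
      reasons[i] <- "min_value"
    } else if (max(vals, na.rm = TRUE) >= max_value) {
      reasons[i] <- "max_value"
    } else {
      sn <- sn_ratio(list(react), list(rerr))
      if (!(sn > sn_threshold)) reasons[i] <- "sn_ratio"
      else flags[i] <- 1L
    }
  }
  constructs$SN_filter <- flags
  constructs$sn_fail_reason <- reasons
  constructs
}

#' Pairwise sequence distance
#'
#' Distance in \[0, 1\] used for clustering-based split curation:
#' equal-length sequences use the normalized Hamming distance; unequal
#' lengths use `1 - matches / max(length)` from a global
#' Needleman-Wunsch alignment (match 1, mismatch 0, gap open 0, gap
#' extend 1; via Biostrings).
#'
#' @param a,b RNA sequence strings over A/C/G/U.
#' @return Distance in \[0, 1\]; 0 for identical sequences.
#' @export
sequence_distance <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort("Empty sequence.")
  if (nchar(a) == nchar(b)) {
    ca <- chars(a); cb <- chars(b)
    return(sum(ca != cb) / length(ca))
  }
  1 - alignment_matches(a, b) / max(nchar(a), nchar(b))
}

alignment_matches <- function(a, b) {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    gsub("U", "T", a, fixed = TRUE), gsub("U", "T", b, fixed = TRUE),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(aln)
}

#' Pairwise distance matrix for a set of sequences
#'
#' @param sequences Character vector of RNA sequences.
#' @return Symmetric matrix of [sequence_distance()] values.
#' @export
sequence_distance_matrix <- function(sequences) {
  n <- length(sequences)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sequence_distance(sequences[i], sequences[j])
    }
  }
  d
}

#' Clustering-based blind split
#'
#' Builds a train / public-test / private-test split designed to keep the
#' private test set maximally distant from over-represented sequence
#' families: sequences are clustered with Ward-linkage hierarchical
#' clustering on the pairwise sequence-distance matrix and cut into flat
#' clusters at a cophenetic (merge-height) threshold. Every cluster with
#' at most `max_private_size` members goes wholly to the private test
#' set; if `n_private_test` asks for more, one seeded-random member from
#' each of enough randomly-selected larger clusters is added. Remaining
#' clusters are assigned wholly to the public test set (until
#' `n_public_test` is reached) or to training, by seeded sampling at
#' cluster granularity. Records are sorted by id internally, so the
#' assignment is invariant to input order and deterministic given `seed`.
#'
#' @param constructs Construct tibble (typically pre-filtered with
#'   [apply_sn_filter()]).
#' @param cut Cophenetic distance threshold for flat clusters
#'   (default 0.5, i.e. members of a cluster share > 50% similarity
#'   structure in the dendrogram).
#' @param max_private_size Clusters of this size or smaller go wholly to
#'   the private test set (default 3).
#' @param n_private_test,n_public_test Optional target sizes.
#' @param seed Integer seed (mandatory) for all sampling.
#' @return A tibble (`split_assignment`): `id`, `split` (`train`,
#'   `public_test`, `private_test`), `cluster_id`, `cluster_size`,
#'   `SN_filter`.
#' @export
cluster_split <- function(constructs, cut = 0.5, max_private_size = 3L,
                          n_private_test = NULL, n_public_test = NULL,
                          seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (nrow(constructs) < 2L) abort("Need at least 2 records to split.")
  ord <- order(constructs$id)
  cs <- constructs[ord, ]
  d <- sequence_distance_matrix(cs$sequence)
  hc <- hclust(as.dist(d), method = "ward.D2")
  cl <- cutree(hc, h = cut)
  sizes <- table(cl)
  cluster_ids <- as.integer(names(sizes))

  small <- cluster_ids[sizes <= max_private_size]
  big <- setdiff(cluster_ids, small)
  split <- rep(NA_character_, nrow(cs))
  split[cl %in% small] <- "private_test"

  with_seed(seed, {
    n_priv <- sum(split == "private_test", na.rm = TRUE)
    if (!is.null(n_private_test) && n_private_test > n_priv) {
      need <- n_private_test - n_priv
      if (need > length(big)) {
        abort("Infeasible `n_private_test`: not enough clusters to draw from.")
      }
      donors <- resample(big, need)
      for (cid in donors) {
        members <- which(cl == cid & is.na(split))
        split[resample(members, 1L)] <- "private_test"
      }
    }
    # assign remaining clusters wholly, in seeded-random order
    remaining <- resample(big, length(big))
    target_pub <- n_public_test %||% 0L
    n_pub <- 0L
    for (cid in remaining) {
      members <- which(cl == cid & is.na(split))
      if (n_pub < target_pub) {
        split[members] <- "public_test"
        n_pub <- n_pub + length(members)
      } else {
        split[members] <- "train"
      }
    }
    if (!is.null(n_public_test) && n_pub < n_public_test) {
      abort("Infeasible `n_public_test`: not enough non-private records.")
    }
  })

  structure(
    tibble::tibble(
      id = cs$id, split = split, cluster_id = as.integer(cl),
      cluster_size = as.integer(sizes[as.character(cl)]),
      SN_filter = if ("SN_filter" %in% names(cs)) cs$SN_filter else
        NA_integer_
    ),
    class = c("split_assignment", class(tibble::tibble())),
    hclust = hc
  )
}
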