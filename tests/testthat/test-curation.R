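make_profile_record <- function(id, react, rerr, degs = NULL) {
  n <- length(react)
  row <- tibble::tibble(
    id = id, sequence = strrep("A", n), structure = strrep(".", n),
    loop_type = strrep("E", n), seq_length = n, seq_scored = n,
    signal_to_noise = NA_real_, SN_filter = NA_integer_,
    reactivity = list(react), reactivity_err = list(rerr),
    extra = list(list())
  )
  if (!is.null(degs)) {
    row$deg_Mg_pH10 <- list(degs)
    row$deg_Mg_pH10_err <- list(rep(0.1, n))
  }
  row
}

test_that("SN filter keeps exactly the planted passing records, without mutation", {
  good <- make_profile_record("good", rep(2, 5), rep(0.5, 5), rep(1, 5))
  low_sn <- make_profile_record("low_sn", rep(2, 5), rep(4, 5), rep(1, 5))
  low_min <- make_profile_record("low_min", c(0.4, rep(2, 4)), rep(0.5, 5),
                                 rep(1, 5))
  high_max <- make_profile_record("high_max", rep(2, 5), rep(0.5, 5),
                                  c(25, rep(1, 4)))
  missing <- make_profile_record("missing", rep(2, 5), rep(0.5, 5))
  missing$reactivity <- list(NULL)
  batch <- dplyr::bind_rows(good, low_sn, low_min, high_max, missing)

  before <- batch$reactivity
  out <- apply_sn_filter(batch)
  expect_equal(nrow(out), 5L)                       # nothing deleted
  expect_identical(out$reactivity, before)          # pure annotation
  expect_equal(out$SN_filter, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(out$sn_fail_reason,
               c(NA, "sn_ratio", "min_value", "max_value",
                 "missing_profile"))
})

test_that("SN filter flag rate matches the planted failure fraction", {
  ds <- synthetic_dataset(
    synthetic_config(n_constructs = 150, sn_fail_frac = 0.2, seed = 77)
  )
  flagged <- sum(ds$constructs$SN_filter == 0L)
  # binomial(150, 0.2): allow +/- 4 sd around the mean
  expect_gt(flagged, 30 - 4 * sqrt(150 * 0.2 * 0.8))
  expect_lt(flagged, 30 + 4 * sqrt(150 * 0.2 * 0.8))
})

test_that("sequence distance: Hamming for equal length, alignment otherwise", {
  expect_equal(sequence_distance("ACGU", "ACGU"), 0)
  expect_equal(sequence_distance("AAAA", "CCCC"), 1)
  expect_equal(sequence_distance("ACGU", "ACGA"), 0.25)   # 1 mismatch / 4
  # unequal lengths: one deletion, 4 of 5 positions match
  expect_equal(sequence_distance("ACGUA", "ACGA"), 1 - 4 / 5)
  expect_error(sequence_distance("", "A"), "Empty")
})

test_that("small clusters land wholly in the private test set", {
  # 3 families of 6 near-identical variants + singleton/doubleton/tripleton
  cs <- make_family_constructs(c(6, 6, 6, 1, 2, 3), seed = 5)
  asg <- cluster_split(cs, cut = 0.5, max_private_size = 3,
                       n_public_test = 6, seed = 9)
  small_ids <- cs$id[grepl("fam0[456]", cs$id)]
  expect_true(all(asg$split[asg$id %in% small_ids] == "private_test"))
  # big-family members never leak into private without an explicit target
  big_ids <- cs$id[grepl("fam0[123]", cs$id)]
  expect_true(all(asg$split[asg$id %in% big_ids] != "private_test"))
  # splits disjoint and exhaustive
  expect_setequal(asg$id, cs$id)
  expect_true(all(asg$split %in% c("train", "public_test", "private_test")))
  # public test assigned at cluster granularity
  pub_clusters <- unique(asg$cluster_id[asg$split == "public_test"])
  for (cid in pub_clusters) {
    expect_true(all(asg$split[asg$cluster_id == cid] == "public_test"))
  }
})

test_that("cophenetic distance within every flat cluster stays below the cut", {
  cs <- make_family_constructs(c(5, 4, 3, 2, 1), seed = 11)
  asg <- cluster_split(cs, cut = 0.5, seed = 2)
  hc <- attr(asg, "hclust")
  coph <- as.matrix(cophenetic(hc))
  for (cid in unique(asg$cluster_id)) {
    members <- which(asg$cluster_id == cid)
    if (length(members) > 1) {
      expect_lte(max(coph[members, members]), 0.5)
    }
  }
})

test_that("splits are seed-deterministic and input-order invariant", {
  cs <- make_family_constructs(c(5, 5, 4, 1, 2), seed = 3)
  a1 <- cluster_split(cs, n_public_test = 4, seed = 42)
  a2 <- cluster_split(cs, n_public_test = 4, seed = 42)
  expect_equal(as.data.frame(a1), as.data.frame(a2))
  perm <- withr::with_seed(1, sample.int(nrow(cs)))
  a3 <- cluster_split(cs[perm, ], n_public_test = 4, seed = 42)
  expect_equal(as.data.frame(a1), as.data.frame(a3))
})

test_that("degenerate all-identical input yields one sampled private member", {
  cs <- make_family_constructs(c(5), seed = 4)
  cs$sequence <- rep(cs$sequence[1], 5)     # strictly identical
  asg <- cluster_split(cs, n_private_test = 1, seed = 8)
  expect_equal(length(unique(asg$cluster_id)), 1L)
  expect_equal(sum(asg$split == "private_test"), 1L)
})
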