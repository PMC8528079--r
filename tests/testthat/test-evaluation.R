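test_that("MCRMSE matches hand-computed fixtures", {
  m <- cbind(a = c(1, 2, 3), b = c(0, 1, 2))
  expect_equal(mcrmse(m, m)$mcrmse, 0)
  # constant residual r in every column -> MCRMSE r
  expect_equal(mcrmse(m, m + 0.3)$mcrmse, 0.3)
  # hand arithmetic on a 4-nt fixture: column RMSEs 0.2 and 0.4 -> 0.3
  meas <- cbind(a = rep(0, 4), b = rep(0, 4))
  pred <- cbind(a = rep(0.2, 4), b = rep(0.4, 4))
  rep_ <- mcrmse(meas, pred)
  expect_equal(rep_$per_type$rmse, c(0.2, 0.4))
  expect_equal(rep_$mcrmse, 0.3)
  # single data type: MCRMSE is that column's RMSE
  expect_equal(mcrmse(meas[, 1], pred[, 1])$mcrmse, 0.2)
})

test_that("MCRMSE is invariant to row order and mask-respecting concatenation", {
  withr::with_seed(3, {
    meas <- matrix(rnorm(60), 20, 3)
    pred <- meas + matrix(rnorm(60, 0, 0.4), 20, 3)
    base <- mcrmse(meas, pred)$mcrmse
    perm <- sample.int(20)
    expect_equal(mcrmse(meas[perm, ], pred[perm, ])$mcrmse, base)
    # appending masked-out rows changes nothing
    meas2 <- rbind(meas, matrix(NA_real_, 5, 3))
    pred2 <- rbind(pred, matrix(0, 5, 3))
    expect_equal(mcrmse(meas2, pred2)$mcrmse, base)
  })
})

test_that("MCRMSE errors when a column has no scored nucleotides", {
  meas <- cbind(a = c(1, 2), b = c(NA_real_, NA_real_))
  expect_error(mcrmse(meas, meas * 0), "column 'b'")
})

test_that("within-error fraction: exact, strict, and monotone in sigma", {
  y <- c(1, 2, 3)
  expect_equal(fraction_within_error(y, y, rep(0.1, 3)), 1)
  expect_equal(fraction_within_error(y, y + 0.5, rep(0, 3)), 0)   # strict
  withr::with_seed(4, {
    truth <- rnorm(500)
    meas <- truth + rnorm(500, 0, 0.3)
    s1 <- runif(500, 0.1, 0.5)
    f1 <- fraction_within_error(meas, truth, s1)
    f2 <- fraction_within_error(meas, truth, s1 * 2)
    expect_gte(f2, f1)
  })
})

test_that("SN ratio follows the two-level mean of value over error", {
  expect_equal(sn_ratio(rep(2, 10), rep(1, 10)), 2)
  expect_equal(sn_ratio(c(1, 3), c(1, 1)), 2)
  # two data types with per-type means 1 and 3 -> 2 (hand arithmetic)
  expect_equal(sn_ratio(list(c(0.5, 1.5), c(3, 3)),
                        list(c(0.5, 1.5) / c(1, 1), c(1, 1))), 2)
  expect_error(sn_ratio(c(1, 2), c(1, 0)), "sigma == 0")
})

test_that("motif aggregation averages by class and counts partition", {
  pt <- parse_dotbracket("(((...)))")
  motifs <- extract_motifs(pt)
  # constant signal -> every class mean is that constant
  agg <- aggregate_by_motif(rep(0.7, 9), motifs)
  expect_true(all(abs(agg$mean - 0.7) < 1e-12))
  # signal 1 on hairpin positions only
  v <- rep(0, 9); v[4:6] <- 1
  agg <- aggregate_by_motif(v, motifs)
  expect_equal(agg$mean[agg$class == "hairpin_triloop"], 1)
  expect_equal(agg$mean[agg$class == "stem"], 0)
  expect_equal(sum(agg$n), 9L)

  # class vocabulary distinguishes hairpin sizes and internal symmetry
  m2 <- extract_motifs(parse_dotbracket("((....))"))
  a2 <- aggregate_by_motif(rep(1, 8), m2)
  expect_true("hairpin_tetraloop" %in% a2$class)
})

test_that("per-construct RMSE is consistent with MCRMSE on one construct", {
  ds <- small_dataset()
  one <- ds$constructs[1, ]
  pred <- constructs_to_long(one)
  pred$value <- pred$value + 0.25
  tab <- per_construct_rmse(one, pred)
  expect_equal(tab$rmse, rep(0.25, nrow(tab)), tolerance = 1e-12)
  rep_ <- score_predictions(one, pred)
  expect_equal(rep_$mcrmse, mean(tab$rmse), tolerance = 1e-12)
})

test_that("score_predictions agrees with matrix MCRMSE on a full dataset", {
  ds <- small_dataset()
  dts <- c("reactivity", "deg_Mg_pH10", "deg_Mg_50C")
  long <- constructs_to_long(ds$constructs, dts)
  pred <- long
  withr::with_seed(6, pred$value <- pred$value + rnorm(nrow(pred), 0, 0.1))
  rep_ <- score_predictions(ds$constructs,
                            pred[, c("id", "position", "data_type", "value")])
  key <- paste(long$id, long$position, long$data_type)
  resid <- pred$value - long$value
  by_type <- tapply(resid^2, long$data_type, mean)
  expect_equal(rep_$mcrmse, mean(sqrt(by_type[dts])), tolerance = 1e-12)
})

test_that("spearman matches a rank-then-Pearson oracle and handles edges", {
  x <- c(3, 1, 2, 5, 4)
  expect_equal(spearman(x, x), 1)
  expect_equal(spearman(x, -x), -1)
  expect_error(spearman(x, rep(1, 5)), "constant")
  withr::with_seed(12, {
    for (rep in 1:50) {
      a <- rnorm(40)
      b <- rnorm(40) + a * runif(1, -1, 1)
      oracle <- cor(rank(a), rank(b))       # rank + Pearson by hand
      expect_equal(spearman(a, b), oracle, tolerance = 1e-12)
    }
  })
})
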