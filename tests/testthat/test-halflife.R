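test_that("total rate sums the probed window and validates it", {
  expect_equal(total_rate(rep(0.01, 100), 0, 100), 1.0)
  expect_error(total_rate(rep(0.01, 100), 50, 50), "invalid")
  expect_error(total_rate(rep(0.01, 100), -1, 10), "invalid")
  expect_error(total_rate(rep(0.01, 100), 0, 101), "invalid")
  withr::with_seed(5, {
    x <- rnorm(80)
    s <- 7L; e <- 63L
    acc <- 0
    for (i in (s + 1):e) acc <- acc + x[i]   # brute-force loop oracle
    expect_equal(total_rate(x, s, e), acc, tolerance = 1e-15)
  })
})

test_that("rate summation is additive over window partitions", {
  withr::with_seed(6, {
    x <- runif(120)
    expect_equal(total_rate(x, 0, 120),
                 total_rate(x, 0, 47) + total_rate(x, 47, 120),
                 tolerance = 1e-15)
  })
})

test_that("half-life closed forms hold", {
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(half_life(0.0231), log(2) / 0.0231)
  expect_equal(round(half_life(0.0231)), 30)
  expect_error(half_life(0), "positive")
  expect_error(half_life(-1), "positive")
  # monotone: increasing any rate shortens the half-life
  x <- rep(0.01, 50)
  h0 <- half_life(total_rate(x, 0, 50))
  x[20] <- x[20] + 0.005
  expect_lt(half_life(total_rate(x, 0, 50)), h0)
})

test_that("length-normalized rate is the window mean", {
  expect_equal(length_normalized_rate(rep(0.3, 40), 0, 40), 0.3)
  expect_equal(length_normalized_rate(rep(0.3, 80), 0, 80), 0.3)
  withr::with_seed(7, {
    x <- runif(60)
    expect_equal(length_normalized_rate(x, 10, 50),
                 total_rate(x, 10, 50) / 40)
  })
})

test_that("unpaired-sum baseline composes unpaired probability with summation", {
  expect_equal(unpaired_sum_baseline(matrix(0, 30, 30), 0, 20), 20)
  m <- matrix(0, 10, 10)
  for (i in 1:5) { m[i, 11 - i] <- 1; m[11 - i, i] <- 1 }
  expect_equal(unpaired_sum_baseline(m, 0, 10), 0)
  withr::with_seed(8, {
    n <- 12
    m <- matrix(0, n, n)
    for (i in 1:5) m[i, n - i + 1] <- m[n - i + 1, i] <- runif(1, 0, 0.9)
    expect_equal(unpaired_sum_baseline(m, 2, 9),
                 total_rate(unpaired_probability(m), 2, 9))
  })
})

test_that("predicting on the full mRNA differs from predicting the excised window", {
  # fixture where the 5' UTR pairs with the CDS: excising the CDS removes
  # those interactions, so the summed prediction changes
  model <- small_dataset()$models$reactivity
  utr <- "GGGGGGGG"
  cds <- "AAACCCCCUUUAAACCCCCC"
  seqfull <- paste0(utr, cds)
  # UTR paired into the 3' end of the CDS (8 pairs, 12-nt loop)
  structure_full <- paste0(strrep("(", 8), strrep(".", 12), strrep(")", 8))
  ct_full <- tibble::tibble(
    id = "mrna", sequence = seqfull, structure = structure_full,
    loop_type = NA_character_, seq_length = nchar(seqfull)
  )
  win_start <- nchar(utr); win_end <- nchar(seqfull)
  pred_full <- predict(model, ct_full)$value
  sum_full <- total_rate(pred_full, win_start, win_end)
  # excised window refolds with no partner for the former UTR contacts
  ct_win <- tibble::tibble(
    id = "cds", sequence = cds, structure = strrep(".", nchar(cds)),
    loop_type = NA_character_, seq_length = nchar(cds)
  )
  sum_win <- total_rate(predict(model, ct_win)$value, 0, nchar(cds))
  expect_false(isTRUE(all.equal(sum_full, sum_win)))
})

test_that("predictor comparison ranks predictors and bounds the noise ceiling", {
  withr::with_seed(9, {
    n <- 40
    truth <- runif(n, 0.5, 2)
    dat <- tibble::tibble(
      measured = truth,
      se = rep(0.05, n),
      perfect = truth,
      noisy = truth + rnorm(n, 0, 0.6),
      anti = -truth
    )
    tab <- compare_predictors(dat, c("perfect", "noisy", "anti"),
                              n_boot = 200, seed = 3)
    expect_equal(tab$spearman[tab$predictor == "perfect"], 1)
    expect_equal(tab$spearman[tab$predictor == "anti"], -1)
    expect_lt(abs(tab$spearman[tab$predictor == "noisy"]), 1)
    ceiling_rho <- tab$spearman[tab$predictor == "noise_ceiling"]
    expect_gt(ceiling_rho, 0.9)   # small SE: ceiling near 1
    # SE -> 0 limit: ceiling -> 1
    dat0 <- dat; dat0$se <- rep(1e-9, n)
    tab0 <- compare_predictors(dat0, "perfect", n_boot = 20, seed = 3)
    expect_equal(tab0$spearman[tab0$predictor == "noise_ceiling"], 1)
  })
})

test_that("noise-ceiling estimate tracks a simulation oracle", {
  # with known rank-disrupting noise, the ceiling matches an independent
  # Monte-Carlo estimate of E[spearman(y + e, y)]
  withr::with_seed(10, {
    n <- 60
    y <- rnorm(n)
    se <- rep(0.8, n)
    dat <- tibble::tibble(measured = y, se = se, p = y)
    tab <- compare_predictors(dat, "p", n_boot = 400, seed = 5)
    oracle <- mean(replicate(400, cor(y + rnorm(n, 0, se), y,
                                      method = "spearman")))
    expect_equal(tab$spearman[tab$predictor == "noise_ceiling"], oracle,
                 tolerance = 0.05)
  })
})
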