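test_that("parameter accounting follows the 10-channels-per-offset rule", {
  expect_equal(n_parameters(12), 251L)
  expect_equal(n_parameters(0), 11L)
  expect_equal(n_parameters(1), 31L)
  expect_error(n_parameters(-1), "nonnegative")
})

test_that("featurization is one-hot with all-zero out-of-range offsets", {
  v <- featurize("A", "E", k = 1, w = 0)
  expect_equal(sum(v), 2)
  expect_equal(v[["off+00.A"]], 1)
  expect_equal(v[["off+00.E"]], 1)

  # fully in-range window: exactly one nt + one loop indicator per offset
  v <- featurize("GGAAACCCUU", "SSHHHSSSXX", k = 5, w = 2)
  expect_equal(sum(v), 2 * (2 * 2 + 1))

  # k at the 5' edge: offsets -2, -1 fall outside and contribute zeros
  v <- featurize("GGAAACCCUU", "SSHHHSSSXX", k = 1, w = 2)
  expect_equal(sum(v), 6)
  expect_equal(sum(v[1:20]), 0)

  # X dangles are merged into the E channel at featurization time
  v <- featurize("GGAAACCCUU", "SSHHHSSSXX", k = 10, w = 0)
  expect_equal(v[["off+00.E"]], 1)
  expect_error(featurize("ACGT", "EEEE", 1, 0), "Invalid sequence")
})

test_that("ridge fit recovers planted predictions on noise-free labels", {
  ds <- synthetic_dataset(
    synthetic_config(n_constructs = 25, noise_sd = 0, sn_fail_frac = 0,
                     seed = 31)
  )
  fit <- fit_degscore(ds$constructs, "deg_Mg_pH10", lambda = 1e-8)
  pred <- predict(fit, ds$constructs)
  truth <- ds$truth[ds$truth$data_type == "deg_Mg_pH10", ]
  j <- dplyr::inner_join(truth, pred, by = c("id", "position", "data_type"))
  expect_lt(sqrt(mean((j$value.x - j$value.y)^2)), 1e-6)
})

test_that("infinite regularization shrinks predictions to the label mean", {
  ds <- small_dataset()
  fit <- fit_degscore(ds$constructs, "reactivity", lambda = 1e12)
  expect_lt(max(abs(fit$beta)), 1e-6)
  y <- unlist(ds$constructs$reactivity)
  expect_equal(fit$beta0, mean(y[is.finite(y)]), tolerance = 1e-4)
})

test_that("closed-form ridge equals a gradient-descent oracle", {
  ds <- synthetic_dataset(
    synthetic_config(n_constructs = 4, length_range = c(50L, 50L),
                     seed = 17)
  )
  w <- 3L; lambda <- 0.5
  fit <- fit_degscore(ds$constructs, "reactivity", w = w, lambda = lambda)
  # oracle: iterative minimization of the same penalized least squares
  tr <- degkit:::build_training_matrix(ds$constructs, "reactivity", w)
  X <- cbind(tr$X, 1); y <- tr$y
  p <- ncol(tr$X)
  obj <- function(b) {
    sum((drop(X %*% b) - y)^2) + lambda * sum(b[1:p]^2)
  }
  grad <- function(b) {
    2 * drop(crossprod(X, drop(X %*% b) - y)) + 2 * lambda * c(b[1:p], 0)
  }
  opt <- optim(rep(0, p + 1), obj, grad, method = "L-BFGS-B",
               control = list(maxit = 5000, factr = 10))
  expect_equal(unname(fit$beta), opt$par[1:p], tolerance = 1e-4)
  expect_equal(fit$beta0, opt$par[p + 1], tolerance = 1e-4)
})

test_that("prediction is translation-local within the +/-w window", {
  ds <- small_dataset()
  model <- ds$models$reactivity
  r <- ds$constructs[1, ]
  k <- 40L; w <- model$w
  p0 <- predict(model, r)$value[k]
  # mutate a nucleotide outside the window: prediction at k unchanged
  mut <- r
  far <- k + w + 5L
  s <- chars_of(mut$sequence)
  s[far] <- setdiff(c("A", "C", "G", "U"), s[far])[1]
  mut$sequence <- paste(s, collapse = "")
  mut$structure <- NA_character_   # keep loop types fixed via loop_type
  expect_equal(predict(model, mut)$value[k], p0)
  # mutate inside the window: prediction at k moves (planted coefs dense)
  mut2 <- r
  s <- chars_of(mut2$sequence)
  near <- which(is.na(parse_dotbracket(r$structure)))  # keep structure valid
  near <- near[abs(near - k) <= w][1]
  s[near] <- setdiff(c("A", "C", "G", "U"), s[near])[1]
  mut2$sequence <- paste(s, collapse = "")
  expect_false(isTRUE(all.equal(predict(model, mut2)$value[k], p0)))
})

test_that("an all-zero model predicts its intercept everywhere", {
  m <- ds_model <- small_dataset()$models$reactivity
  m$beta[] <- 0
  m$beta0 <- 1.25
  r <- small_dataset()$constructs[2, ]
  expect_equal(predict(m, r)$value, rep(1.25, r$seq_length))
})

test_that("boosted variant: constant fallback, determinism, and fit quality", {
  ds <- small_dataset()
  # a single no-split tree with unit learning rate predicts the label mean
  flat <- fit_degscore_xgb(
    ds$constructs, "reactivity", nrounds = 1, seed = 2,
    params = list(max_depth = 1L, gamma = 1e12, eta = 1, lambda = 0,
                  base_score = 0.5)
  )
  pv <- predict(flat, ds$constructs[1, ])$value
  y <- unlist(ds$constructs$reactivity)
  expect_equal(unique(round(pv, 6)),
               round(mean(y[is.finite(y)]), 6))

  m1 <- fit_degscore_xgb(ds$constructs, "reactivity", nrounds = 30, seed = 9)
  m2 <- fit_degscore_xgb(ds$constructs, "reactivity", nrounds = 30, seed = 9)
  expect_identical(predict(m1, ds$constructs[1:2, ])$value,
                   predict(m2, ds$constructs[1:2, ])$value)
})

test_that("boosted trees beat the linear fit on a loop-type step target", {
  # piecewise-constant dependence on the loop-type channel alone: trees can
  # carve it with fewer effective parameters than the dense linear window
  ds <- small_dataset()
  cs <- ds$constructs
  step_label <- function(r) {
    lt <- chars_of(r$loop_type)[seq_len(r$seq_scored)]
    ifelse(lt == "H", 3, ifelse(lt == "S", 0.5, 1.5))
  }
  cs$reactivity <- lapply(seq_len(nrow(cs)), function(i) step_label(cs[i, ]))
  lin <- fit_degscore(cs, "reactivity", w = 2)
  xgb <- fit_degscore_xgb(cs, "reactivity", w = 2, nrounds = 80, seed = 4)
  expect_lte(xgb$train_rmse, lin$train_rmse)
})

test_that("linear model JSON serialization round-trips", {
  ds <- small_dataset()
  fit <- fit_degscore(ds$constructs, "deg_Mg_50C", w = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_deg_model(fit, path)
  back <- read_deg_model(path)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(back$beta0, fit$beta0, tolerance = 1e-12)
  expect_equal(predict(back, ds$constructs[1, ]),
               predict(fit, ds$constructs[1, ]), tolerance = 1e-10)
})

test_that("tidy/glance/autoplot expose the fitted model", {
  ds <- small_dataset()
  fit <- fit_degscore(ds$constructs, "reactivity", w = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), n_parameters(2))
  expect_setequal(unique(td$channel_kind),
                  c("nucleotide", "loop_type", "intercept"))
  gl <- glance(fit)
  expect_equal(gl$n_parameters, 51L)
  expect_s3_class(autoplot(fit), "ggplot")
})
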