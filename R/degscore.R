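#' Parameter count of the windowed linear degradation model
#'
#' The model regresses per-nucleotide degradation on one-hot indicators of
#' nucleotide identity (4 channels) and loop type (6 channels) at every
#' offset in a window of half-width `w` around the scored position:
#' `10 * (2w + 1)` coefficients plus one intercept. At the published
#' half-width `w = 12` (25 positions) that is 251 parameters.
#'
#' @param w Window half-width in nucleotides (`w >= 0`).
#' @return Integer parameter count `10 * (2w + 1) + 1`.
#' @examples
#' n_parameters(12) # 251
#' @export
n_parameters <- function(w) {
  w <- as.integer(w)
  if (is.na(w) || w < 0L) abort("`w` must be a nonnegative integer.")
  10L * (2L * w + 1L) + 1L
}

# Feature column names, channel-ordered: for each offset -w..w, the 4
# nucleotide channels then the 6 loop channels (H, E, I, M, B, S).
feature_names <- function(w) {
  offs <- -w:w
  unlist(lapply(offs, function(o) {
    sprintf("off%+03d.%s", o, c(NT_ALPHABET, LOOP_CHANNELS))
  }), use.names = FALSE)
}

#' One-hot window featurization of a single position
#'
#' Builds the binary feature vector for position `k`: for each offset in
#' `-w..w` that falls inside the sequence, exactly one nucleotide
#' indicator and one loop-type indicator are set; offsets outside the
#' sequence contribute all-zero blocks. Dangle (`X`) loop labels are
#' merged into the external-loop channel `E` here, keeping the 6-letter
#' loop alphabet of the parameter accounting.
#'
#' @param sequence RNA sequence string (A/C/G/U).
#' @param loop_type Loop-type string of equal length (S/E/I/B/H/M/X).
#' @param k 1-based position to featurize.
#' @param w Window half-width.
#' @return Named binary vector of length `10 * (2w + 1)`.
#' @export
featurize <- function(sequence, loop_type, k, w = 12L) {
  featurize_positions(sequence, loop_type, k, w)[1, ]
}

# Vectorized featurization: one row per requested position.
featurize_positions <- function(sequence, loop_type, positions, w = 12L) {
  w <- as.integer(w)
  seq_c <- chars(sequence)
  loop_c <- chars(loop_type)
  n <- length(seq_c)
  if (length(loop_c) != n) {
    abort("`sequence` and `loop_type` must have equal length.")
  }
  if (any(positions < 1L | positions > n)) {
    abort("Positions outside the sequence.")
  }
  loop_c[loop_c == "X"] <- "E"   # dangles share the external-loop channel
  nt_idx <- match(seq_c, NT_ALPHABET)
  lp_idx <- match(loop_c, LOOP_CHANNELS)
  if (anyNA(nt_idx)) abort("Invalid sequence character.")
  if (anyNA(lp_idx)) abort("Invalid loop-type character.")
  p <- 10L * (2L * w + 1L)
  X <- matrix(0, nrow = length(positions), ncol = p,
              dimnames = list(NULL, feature_names(w)))
  for (o in -w:w) {
    src <- positions + o
    ok <- which(src >= 1L & src <= n)
    if (!length(ok)) next
    base <- (o + w) * 10L
    X[cbind(ok, base + nt_idx[src[ok]])] <- 1
    X[cbind(ok, base + 4L + lp_idx[src[ok]])] <- 1
  }
  X
}

# Pooled design matrix over all constructs and their scored positions with
# a finite label for `target`. Returns X, y, and the (id, position) index.
build_training_matrix <- function(constructs, target, w) {
  if (!target %in% names(constructs)) {
    abort(sprintf("Target data type '%s' not present in the dataset.", target))
  }
  blocks <- list()
  ys <- list()
  ids <- list()
  poss <- list()
  for (i in seq_len(nrow(constructs))) {
    r <- constructs[i, ]
    y <- r[[target]][[1]]
    if (is.null(y)) next
    ks <- which(is.finite(y))
    if (!length(ks)) next
    lt <- r$loop_type
    if (is.na(lt)) lt <- assign_loop_types(parse_dotbracket(r$structure))
    blocks[[length(blocks) + 1L]] <-
      featurize_positions(r$sequence, lt, ks, w)
    ys[[length(ys) + 1L]] <- y[ks]
    ids[[length(ids) + 1L]] <- rep(r$id, length(ks))
    poss[[length(poss) + 1L]] <- ks
  }
  if (!length(blocks)) abort("No finite labelled nucleotides to train on.")
  list(X = do.call(rbind, blocks),
       y = unlist(ys, use.names = FALSE),
       id = unlist(ids, use.names = FALSE),
       position = unlist(poss, use.names = FALSE))
}

#' Fit the windowed linear degradation model by ridge regression
#'
#' Pools every scored, finite-labelled nucleotide of the chosen data type
#' across all constructs, featurizes a `+/-w` window of one-hot sequence
#' and loop-type indicators around each, and solves the ridge problem
#' `min_beta sum (y - X beta)^2 + lambda * ||beta||^2` in closed form
#' (the intercept is unpenalized). The fit is deterministic given its
#' inputs.
#'
#' @param constructs Construct tibble (see [read_constructs()]) carrying
#'   structures or loop-type strings and labels for `target`.
#' @param target Data-type name to model, e.g. `"deg_Mg_pH10"`. Mandatory:
#'   one model is trained per data type.
#' @param w Window half-width (default 12, giving 251 parameters).
#' @param lambda Nonnegative L2 penalty (default 0.15).
#' @return An object of class `deg_model`: coefficients indexed by
#'   (offset, channel), intercept, window, penalty, target and training
#'   RMSE. Supports [predict()][predict.deg_model], [tidy()], [glance()]
#'   and [autoplot()].
#' @seealso [fit_degscore_xgb()] for the boosted-tree variant on the same
#'   featurization.
#' @export
fit_degscore <- function(constructs, target, w = 12L, lambda = 0.15) {
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  tr <- build_training_matrix(constructs, target, w)
  if (sd(tr$y) == 0) {
    warn("Training target is constant; the fit reduces to its mean.")
  }
  p <- ncol(tr$X)
  Xa <- cbind(tr$X, `(Intercept)` = 1)
  A <- crossprod(Xa)
  diag(A)[seq_len(p)] <- diag(A)[seq_len(p)] + lambda
  beta_full <- solve(A, crossprod(Xa, tr$y))
  beta <- setNames(beta_full[seq_len(p)], colnames(tr$X))
  beta0 <- beta_full[p + 1L]
  fitted <- drop(tr$X %*% beta) + beta0
  structure(
    list(kind = "linear", w = as.integer(w), lambda = lambda,
         target = target, beta = beta, beta0 = unname(beta0),
         n_train = length(tr$y),
         train_rmse = sqrt(mean((tr$y - fitted)^2)),
         metadata = list(regularization = "ridge (L2), intercept unpenalized")),
    class = "deg_model"
  )
}

#' Fit the boosted-tree variant on the identical featurization
#'
#' Gradient-boosted decision trees (xgboost) trained on exactly the same
#' windowed one-hot design matrix as [fit_degscore()]. Seeded and
#' single-threaded for reproducibility.
#'
#' @inheritParams fit_degscore
#' @param nrounds Number of boosting rounds.
#' @param max_depth,eta Tree depth and learning rate.
#' @param seed Integer seed for the boosting RNG.
#' @param params Extra parameters passed to [xgboost::xgb.train()].
#' @return An object of class `deg_xgb_model` honouring the same
#'   [predict()][predict.deg_model] contract as `deg_model`.
#' @export
fit_degscore_xgb <- function(constructs, target, w = 12L, nrounds = 400L,
                             max_depth = 6L, eta = 0.3, seed = 1L,
                             params = list()) {
  tr <- build_training_matrix(constructs, target, w)
  pars <- modifyList(
    list(objective = "reg:squarederror", max_depth = as.integer(max_depth),
         eta = eta, nthread = 1L, seed = as.integer(seed)),
    params
  )
  dtrain <- xgboost::xgb.DMatrix(tr$X, label = tr$y)
  booster <- with_seed(seed, xgboost::xgb.train(
    params = pars, data = dtrain, nrounds = as.integer(nrounds),
    verbose = 0
  ))
  fitted <- predict(booster, dtrain)
  structure(
    list(kind = "xgb", w = as.integer(w), target = target,
         booster = booster, n_train = length(tr$y),
         nrounds = as.integer(nrounds), params = pars,
         seed = as.integer(seed),
         train_rmse = sqrt(mean((tr$y - fitted)^2))),
    class = "deg_xgb_model"
  )
}

#' Predict per-nucleotide degradation
#'
#' Evaluates the windowed model at every position of every construct
#' (no masking: downstream consumers select scored windows themselves).
#' Prediction is translation-local: the value at position k depends only
#' on positions within `+/-w` of k.
#'
#' @param object A `deg_model` or `deg_xgb_model`.
#' @param constructs Construct tibble with `sequence` and `loop_type`
#'   (or `structure`, from which loop types are derived).
#' @param ... Unused.
#' @return A tibble with columns `id`, `position` (1-based), `data_type`,
#'   `value`, one row per nucleotide.
#' @export
predict.deg_model <- function(object, constructs, ...) {
  predict_windowed(object, constructs)
}

#' @rdname predict.deg_model
#' @export
predict.deg_xgb_model <- function(object, constructs, ...) {
  predict_windowed(object, constructs)
}

predict_windowed <- function(model, constructs) {
  rows <- lapply(seq_len(nrow(constructs)), function(i) {
    r <- constructs[i, ]
    lt <- r$loop_type
    if (is.na(lt)) lt <- assign_loop_types(parse_dotbracket(r$structure))
    if (nchar(r$sequence) != nchar(lt)) {
      abort(sprintf("Record '%s': sequence/loop-type length mismatch.", r$id))
    }
    ks <- seq_len(nchar(r$sequence))
    X <- featurize_positions(r$sequence, lt, ks, model$w)
    v <- if (model$kind == "linear") {
      drop(X %*% model$beta) + model$beta0
    } else {
      predict(model$booster, xgboost::xgb.DMatrix(X))
    }
    tibble::tibble(id = r$id, position = ks, data_type = model$target,
                   value = as.numeric(v))
  })
  dplyr::bind_rows(rows)
}

#' Serialize / restore a linear degradation model as JSON
#'
#' @param model A `deg_model`.
#' @param path Output JSON path.
#' @return `path` (write) or the restored `deg_model` (read).
#' @export
write_deg_model <- function(model, path) {
  if (!inherits(model, "deg_model")) {
    abort("Only linear `deg_model` objects serialize to this JSON schema; use xgboost's own JSON format for boosted models.")
  }
  jsonlite::write_json(
    list(kind = "degkit_linear_model", version = 1L, w = model$w,
         lambda = model$lambda, target = model$target,
         coefficients = as.list(model$beta), intercept = model$beta0,
         n_train = model$n_train, train_rmse = model$train_rmse),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_deg_model
#' @export
read_deg_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$kind, "degkit_linear_model")) {
    abort("Not a degkit linear model JSON file.")
  }
  beta <- unlist(o$coefficients)
  structure(
    list(kind = "linear", w = as.integer(o$w), lambda = o$lambda,
         target = o$target, beta = beta[feature_names(as.integer(o$w))],
         beta0 = o$intercept, n_train = o$n_train,
         train_rmse = o$train_rmse, metadata = list()),
    class = "deg_model"
  )
}

#' @export
print.deg_model <- function(x, ...) {
  cat(sprintf(
    "<deg_model> windowed linear (ridge)\n  target: %s | w = %d (%d parameters) | lambda = %g\n  trained on %d nucleotides, train RMSE %.4f\n",
    x$target, x$w, n_parameters(x$w), x$lambda, x$n_train, x$train_rmse))
  invisible(x)
}

#' @export
print.deg_xgb_model <- function(x, ...) {
  cat(sprintf(
    "<deg_xgb_model> windowed boosted trees\n  target: %s | w = %d | %d rounds, depth %d\n  trained on %d nucleotides, train RMSE %.4f\n",
    x$target, x$w, x$nrounds, x$params$max_depth, x$n_train, x$train_rmse))
  invisible(x)
}
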