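#' Mean column RMSE (MCRMSE)
#'
#' The multi-target benchmark metric: for each data-type column the RMSE
#' is computed over all masked (scored, finite) nucleotides pooled across
#' constructs, and MCRMSE is the unweighted mean of the column RMSEs.
#' With a single data type MCRMSE equals that column's RMSE.
#'
#' @param measured,predicted Numeric matrices of identical shape, one
#'   column per data type (column names name the data types), rows =
#'   pooled nucleotides. Vectors are treated as one-column matrices.
#' @param mask Optional logical matrix of the same shape marking positions
#'   to score; non-finite measured values are always excluded.
#' @param per_construct_id Optional vector of construct ids (one per row):
#'   when supplied together with `per_construct = TRUE`, column RMSEs are
#'   averaged per construct first.
#' @param per_construct Average RMSE per construct before pooling
#'   (default `FALSE`: nucleotides pooled across constructs, the single-n
#'   formulation).
#' @return A `score_report`: list with `per_type` (tibble: `data_type`,
#'   `rmse`, `n`), `mcrmse`, and `n_total`.
#' @examples
#' m <- cbind(a = c(1, 2), b = c(3, 4))
#' mcrmse(m, m + 0.3)$mcrmse # 0.3
#' @export
mcrmse <- function(measured, predicted, mask = NULL,
                   per_construct_id = NULL, per_construct = FALSE) {
  measured <- as_score_matrix(measured)
  predicted <- as_score_matrix(predicted)
  if (!identical(dim(measured), dim(predicted))) {
    abort("`measured` and `predicted` must have identical shapes.")
  }
  keep <- is.finite(measured) & is.finite(predicted)
  if (!is.null(mask)) keep <- keep & mask
  types <- colnames(measured) %||% paste0("type", seq_len(ncol(measured)))
  per_type <- lapply(seq_len(ncol(measured)), function(j) {
    kj <- keep[, j]
    if (!any(kj)) {
      abort(sprintf("No scored nucleotides in column '%s'.", types[j]))
    }
    res2 <- (measured[kj, j] - predicted[kj, j])^2
    if (per_construct && !is.null(per_construct_id)) {
      rmse <- mean(sqrt(tapply(res2, per_construct_id[kj], mean)))
    } else {
      rmse <- sqrt(mean(res2))
    }
    tibble::tibble(data_type = types[j], rmse = rmse, n = sum(kj))
  })
  per_type <- dplyr::bind_rows(per_type)
  structure(
    list(per_type = per_type, mcrmse = mean(per_type$rmse),
         n_total = sum(per_type$n)),
    class = "score_report"
  )
}

as_score_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> MCRMSE = %.5f over %d nucleotides\n",
              x$mcrmse, x$n_total))
  print(x$per_type)
  invisible(x)
}

#' Fraction of predictions within experimental error
#'
#' The fraction of scored nucleotides whose prediction agrees with the
#' measurement more closely than the measurement's own uncertainty:
#' `|predicted - measured| < sigma` (strict). For a perfect predictor of
#' the underlying truth with Gaussian measurement noise, this fraction
#' approaches the 1-sigma normal mass, about 68.3% — the ceiling against
#' which model within-error fractions are judged.
#'
#' @param measured,predicted,sigma Aligned numeric vectors (or matrices);
#'   `sigma >= 0` elementwise. Non-finite measured entries are excluded.
#' @return Fraction in \[0, 1\].
#' @export
fraction_within_error <- function(measured, predicted, sigma) {
  if (length(measured) != length(predicted) ||
      length(measured) != length(sigma)) {
    abort("`measured`, `predicted` and `sigma` must have equal lengths.")
  }
  if (any(sigma < 0, na.rm = TRUE)) abort("`sigma` must be nonnegative.")
  keep <- is.finite(measured) & is.finite(predicted) & is.finite(sigma)
  if (!any(keep)) abort("No scored values.")
  mean(abs(predicted[keep] - measured[keep]) < sigma[keep])
}

#' Per-construct signal-to-noise ratio
#'
#' Mean over data types of the mean over nucleotides of the measured
#' value divided by its estimated error: `SN = (1/M) sum_i (1/N) sum_j
#' mu_ij / sigma_ij`.
#'
#' @param mu List of numeric vectors (one per data type) of measured
#'   values, or a single vector/matrix (columns = data types).
#' @param sigma Errors, same shape; must be positive wherever scored.
#' @return Scalar SN ratio.
#' @export
sn_ratio <- function(mu, sigma) {
  if (!is.list(mu)) mu <- asplit_cols(mu)
  if (!is.list(sigma)) sigma <- asplit_cols(sigma)
  if (length(mu) != length(sigma)) {
    abort("`mu` and `sigma` must cover the same data types.")
  }
  per_type <- vapply(seq_along(mu), function(i) {
    m <- mu[[i]]; s <- sigma[[i]]
    if (length(m) != length(s)) abort("mu/sigma length mismatch.")
    keep <- is.finite(m) & is.finite(s)
    if (any(s[keep] == 0)) {
      abort("sigma == 0 at a scored position; SN ratio undefined.")
    }
    mean(m[keep] / s[keep])
  }, numeric(1))
  mean(per_type)
}

asplit_cols <- function(x) {
  x <- as_score_matrix(x)
  lapply(seq_len(ncol(x)), function(j) x[, j])
}

#' Aggregate a per-nucleotide signal over structure motifs
#'
#' Averages a per-nucleotide vector (measured or predicted signal) within
#' motif classes: stems, hairpins by loop size (3 = triloop, 4 =
#' tetraloop, >= 5), bulges, symmetric and asymmetric internal loops,
#' multiloops, and exterior/dangle regions.
#'
#' @param values Numeric vector, one entry per position (NA allowed).
#' @param motifs Motif tibble from [extract_motifs()].
#' @return Tibble with columns `class`, `mean`, `n` (position count;
#'   counts sum to the sequence length).
#' @export
aggregate_by_motif <- function(values, motifs) {
  class_of <- function(kind, loop_size, symmetric) {
    if (kind == "hairpin") {
      if (loop_size == 3L) "hairpin_triloop"
      else if (loop_size == 4L) "hairpin_tetraloop"
      else "hairpin_5plus"
    } else if (kind == "internal") {
      if (isTRUE(symmetric)) "internal_symmetric" else "internal_asymmetric"
    } else if (kind == "exterior") "exterior_dangle"
    else kind
  }
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    m <- motifs[i, ]
    pos <- m$positions[[1]]
    tibble::tibble(
      class = class_of(m$kind, m$loop_size, m$symmetric),
      position = pos, value = values[pos]
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     n = dplyr::n(), .groups = "drop")
}

#' Per-construct RMSE table
#'
#' RMSE per construct and data type between measured profiles and a
#' long-format prediction table; consistent with [mcrmse()] restricted to
#' one construct.
#'
#' @param constructs Construct tibble with measured value list-columns.
#' @param predictions Long prediction tibble (`id`, `position`,
#'   `data_type`, `value`).
#' @return Tibble with columns `id`, `data_type`, `rmse`, `n`.
#' @export
per_construct_rmse <- function(constructs, predictions) {
  truth <- constructs_to_long(constructs)
  dplyr::inner_join(
    truth, predictions,
    by = c("id", "position", "data_type"),
    suffix = c("_meas", "_pred")
  ) |>
    dplyr::filter(is.finite(.data$value_meas),
                  is.finite(.data$value_pred)) |>
    dplyr::group_by(.data$id, .data$data_type) |>
    dplyr::summarise(
      rmse = sqrt(mean((.data$value_meas - .data$value_pred)^2)),
      n = dplyr::n(), .groups = "drop"
    )
}

#' Flatten construct profiles to a long table
#'
#' One row per (construct, scored position, data type), with measured
#' `value` and `error`.
#'
#' @param constructs Construct tibble.
#' @param data_types Data types to include (default: those present).
#' @return Tibble `id`, `position`, `data_type`, `value`, `error`.
#' @export
constructs_to_long <- function(constructs,
                               data_types = intersect(DATA_TYPES,
                                                      names(constructs))) {
  rows <- list()
  for (i in seq_len(nrow(constructs))) {
    r <- constructs[i, ]
    for (dt in data_types) {
      v <- r[[dt]][[1]]
      if (is.null(v)) next
      e <- r[[paste0(dt, "_err")]][[1]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = r$id, position = seq_along(v), data_type = dt, value = v,
        error = if (is.null(e)) NA_real_ else e
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Score a long prediction table against measured constructs
#'
#' Joins measured profiles with predictions and computes the
#' [mcrmse()] report over the shared scored nucleotides.
#'
#' @inheritParams per_construct_rmse
#' @inheritParams mcrmse
#' @return A `score_report`.
#' @export
score_predictions <- function(constructs, predictions,
                              per_construct = FALSE) {
  joined <- dplyr::inner_join(
    constructs_to_long(constructs), predictions,
    by = c("id", "position", "data_type"), suffix = c("_meas", "_pred")
  )
  if (nrow(joined) == 0L) abort("Predictions share no scored nucleotides with the truth.")
  types <- sort(unique(joined$data_type))
  align <- joined |>
    tidyr::pivot_wider(id_cols = c("id", "position"),
                       names_from = "data_type",
                       values_from = c("value_meas", "value_pred"))
  meas <- as.matrix(align[paste0("value_meas_", types)])
  pred <- as.matrix(align[paste0("value_pred_", types)])
  colnames(meas) <- colnames(pred) <- types
  mcrmse(meas, pred, per_construct_id = align$id,
         per_construct = per_construct)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, via
#' `stats::cor(method = "spearman")`.
#'
#' @param x,y Numeric vectors of equal length (>= 3, non-constant).
#' @return Correlation in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal lengths.")
  if (length(x) < 3L) abort("Need at least 3 observations.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation undefined for constant input.")
  }
  cor(x, y, method = "spearman")
}
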