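#' Tidy a fitted windowed linear degradation model
#'
#' @param x A `deg_model`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `offset` (window offset
#'   relative to the scored nucleotide), `channel` (A/C/G/U or
#'   H/E/I/M/B/S), `channel_kind` (`nucleotide` / `loop_type`) and
#'   `estimate`. The intercept appears with `channel = "(Intercept)"`.
#' @export
tidy.deg_model <- function(x, ...) {
  nm <- names(x$beta)
  off <- as.integer(sub("^off([+-][0-9]+)\\..*$", "\\1", nm))
  ch <- sub("^off[+-][0-9]+\\.", "", nm)
  dplyr::bind_rows(
    tibble::tibble(
      offset = off, channel = ch,
      channel_kind = ifelse(ch %in% NT_ALPHABET, "nucleotide", "loop_type"),
      estimate = unname(x$beta)
    ),
    tibble::tibble(offset = NA_integer_, channel = "(Intercept)",
                   channel_kind = "intercept", estimate = x$beta0)
  )
}

#' @rdname tidy.deg_model
#' @export
glance.deg_model <- function(x, ...) {
  tibble::tibble(
    target = x$target, w = x$w, n_parameters = n_parameters(x$w),
    lambda = x$lambda, n_train = x$n_train, train_rmse = x$train_rmse
  )
}

#' @rdname tidy.deg_model
#' @export
glance.deg_xgb_model <- function(x, ...) {
  tibble::tibble(
    target = x$target, w = x$w, nrounds = x$nrounds,
    max_depth = x$params$max_depth, eta = x$params$eta,
    n_train = x$n_train, train_rmse = x$train_rmse
  )
}

#' Tidy an ensemble spec
#'
#' @param x An `ensemble_spec`.
#' @param ... Unused.
#' @return Tibble with columns `member` and `weight`.
#' @export
tidy.ensemble_spec <- function(x, ...) {
  tibble::tibble(member = x$members, weight = x$weights)
}

#' @rdname tidy.ensemble_spec
#' @export
glance.ensemble_spec <- function(x, ...) {
  tibble::tibble(n_members = length(x$members),
                 optimized_score = x$optimized_score,
                 best_single_score = x$best_single_score)
}

#' Tidy a score report
#'
#' @param x A `score_report` from [mcrmse()].
#' @param ... Unused.
#' @return The per-data-type RMSE tibble.
#' @export
tidy.score_report <- function(x, ...) x$per_type

#' @rdname tidy.score_report
#' @export
glance.score_report <- function(x, ...) {
  tibble::tibble(mcrmse = x$mcrmse, n_types = nrow(x$per_type),
                 n_total = x$n_total)
}
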