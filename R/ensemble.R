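#' Convex blend of member predictions
#'
#' Elementwise convex combination of aligned prediction arrays. With
#' uniform weights this is the simple top-k average used as the reference
#' ensembling strategy.
#'
#' @param predictions List of aligned numeric vectors/matrices, one per
#'   member.
#' @param weights Nonnegative weights, one per member; normalized to sum
#'   to 1.
#' @return Blended array with the members' shape.
#' @export
blend <- function(predictions, weights = rep(1, length(predictions))) {
  if (!length(predictions)) abort("No member predictions.")
  if (length(weights) != length(predictions)) {
    abort("One weight per member required.")
  }
  if (any(weights < 0)) abort("Weights must be nonnegative.")
  if (sum(weights) == 0) abort("Weights sum to zero.")
  weights <- weights / sum(weights)
  dims <- dim(predictions[[1]]) %||% length(predictions[[1]])
  out <- predictions[[1]] * weights[1]
  for (i in seq_along(predictions)[-1]) {
    if (!identical(dim(predictions[[i]]) %||% length(predictions[[i]]),
                   dims)) {
      abort("Member predictions have mismatched shapes.")
    }
    out <- out + predictions[[i]] * weights[i]
  }
  out
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

ensemble_score <- function(sel, wraw, members, truth, mask) {
  idx <- which(sel)
  if (!length(idx)) return(Inf)
  w <- softmax(wraw[idx])
  mcrmse(truth, blend(members[idx], w), mask = mask)$mcrmse
}

#' Genetic-algorithm ensembling of member predictors
#'
#' Jointly selects at most `max_members` members and nonnegative blend
#' weights (softmax-parameterized) minimizing the MCRMSE of the convex
#' blend on the optimization split. The chromosome is a membership
#' bitmask plus raw weight genes; uniform crossover, tournament
#' selection, elitism of 2, and the best single member seeded into the
#' initial population — so the returned ensemble never scores worse on
#' the optimized split than the best single member. Deterministic given
#' `seed`.
#'
#' The optimization split plays the role of a public leaderboard: scores
#' on a held-out (private) split can be obtained with
#' [score_ensemble()] and may well be worse — ensemble weights overfit
#' the split they optimize.
#'
#' @param members List of aligned prediction matrices (rows = pooled
#'   nucleotides, columns = data types), one per member model.
#' @param truth Measured matrix aligned with the members.
#' @param mask Optional logical mask of scored positions.
#' @param max_members Maximum ensemble size (default 10).
#' @param pop_size,n_gen,mut_rate GA hyperparameters (defaults 64, 200,
#'   0.05).
#' @param seed Integer seed (mandatory).
#' @return An `ensemble_spec`: selected member indices, weights (summing
#'   to 1), and the optimized-split MCRMSE.
#' @export
ga_ensemble <- function(members, truth, mask = NULL, max_members = 10L,
                        pop_size = 64L, n_gen = 200L, mut_rate = 0.05,
                        seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  n_m <- length(members)
  if (n_m == 0L) abort("No member predictors.")
  truth <- as_score_matrix(truth)
  members <- lapply(members, as_score_matrix)

  single_scores <- vapply(seq_len(n_m), function(i) {
    mcrmse(truth, members[[i]], mask = mask)$mcrmse
  }, numeric(1))
  best_single <- which.min(single_scores)

  if (n_m == 1L) {
    return(new_ensemble_spec(1L, 1, single_scores[1], single_scores[1]))
  }

  cap <- function(sel) {
    idx <- which(sel)
    if (length(idx) > max_members) {
      sel[resample(idx, length(idx) - max_members)] <- FALSE
    }
    if (!any(sel)) sel[sample.int(n_m, 1L)] <- TRUE
    sel
  }

  with_seed(seed, {
    pop <- lapply(seq_len(pop_size), function(i) {
      sel <- rep(FALSE, n_m)
      sel[sample.int(n_m, sample.int(min(max_members, n_m), 1L))] <- TRUE
      list(sel = sel, wraw = rnorm(n_m, 0, 0.5))
    })
    # seed the best single member as its own chromosome
    pop[[1]] <- list(sel = seq_len(n_m) == best_single,
                     wraw = rep(0, n_m))
    fit <- vapply(pop, function(ch) {
      ensemble_score(ch$sel, ch$wraw, members, truth, mask)
    }, numeric(1))

    for (g in seq_len(n_gen)) {
      ord <- order(fit)
      newpop <- pop[ord[1:2]]          # elitism
      newfit <- fit[ord[1:2]]
      while (length(newpop) < pop_size) {
        pick <- function() {
          cands <- sample.int(pop_size, 3L)
          pop[[cands[which.min(fit[cands])]]]
        }
        pa <- pick(); pb <- pick()
        take_a <- runif(n_m) < 0.5
        child <- list(sel = ifelse(take_a, pa$sel, pb$sel),
                      wraw = ifelse(take_a, pa$wraw, pb$wraw))
        flip <- runif(n_m) < mut_rate
        child$sel[flip] <- !child$sel[flip]
        jig <- runif(n_m) < mut_rate
        child$wraw[jig] <- child$wraw[jig] + rnorm(sum(jig), 0, 0.3)
        child$sel <- cap(child$sel)
        newpop[[length(newpop) + 1L]] <- child
        newfit <- c(newfit,
                    ensemble_score(child$sel, child$wraw, members, truth,
                                   mask))
      }
      pop <- newpop
      fit <- newfit
    }
    best <- pop[[which.min(fit)]]
    idx <- which(best$sel)
    w <- softmax(best$wraw[idx])
    # drop numerically negligible members for a readable spec
    keep <- w > 1e-12
    idx <- idx[keep]; w <- w[keep] / sum(w[keep])
    new_ensemble_spec(idx, w, min(fit), single_scores[best_single])
  })
}

new_ensemble_spec <- function(members, weights, score, best_single_score) {
  structure(
    list(members = as.integer(members), weights = as.numeric(weights),
         optimized_score = score, best_single_score = best_single_score),
    class = "ensemble_spec"
  )
}

#' Score an ensemble spec on a (held-out) split
#'
#' @param spec An `ensemble_spec` from [ga_ensemble()].
#' @param members List of member prediction matrices for the split.
#' @param truth Measured matrix for the split.
#' @param mask Optional logical mask.
#' @return MCRMSE of the blended ensemble on this split.
#' @export
score_ensemble <- function(spec, members, truth, mask = NULL) {
  mcrmse(as_score_matrix(truth),
         blend(lapply(members[spec$members], as_score_matrix),
               spec$weights),
         mask = mask)$mcrmse
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf(
    "<ensemble_spec> %d member(s), optimized-split MCRMSE %.5f (best single %.5f)\n",
    length(x$members), x$optimized_score, x$best_single_score))
  print(tibble::tibble(member = x$members, weight = x$weights))
  invisible(x)
}

#' Serialize an ensemble spec as JSON
#'
#' @inheritParams score_ensemble
#' @param path Output path.
#' @return `path` (write) or an `ensemble_spec` (read).
#' @export
write_ensemble_spec <- function(spec, path) {
  jsonlite::write_json(
    list(kind = "degkit_ensemble_spec", members = spec$members,
         weights = spec$weights, optimized_score = spec$optimized_score,
         best_single_score = spec$best_single_score),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_ensemble_spec
#' @export
read_ensemble_spec <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_ensemble_spec(o$members, o$weights, o$optimized_score,
                    o$best_single_score)
}
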