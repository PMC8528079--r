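#' Synthetic dataset configuration
#'
#' Fixes every knob of the seeded synthetic construct generator: the
#' generator emulates benchmark-style datasets of 102-130 nt constructs
#' with nested secondary structures, labels on a scored 5' prefix
#' (`ceiling(scored_frac * length)`, mimicking 68 scored nucleotides of
#' 107-nt constructs), per-nucleotide Gaussian noise with recorded sigma,
#' and a planted windowed linear dependence of degradation on sequence
#' and loop-type context.
#'
#' @param n_constructs Number of constructs.
#' @param length_range Inclusive nucleotide length range (default
#'   `c(102, 130)`).
#' @param scored_frac Scored-prefix fraction (default 0.64).
#' @param data_types Data types to simulate (default reactivity,
#'   deg_Mg_pH10, deg_Mg_50C — the three scored types).
#' @param w Planted-model window half-width (default 12).
#' @param noise_sd Baseline per-nucleotide noise scale; each nucleotide's
#'   sigma is `noise_sd * Uniform(0.5, 1.5)` (default 0.05).
#' @param sn_fail_frac Fraction of constructs planted to fail the
#'   signal/noise filter, via 25x inflated sigma (default 0.1).
#' @param intercept,coef_sd Planted-model intercept and coefficient scale
#'   (defaults 2 and 0.05, keeping profiles inside the curation bounds).
#' @param seed Integer seed (mandatory): the entire dataset, including
#'   the planted models, is a pure function of this configuration.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_constructs = 200L,
                             length_range = c(102L, 130L),
                             scored_frac = 0.64,
                             data_types = c("reactivity", "deg_Mg_pH10",
                                            "deg_Mg_50C"),
                             w = 12L, noise_sd = 0.05,
                             sn_fail_frac = 0.1, intercept = 2,
                             coef_sd = 0.05, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  stopifnot(length(length_range) == 2L, length_range[1] >= 10L,
            length_range[2] >= length_range[1],
            scored_frac > 0, scored_frac <= 1, noise_sd >= 0,
            sn_fail_frac >= 0, sn_fail_frac <= 1,
            all(data_types %in% DATA_TYPES))
  structure(
    list(n_constructs = as.integer(n_constructs),
         length_range = as.integer(length_range),
         scored_frac = scored_frac, data_types = data_types,
         w = as.integer(w), noise_sd = noise_sd,
         sn_fail_frac = sn_fail_frac, intercept = intercept,
         coef_sd = coef_sd, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a random nested RNA structure with consistent sequence
#'
#' Builds a nested secondary structure from randomized helices
#' (Watson-Crick and GU wobble pairs), hairpin loops of 3-8 nt, bulges,
#' internal loops, multiloops and terminal dangles, then draws a sequence
#' consistent with every pair. Uses the current RNG state; wrap in a
#' seeded context for reproducibility.
#'
#' @param length Construct length in nucleotides (>= 10).
#' @return List with `sequence` and `structure` (dot-bracket), both of
#'   the requested length.
#' @export
generate_structure <- function(length) {
  length <- as.integer(length)
  if (length < 10L) abort("`length` must be at least 10 nt.")
  db <- character(length)

  hairpin_region <- function(l, r) {
    db[l:r] <<- "."
  }
  # fill region [l, r] with a helix whose interior recurses
  helix_region <- function(l, r) {
    m <- r - l + 1L
    if (m < 11L) { hairpin_region(l, r); return(invisible()) }
    s_max <- min(8L, (m - 3L) %/% 2L)
    s <- max(2L, sample.int(s_max, 1L))
    inner <- m - 2L * s
    if (inner %in% c(9L, 10L)) {   # keep hairpin loops at 3-8 nt
      s <- s + 1L
      inner <- inner - 2L
    }
    db[l:(l + s - 1L)] <<- "("
    db[(r - s + 1L):r] <<- ")"
    interior(l + s, r - s, inner)
  }
  interior <- function(l, r, m) {
    if (m <= 8L) { hairpin_region(l, r); return(invisible()) }
    if (m >= 28L && runif(1) < 0.25) {
      # multiloop: two child helices separated by unpaired spacers
      a <- sample.int(3L, 1L); b <- sample.int(3L, 1L); cc <- sample.int(3L, 1L)
      rest <- m - a - b - cc
      m1 <- max(11L, (rest %/% 2L))
      m2 <- rest - m1
      if (m2 >= 11L) {
        if (a > 0L) db[l:(l + a - 1L)] <<- "."
        helix_region(l + a, l + a + m1 - 1L)
        mid <- l + a + m1
        db[mid:(mid + b - 1L)] <<- "."
        helix_region(mid + b, mid + b + m2 - 1L)
        if (cc > 0L) db[(r - cc + 1L):r] <<- "."
        return(invisible())
      }
    }
    # bulge / internal loop / stacked continuation
    a <- sample(0:3, 1L); b <- sample(0:3, 1L)
    if (m - a - b < 11L) { a <- 0L; b <- 0L }
    if (m - a - b < 11L) { hairpin_region(l, r); return(invisible()) }
    if (a > 0L) db[l:(l + a - 1L)] <<- "."
    if (b > 0L) db[(r - b + 1L):r] <<- "."
    helix_region(l + a, r - b)
  }

  d5 <- sample(0:4, 1L)
  d3 <- sample(0:4, 1L)
  if (d5 > 0L) db[1:d5] <- "."
  if (d3 > 0L) db[(length - d3 + 1L):length] <- "."
  body_l <- d5 + 1L
  body_r <- length - d3
  m <- body_r - body_l + 1L
  if (m >= 40L && runif(1) < 0.35) {
    gap <- sample.int(4L, 1L)
    m1 <- max(11L, sample.int(m - gap - 11L, 1L))
    m2 <- m - gap - m1
    if (m2 >= 11L) {
      helix_region(body_l, body_l + m1 - 1L)
      db[(body_l + m1):(body_l + m1 + gap - 1L)] <- "."
      helix_region(body_l + m1 + gap, body_r)
    } else {
      helix_region(body_l, body_r)
    }
  } else {
    helix_region(body_l, body_r)
  }

  structure_str <- paste(db, collapse = "")
  partner <- parse_dotbracket(structure_str)
  seq_c <- character(length)
  unpaired <- which(is.na(partner))
  seq_c[unpaired] <- sample(NT_ALPHABET, length(unpaired), replace = TRUE)
  pair_pool <- list(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"),
                    c("G", "U"), c("U", "G"))
  pair_probs <- c(0.3, 0.3, 0.15, 0.15, 0.05, 0.05)
  opens <- which(!is.na(partner) & partner > seq_along(partner))
  for (i in opens) {
    pr <- pair_pool[[sample.int(6L, 1L, prob = pair_probs)]]
    seq_c[i] <- pr[1]
    seq_c[partner[i]] <- pr[2]
  }
  list(sequence = paste(seq_c, collapse = ""), structure = structure_str)
}

# Planted windowed linear models, one per data type, drawn from the
# config's seed (offset so they never share draws with the constructs).
planted_models <- function(config) {
  with_seed(config$seed + 1000003L, {
    setNames(lapply(config$data_types, function(dt) {
      p <- 10L * (2L * config$w + 1L)
      structure(
        list(kind = "linear", w = config$w, lambda = 0,
             target = dt,
             beta = setNames(rnorm(p, 0, config$coef_sd),
                             feature_names(config$w)),
             beta0 = config$intercept, n_train = 0L, train_rmse = NA_real_,
             metadata = list(planted = TRUE)),
        class = "deg_model"
      )
    }), config$data_types)
  })
}

#' Simulate measured labels for one construct
#'
#' For each data type, the measured value over the scored prefix is the
#' planted model's prediction plus Gaussian noise with a per-nucleotide
#' sigma (stored as the error array); the construct's signal-to-noise
#' ratio is computed from the simulated values and errors. Uses the
#' current RNG state.
#'
#' @param construct One-row construct tibble with `sequence`,
#'   `structure`, `loop_type`, `seq_scored`.
#' @param models Named list of planted `deg_model`s, one per data type.
#' @param noise_sd Baseline noise scale (0 = noise-free labels).
#' @param sigma_inflation Multiplier applied to sigma (used to plant
#'   signal/noise-filter failures).
#' @return The construct row with value/error list-columns,
#'   `signal_to_noise` and `SN_filter` filled in.
#' @export
simulate_labels <- function(construct, models, noise_sd = 0.05,
                            sigma_inflation = 1) {
  ns <- construct$seq_scored
  mu_list <- list()
  sd_list <- list()
  for (dt in names(models)) {
    pred <- predict(models[[dt]], construct)
    mu <- pred$value[seq_len(ns)]
    sig <- noise_sd * runif(ns, 0.5, 1.5) * sigma_inflation
    y <- mu + rnorm(ns, 0, sig)
    construct[[dt]] <- list(y)
    construct[[paste0(dt, "_err")]] <- list(sig)
    mu_list[[dt]] <- y
    sd_list[[dt]] <- sig
  }
  construct$signal_to_noise <-
    if (noise_sd > 0) sn_ratio(mu_list, sd_list) else Inf
  construct$SN_filter <- NA_integer_
  construct
}

#' Generate a seeded synthetic labelled dataset
#'
#' Draws `n_constructs` structured RNA constructs, simulates measured
#' profiles from planted windowed linear models with per-nucleotide
#' Gaussian noise, plants a fraction of signal/noise-filter failures by
#' sigma inflation, and annotates `SN_filter` with [apply_sn_filter()].
#' Byte-identical output for a fixed configuration.
#'
#' @param config A [synthetic_config()].
#' @return List with `constructs` (labelled construct tibble),
#'   `truth` (noise-free planted labels in the same long format as
#'   predictions: `id`, `position`, `data_type`, `value`), and
#'   `models` (the planted `deg_model`s).
#' @export
synthetic_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  models <- planted_models(config)
  with_seed(config$seed, {
    n <- config$n_constructs
    rows <- vector("list", n)
    fail_flags <- if (n > 0L)
      runif(n) < config$sn_fail_frac else logical(0)
    for (i in seq_len(n)) {
      len <- resample(config$length_range[1]:config$length_range[2], 1L)
      gs <- generate_structure(len)
      row <- tibble::tibble(
        id = sprintf("synth_%04d", i),
        sequence = gs$sequence, structure = gs$structure,
        loop_type = assign_loop_types(parse_dotbracket(gs$structure)),
        seq_length = len,
        seq_scored = as.integer(ceiling(config$scored_frac * len)),
        signal_to_noise = NA_real_, SN_filter = NA_integer_,
        extra = list(list())
      )
      rows[[i]] <- simulate_labels(
        row, models, noise_sd = config$noise_sd,
        sigma_inflation = if (fail_flags[i]) 25 else 1
      )
    }
    constructs <- if (n > 0L) dplyr::bind_rows(rows) else
      empty_constructs()
    if (n > 0L) {
      if (config$noise_sd > 0) {
        constructs <- apply_sn_filter(constructs)
      } else {
        constructs$SN_filter <- 1L   # noise-free labels: SN undefined
      }
    }
    truth <- if (n > 0L) dplyr::bind_rows(lapply(seq_len(n), function(i) {
      r <- constructs[i, ]
      dplyr::bind_rows(lapply(names(models), function(dt) {
        pred <- predict(models[[dt]], r)
        pred[seq_len(r$seq_scored), ]
      }))
    })) else tibble::tibble(id = character(), position = integer(),
                            data_type = character(), value = double())
    list(constructs = constructs, truth = truth, models = models)
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes the labelled constructs as JSON-lines plus a planted-truth
#' sidecar JSON (planted coefficients, noise parameters, and noise-free
#' labels) for recovery tests.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`constructs`, `truth`).
#' @export
make_dataset <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ds <- synthetic_dataset(config)
  data_path <- file.path(dir, "constructs.jsonl")
  truth_path <- file.path(dir, "planted_truth.json")
  write_constructs(ds$constructs, data_path)
  jsonlite::write_json(
    list(
      kind = "degkit_planted_truth",
      config = unclass(config),
      models = lapply(ds$models, function(m) {
        list(target = m$target, w = m$w, intercept = m$beta0,
             coefficients = as.list(m$beta))
      }),
      truth = ds$truth
    ),
    truth_path, auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(list(constructs = data_path, truth = truth_path))
}
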