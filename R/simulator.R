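#' Incremental Bayesian posterior over words
#'
#' Combines word priors (relative usage frequencies) with product-rule
#' sensory evidence for the heard prefix:
#' `posterior_i = prior_i * likelihood_i / sum_j prior_j * likelihood_j`.
#' The posterior is recomputed afresh for every prefix; the model carries no
#' state across segments. When every evidence-weighted prior is zero the
#' state is flagged degenerate (posteriors set to 0) rather than erroring.
#'
#' @param lexicon A `cohort_lexicon`.
#' @param evidence An `evidence_matrix` over the lexicon's inventory.
#' @param heard_segments Heard prefix (boundary tokens included); may be
#'   empty, in which case the posterior equals the normalised priors.
#' @return A tibble of class `posterior_state` with columns `word`, `prior`,
#'   `likelihood`, `posterior`, and attributes `heard` and `degenerate`.
#' @export
posterior_update <- function(lexicon, evidence, heard_segments = character(0)) {
  if (nrow(lexicon) == 0) abort("empty lexicon", class = "cohortpe_bad_lexicon")
  heard <- parse_segments(heard_segments)
  check_known_segments(lexicon, heard, "heard_segments")
  prior <- lexicon$frequency / sum(lexicon$frequency)
  lik <- vapply(lexicon$segments, word_evidence, numeric(1),
                evidence = evidence, heard_segments = heard)
  w <- prior * lik
  z <- sum(w)
  degenerate <- z <= 0
  posterior <- if (degenerate) rep(0, length(w)) else w / z
  out <- tibble::tibble(word = lexicon$word, prior = prior,
                        likelihood = lik, posterior = posterior)
  structure(out,
            class = c("posterior_state", class(out)),
            heard = heard, degenerate = degenerate,
            inventory = segment_inventory(lexicon))
}

#' Predicted probability of each next segment
#'
#' Sums word posteriors over words sharing the same next segment (the
#' segment at position `length(heard) + 1` of each word). Words that end at
#' or before the current position contribute to no entry, so the vector can
#' sum to less than one.
#'
#' @param posterior_state Result of [posterior_update()].
#' @param lexicon The same lexicon the posterior was computed from.
#' @param prior_fallback If the posterior is degenerate (all evidence-weighted
#'   priors zero, e.g. a pseudoword prefix past its divergence point), fall
#'   back to a prior-only prediction instead of erroring.
#' @return Named numeric vector over the full inventory (boundary included),
#'   entries in `[0, 1]` summing to at most 1.
#' @export
segment_prediction <- function(posterior_state, lexicon, prior_fallback = FALSE) {
  inv <- segment_inventory(lexicon)
  p <- posterior_state$posterior
  if (isTRUE(attr(posterior_state, "degenerate"))) {
    if (!prior_fallback) {
      abort(paste("degenerate posterior: no word is consistent with the prefix;",
                  "call with prior_fallback = TRUE for a prior-only prediction"),
            class = "cohortpe_degenerate_posterior")
    }
    p <- posterior_state$prior
  }
  heard_n <- length(attr(posterior_state, "heard"))
  pred <- setNames(numeric(length(inv)), inv)
  next_seg <- vapply(lexicon$segments, function(s) {
    if (length(s) > heard_n) s[heard_n + 1] else NA_character_
  }, character(1))
  keep <- !is.na(next_seg) & p > 0
  if (any(keep)) {
    sums <- tapply(p[keep], next_seg[keep], sum)
    pred[names(sums)] <- sums
  }
  pred
}

new_model_repr <- function(values, kind, item_id = NA_character_,
                           condition = NA_character_, temperature = NA_real_) {
  structure(values, class = "model_repr", kind = kind, item_id = item_id,
            condition = condition, temperature = temperature)
}

#' @export
print.model_repr <- function(x, ...) {
  cat(sprintf("<model_repr kind=%s item=%s condition=%s>\n",
              attr(x, "kind"), attr(x, "item_id"), attr(x, "condition")))
  print(unclass(x)[unclass(x) != 0], ...)
  invisible(x)
}

repr_kind <- function(x) attr(x, "kind")

check_repr_kind <- function(x, kind) {
  if (!inherits(x, "model_repr") || !identical(repr_kind(x), kind)) {
    abort(paste0("expected a model representation of kind '", kind, "'"),
          class = "cohortpe_wrong_kind")
  }
  invisible(x)
}

#' Sharpened-signal representation
#'
#' Elementwise product of the segment prediction with the sensory evidence
#' row for the heard segment, renormalised to sum to one: prior knowledge
#' enhances expected features and suppresses the rest. If the product is
#' zero everywhere (prediction and evidence have disjoint support) the raw
#' evidence row is returned unchanged (pure bottom-up fallback) with a
#' warning.
#'
#' @param prediction Named prediction vector from [segment_prediction()].
#' @param input_row Evidence-matrix row for the segment actually heard, in
#'   the same segment order as `prediction`.
#' @param ... Passed to the internal constructor (item id, condition,
#'   temperature tags).
#' @return A `model_repr` of kind `"sharpened"`: non-negative, sums to 1.
#' @export
sharpened_signal <- function(prediction, input_row, ...) {
  stopifnot(length(prediction) == length(input_row))
  v <- as.numeric(prediction) * as.numeric(input_row)
  z <- sum(v)
  if (z <= 0) {
    warn("sharpened signal has no support; falling back to the raw input row",
         class = "cohortpe_no_support")
    v <- as.numeric(input_row) / sum(input_row)
  } else {
    v <- v / z
  }
  new_model_repr(setNames(v, names(prediction)), "sharpened", ...)
}

#' Prediction-error representation
#'
#' Sensory evidence minus prediction, elementwise and unnormalised; entries
#' are negative where predicted features go unheard and positive where heard
#' features were unpredicted.
#'
#' @inheritParams sharpened_signal
#' @return A `model_repr` of kind `"prediction_error"`.
#' @export
prediction_error <- function(prediction, input_row, ...) {
  stopifnot(length(prediction) == length(input_row))
  v <- as.numeric(input_row) - as.numeric(prediction)
  new_model_repr(setNames(v, names(prediction)), "prediction_error", ...)
}

#' Univariate linking functions
#'
#' Map a model representation to a scalar standing in for overall neural
#' response magnitude:
#' * `univariate_pe()` - summed absolute prediction error over the
#'   inventory.
#' * `univariate_sharpened()` - mean of log-transformed sharpened
#'   probabilities (a small floor `eps` keeps zero entries finite);
#'   motivated by neural coding of log probability.
#' * `univariate_entropy_link()` - Shannon entropy `-sum v log v` of the
#'   sharpened distribution, with `0 log 0 = 0`.
#'
#' @param representation A `model_repr` of the matching kind.
#' @param eps Log floor for `univariate_sharpened()`.
#' @return A scalar.
#' @export
univariate_pe <- function(representation) {
  check_repr_kind(representation, "prediction_error")
  sum(abs(as.numeric(representation)))
}

#' @rdname univariate_pe
#' @export
univariate_sharpened <- function(representation, eps = 1e-12) {
  check_repr_kind(representation, "sharpened")
  v <- as.numeric(representation)
  mean(log(v + eps))
}

#' @rdname univariate_pe
#' @export
univariate_entropy_link <- function(representation) {
  check_repr_kind(representation, "sharpened")
  v <- as.numeric(representation)
  v <- v[v > 0]
  -sum(v * log(v))
}

#' Model representations for one item at its divergence point
#'
#' Computes the word posterior and next-segment prediction from the segments
#' heard strictly before the divergence point (DP), takes the evidence row of
#' the segment actually heard at the DP (the word's own segment for Match
#' items, the cross-spliced alternative for Mismatch items), and returns the
#' sharpened-signal and prediction-error representations.
#'
#' @param lexicon A `cohort_lexicon`.
#' @param evidence An `evidence_matrix` over its inventory.
#' @param item A list or one-row data frame with at least `heard_segments`
#'   (full segment sequence of the item as heard) and `dp_index` (1-based
#'   position of the divergence-point segment); `item_id` and `condition`
#'   are carried through as tags when present.
#' @return List with elements `sharpened`, `prediction_error` (both
#'   `model_repr`), `prediction`, `input_row` and `posterior`.
#' @export
simulate_item_at_dp <- function(lexicon, evidence, item) {
  heard <- parse_segments(item$heard_segments[[1]])
  dp <- as.integer(item$dp_index[[1]])
  if (is.na(dp) || dp < 2 || dp > length(heard)) {
    abort("dp_index must lie within the heard segment sequence (and be >= 2)",
          class = "cohortpe_bad_item")
  }
  inv <- segment_inventory(lexicon)
  prefix <- heard[seq_len(dp - 1)]
  post <- posterior_update(lexicon, evidence, prefix)
  if (isTRUE(attr(post, "degenerate"))) {
    abort("degenerate posterior before the divergence point; check the design",
          class = "cohortpe_degenerate_posterior")
  }
  pred <- segment_prediction(post, lexicon)
  input_row <- setNames(as.numeric(evidence[heard[dp], inv]), inv)
  id <- if (!is.null(item$item_id)) as.character(item$item_id[[1]]) else NA_character_
  cond <- if (!is.null(item$condition)) as.character(item$condition[[1]]) else NA_character_
  tt <- attr(evidence, "temperature") %||% NA_real_
  list(
    sharpened = sharpened_signal(pred, input_row, item_id = id,
                                 condition = cond, temperature = tt),
    prediction_error = prediction_error(pred, input_row, item_id = id,
                                        condition = cond, temperature = tt),
    prediction = pred,
    input_row = input_row,
    posterior = post
  )
}

condition_levels <- function() {
  c("Strong+Match", "Weak+Match", "Strong+Mismatch", "Weak+Mismatch")
}

check_design <- function(design) {
  needed <- c("item_id", "set_id", "strength", "congruency",
              "heard_segments", "dp_index", "syl2_label")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("design table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cohortpe_bad_design")
  }
  if (anyDuplicated(design$item_id)) {
    abort("design item_id values must be unique", class = "cohortpe_bad_design")
  }
  if (!all(design$strength %in% c("Strong", "Weak")) ||
      !all(design$congruency %in% c("Match", "Mismatch"))) {
    abort("strength must be Strong|Weak and congruency Match|Mismatch",
          class = "cohortpe_bad_design")
  }
  invisible(design)
}

design_conditions <- function(design) {
  factor(paste(design$strength, design$congruency, sep = "+"),
         levels = condition_levels())
}

#' Condition-level divergence-point simulation
#'
#' Runs [simulate_item_at_dp()] for every item in the design and applies the
#' same two analyses used on neural data: per-item univariate readouts and
#' within-condition pattern distances (Euclidean distances between model
#' representations for all item pairs within a condition, with the
#' reciprocal-pair exclusion applied).
#'
#' @param lexicon,evidence As for [simulate_item_at_dp()].
#' @param design Item design table with columns `item_id`, `set_id`,
#'   `strength` (Strong|Weak), `congruency` (Match|Mismatch),
#'   `heard_segments`, `dp_index`, `syl2_label`. The four conditions must
#'   have equal item counts.
#' @return An object of class `dp_simulation`: a list with
#'   * `items`: tibble of per-item univariate readouts
#'     (`univariate_pe`, `univariate_sharpened`, `entropy_link`),
#'   * `pairs`: tibble of unmasked within-condition pattern distances per
#'     model kind,
#'   * `condition_means`: tibble of mean within-condition distances,
#'   * `crossover`: tibble with the interaction statistic
#'     `(Strong - Weak | Mismatch) - (Strong - Weak | Match)` per kind,
#'   * `representations`: list of item-by-segment matrices per kind,
#'   * `rdms`, `mask`, `design`, `temperature`.
#' Use [tidy()], [glance()] and [autoplot()] on it.
#' @export
run_condition_simulation <- function(lexicon, evidence, design) {
  check_design(design)
  cond <- design_conditions(design)
  counts <- table(cond)
  if (length(unique(counts)) != 1) {
    abort("the four conditions must have equal item counts",
          class = "cohortpe_bad_design")
  }
  inv <- segment_inventory(lexicon)
  n <- nrow(design)
  reprs <- list(
    sharpened = matrix(0, n, length(inv), dimnames = list(design$item_id, inv)),
    prediction_error = matrix(0, n, length(inv),
                              dimnames = list(design$item_id, inv))
  )
  items <- design
  items$condition <- as.character(cond)
  items$univariate_pe <- NA_real_
  items$univariate_sharpened <- NA_real_
  items$entropy_link <- NA_real_
  for (i in seq_len(n)) {
    sim <- simulate_item_at_dp(lexicon, evidence, design[i, ])
    reprs$sharpened[i, ] <- as.numeric(sim$sharpened)
    reprs$prediction_error[i, ] <- as.numeric(sim$prediction_error)
    items$univariate_pe[i] <- univariate_pe(sim$prediction_error)
    items$univariate_sharpened[i] <- univariate_sharpened(sim$sharpened)
    items$entropy_link[i] <- univariate_entropy_link(sim$sharpened)
  }
  mask <- reciprocal_pair_mask(design)
  rdms <- lapply(reprs, euclidean_rdm)
  pairs <- purrr::imap_dfr(rdms, function(rdm, kind) {
    dplyr::mutate(rdm_pairs(rdm, design, mask, within_condition = TRUE),
                  kind = kind, .before = 1)
  })
  condition_means <- pairs |>
    dplyr::group_by(.data$kind, .data$condition) |>
    dplyr::summarise(mean_distance = mean(.data$distance),
                     n_pairs = dplyr::n(), .groups = "drop")
  crossover <- condition_means |>
    tidyr::pivot_wider(id_cols = "kind", names_from = "condition",
                       values_from = "mean_distance") |>
    dplyr::mutate(
      crossover = (.data$`Strong+Mismatch` - .data$`Weak+Mismatch`) -
        (.data$`Strong+Match` - .data$`Weak+Match`),
      match_strong_minus_weak = .data$`Strong+Match` - .data$`Weak+Match`,
      mismatch_strong_minus_weak = .data$`Strong+Mismatch` - .data$`Weak+Mismatch`
    )
  structure(list(items = tibble::as_tibble(items), pairs = pairs,
                 condition_means = condition_means, crossover = crossover,
                 representations = reprs, rdms = rdms, mask = mask,
                 design = design,
                 temperature = attr(evidence, "temperature") %||% NA_real_),
            class = "dp_simulation")
}

# tidy pair list of an RDM restricted to unmasked (and optionally
# within-condition) pairs
rdm_pairs <- function(rdm, design, mask, within_condition = FALSE) {
  ids <- design$item_id
  cond <- as.character(design_conditions(design))
  ut <- which(upper.tri(rdm), arr.ind = TRUE)
  keep <- !mask[ut]
  if (within_condition) keep <- keep & cond[ut[, 1]] == cond[ut[, 2]]
  ut <- ut[keep, , drop = FALSE]
  tibble::tibble(item_a = ids[ut[, 1]], item_b = ids[ut[, 2]],
                 condition = cond[ut[, 1]], distance = rdm[ut])
}

#' @export
print.dp_simulation <- function(x, ...) {
  cat(sprintf("<dp_simulation: %d items, T = %g>\n", nrow(x$items),
              x$temperature))
  print(x$condition_means, ...)
  invisible(x)
}

#' Simulations across a grid of sensory-uncertainty levels
#'
#' Reruns [run_condition_simulation()] at each softmax temperature in
#' `t_grid` (low temperature = high sensory uncertainty) and flags, per
#' temperature, whether the Match-condition prediction-error pattern
#' distances reverse to Strong > Weak — the signature expected under high
#' uncertainty only.
#'
#' @param lexicon A `cohort_lexicon`.
#' @param features Segment feature matrix (boundary row added internally).
#' @param design Item design table.
#' @param t_grid Positive temperatures; at least 3 values spanning at least
#'   two orders of magnitude. Default [default_temperature_grid()].
#' @return Object of class `uncertainty_sweep`: list with `condition_means`
#'   (per T), `flags` (per T: `pe_crossover`, `sharpened_crossover`,
#'   `match_reversal`), and `simulations`.
#' @export
uncertainty_sweep <- function(lexicon, features, design,
                              t_grid = default_temperature_grid()) {
  if (length(t_grid) < 3 || any(t_grid <= 0) ||
      max(t_grid) / min(t_grid) < 100) {
    abort("t_grid needs >= 3 positive values spanning >= 2 orders of magnitude",
          class = "cohortpe_bad_temperature")
  }
  d <- segment_distance_matrix(features, boundary = boundary_token(lexicon))
  sims <- lapply(t_grid, function(tt) {
    run_condition_simulation(lexicon, softmax_evidence(d, tt), design)
  })
  names(sims) <- as.character(t_grid)
  condition_means <- purrr::map2_dfr(sims, t_grid, function(s, tt) {
    dplyr::mutate(s$condition_means, temperature = tt, .before = 1)
  })
  flags <- purrr::map2_dfr(sims, t_grid, function(s, tt) {
    co <- s$crossover
    pe <- co[co$kind == "prediction_error", ]
    sh <- co[co$kind == "sharpened", ]
    tibble::tibble(temperature = tt,
                   pe_crossover = pe$crossover > 0,
                   sharpened_crossover = sh$crossover > 0,
                   match_reversal = pe$match_strong_minus_weak > 0)
  })
  structure(list(condition_means = condition_means, flags = flags,
                 simulations = sims, t_grid = t_grid),
            class = "uncertainty_sweep")
}

#' @export
print.uncertainty_sweep <- function(x, ...) {
  cat("<uncertainty_sweep>\n")
  print(x$flags, ...)
  invisible(x)
}

#' Default softmax temperature settings
#'
#' The single-run default `T = 0.5` puts the default class-structured
#' synthetic features in the moderate-uncertainty regime where the heard
#' segment dominates its evidence row but within-class competitors retain
#' graded support -- the regime in which the qualitative condition orderings
#' of both model readouts hold. The default sweep grid spans two orders of
#' magnitude, from the near-uniform high-uncertainty regime up to the
#' near-one-hot minimal-uncertainty regime.
#'
#' @return A scalar / numeric vector of temperatures.
#' @export
default_temperature <- function() 0.5

#' @rdname default_temperature
#' @export
default_temperature_grid <- function() 10^seq(-1.5, 0.5, length.out = 5)
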