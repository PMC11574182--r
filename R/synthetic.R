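# run code under a temporary RNG state so generators are pure functions of
# their seed and leave the caller's RNG untouched
with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic stimulus design
#'
#' Describes the cross-splicing design the generator emulates: item sets each
#' containing two second-syllable (Syl2) types that share their onset
#' segment, first syllables (Syl1) that either uniquely predict their Syl2
#' (Strong) or compete with several other words (Weak), and pseudowords
#' formed by swapping Syl2 within a set. With the defaults (8 sets, 2 words
#' per strength and Syl2 type) the design has 32 items in each of the four
#' Strong/Weak x Match/Mismatch conditions.
#'
#' @param n_sets Number of item sets (default 8).
#' @param words_per_syl2 Words per set, strength and Syl2 type (default 2;
#'   items per condition = `n_sets * 2 * words_per_syl2`).
#' @param weak_cohort_size Range (min, max) of the number of words sharing a
#'   Weak first syllable, target included (default 3-8).
#' @param weak_frequency_skew Zipf exponent for competitor frequencies
#'   (default 1); the Weak target always ranks at least second, so its
#'   conditional probability stays below 0.5.
#' @param share_onset_prob Probability that a further competitor's Syl2
#'   shares the set's Syl2 onset segment (one competitor per Weak word
#'   always does, so predictive uncertainty survives to the divergence
#'   point). Default 0.5.
#' @param inventory_size Total segment inventory size including the boundary
#'   token (default 48: 47 phoneme stand-ins plus the boundary).
#' @param feature_dim Length of each synthetic acoustic feature vector
#'   (default 20).
#' @param n_feature_classes Number of phonetic classes the feature vectors
#'   cluster into (default 8). Real acoustic features are far more
#'   confusable within a phonetic class (e.g. place or manner neighbours)
#'   than across classes; clustering reproduces that graded confusability.
#' @param feature_within_sd Within-class feature spread relative to the
#'   unit-Gaussian class centres (default 0.3); smaller values make
#'   within-class segments more confusable.
#' @param seed Integer seed; the generator is a pure function of the
#'   parameters.
#' @return A list of class `design_params`.
#' @export
design_params <- function(n_sets = 8, words_per_syl2 = 2,
                          weak_cohort_size = c(3, 8),
                          weak_frequency_skew = 1,
                          share_onset_prob = 0.5,
                          inventory_size = 48, feature_dim = 20,
                          n_feature_classes = 8, feature_within_sd = 0.3,
                          seed = 0) {
  stopifnot(n_sets >= 1, words_per_syl2 >= 1,
            length(weak_cohort_size) == 2,
            weak_cohort_size[1] >= 2,
            weak_cohort_size[2] >= weak_cohort_size[1],
            share_onset_prob >= 0, share_onset_prob <= 1,
            feature_dim >= 2, n_feature_classes >= 1,
            feature_within_sd > 0)
  if (inventory_size < 10) {
    abort("inventory too small to satisfy the design's uniqueness constraints",
          class = "cohortpe_bad_params")
  }
  structure(list(n_sets = n_sets, words_per_syl2 = words_per_syl2,
                 items_per_condition = n_sets * 2 * words_per_syl2,
                 weak_cohort_size = weak_cohort_size,
                 weak_frequency_skew = weak_frequency_skew,
                 share_onset_prob = share_onset_prob,
                 inventory_size = inventory_size, feature_dim = feature_dim,
                 n_feature_classes = n_feature_classes,
                 feature_within_sd = feature_within_sd,
                 seed = seed),
            class = "design_params")
}

zipf_frequencies <- function(k, skew, base = 1000) {
  pmax(1, round(base / seq_len(k)^skew))
}

#' Generate a synthetic lexicon and item design table
#'
#' Builds a lexicon with the statistical structure of the Strong/Weak x
#' Match/Mismatch cross-splicing design: per set, two Syl2 types sharing
#' their first segment; Strong first syllables with exactly one lexical
#' continuation; Weak first syllables embedded among Zipf-weighted
#' competitor words so the target continuation has conditional probability
#' below one half; pseudowords formed by swapping Syl2 within a set, with
#' the divergence point at the second segment of Syl2.
#'
#' @param params A [design_params()] object.
#' @return List with `lexicon` (a `cohort_lexicon`), `design` (item design
#'   tibble with columns `item_id`, `set_id`, `strength`, `congruency`,
#'   `condition`, `heard_segments`, `dp_index`, `syl2_label`, `word`,
#'   `syl1`, `syl2`) and `params`.
#' @export
generate_lexicon <- function(params = design_params()) {
  stopifnot(inherits(params, "design_params"))
  boundary <- "-"
  phonemes <- sprintf("s%02d", seq_len(params$inventory_size - 1))
  with_seed(params$seed, {
    entries <- list()
    design_rows <- list()
    used_syl1 <- character(0)

    new_syl1 <- function() {
      repeat {
        len <- sample(2:3, 1)
        s <- sample(phonemes, len, replace = TRUE)
        key <- paste(s, collapse = " ")
        if (!key %in% used_syl1) {
          used_syl1 <<- c(used_syl1, key)
          return(s)
        }
      }
    }

    add_entry <- function(segments, frequency) {
      entries[[length(entries) + 1]] <<- list(
        word = paste(segments[segments != boundary], collapse = ""),
        transcription = paste(segments, collapse = " "),
        frequency = frequency)
    }

    for (set in seq_len(params$n_sets)) {
      onset <- sample(phonemes, 1)
      second <- sample(setdiff(phonemes, onset), 2)
      syl2 <- lapply(1:2, function(i) {
        tail_len <- sample(0:1, 1)
        c(onset, second[i], if (tail_len) sample(phonemes, 1))
      })
      syl2_labels <- paste0("set", set, c("A", "B"))

      for (strength in c("Strong", "Weak")) {
        for (type in 1:2) {
          for (w in seq_len(params$words_per_syl2)) {
            syl1 <- new_syl1()
            this_syl2 <- syl2[[type]]
            other_syl2 <- syl2[[3 - type]]
            word_segments <- c(syl1, boundary, this_syl2)

            if (strength == "Strong") {
              add_entry(word_segments, sample(10:1000, 1))
            } else {
              k <- sample(params$weak_cohort_size[1]:params$weak_cohort_size[2], 1)
              freqs <- zipf_frequencies(k, params$weak_frequency_skew)
              target_rank <- sample(2:k, 1)
              add_entry(word_segments, freqs[target_rank])
              comp_ranks <- setdiff(seq_len(k), target_rank)
              comp_seconds <- character(0)
              comp_keys <- character(0)
              for (ci in seq_along(comp_ranks)) {
                # the first competitor always survives to the divergence
                # point by sharing the Syl2 onset segment
                shares <- ci == 1 || stats::runif(1) < params$share_onset_prob
                repeat {
                  if (shares) {
                    x <- sample(setdiff(phonemes, c(second, comp_seconds)), 1)
                    comp_syl2 <- c(onset, x, if (sample(0:1, 1)) sample(phonemes, 1))
                  } else {
                    y <- sample(setdiff(phonemes, onset), 1)
                    comp_syl2 <- c(y, sample(phonemes, sample(1:2, 1), replace = TRUE))
                  }
                  key <- paste(comp_syl2, collapse = " ")
                  if (!key %in% comp_keys) break
                }
                comp_keys <- c(comp_keys, key)
                if (shares) comp_seconds <- c(comp_seconds, x)
                add_entry(c(syl1, boundary, comp_syl2), freqs[comp_ranks[ci]])
              }
            }

            word_id <- paste(word_segments[word_segments != boundary],
                             collapse = "")
            # match item: the word itself
            design_rows[[length(design_rows) + 1]] <- tibble::tibble(
              item_id = word_id,
              set_id = set, strength = strength, congruency = "Match",
              heard_segments = paste(word_segments, collapse = " "),
              dp_index = length(syl1) + 3L,
              syl2_label = syl2_labels[type],
              word = word_id,
              syl1 = paste(syl1, collapse = " "),
              syl2 = paste(this_syl2, collapse = " "))
            # mismatch item: same Syl1 cross-spliced with the set's other Syl2
            design_rows[[length(design_rows) + 1]] <- tibble::tibble(
              item_id = paste0(word_id, ".pw"),
              set_id = set, strength = strength, congruency = "Mismatch",
              heard_segments = paste(c(syl1, boundary, other_syl2), collapse = " "),
              dp_index = length(syl1) + 3L,
              syl2_label = syl2_labels[3 - type],
              word = word_id,
              syl1 = paste(syl1, collapse = " "),
              syl2 = paste(other_syl2, collapse = " "))
          }
        }
      }
    }

    lex <- as_lexicon(dplyr::bind_rows(lapply(entries, tibble::as_tibble)),
                      inventory = phonemes, boundary = boundary)
    design <- dplyr::bind_rows(design_rows)
    design$condition <- paste(design$strength, design$congruency, sep = "+")
    list(lexicon = lex, design = design, params = params)
  })
}

#' Generate synthetic per-segment acoustic feature vectors
#'
#' One feature vector per phoneme stand-in, drawn as a Gaussian class centre
#' (segments are assigned round-robin to `n_feature_classes` phonetic
#' classes) plus within-class Gaussian jitter of scale `feature_within_sd`.
#' This gives the acoustic distances the graded structure of real segment
#' confusability: within-class segments are close (easily confused), while
#' across-class segments are far apart. The boundary token receives no
#' features; [segment_distance_matrix()] appends it as a maximally distinct
#' segment. Distinctness of the vectors is checked and enforced by redrawing
#' in the (measure-zero) event of a collision.
#'
#' @param params A [design_params()] object.
#' @return Numeric matrix (phonemes x features) with segment row names.
#' @export
generate_segment_features <- function(params = design_params()) {
  stopifnot(inherits(params, "design_params"))
  n_phon <- params$inventory_size - 1L
  phonemes <- sprintf("s%02d", seq_len(n_phon))
  n_class <- min(params$n_feature_classes, n_phon)
  with_seed(params$seed + 1L, {
    repeat {
      centres <- matrix(rnorm(n_class * params$feature_dim), nrow = n_class)
      classes <- rep_len(seq_len(n_class), n_phon)
      m <- centres[classes, , drop = FALSE] +
        matrix(rnorm(n_phon * params$feature_dim,
                     sd = params$feature_within_sd), nrow = n_phon)
      dimnames(m) <- list(phonemes, paste0("f", seq_len(params$feature_dim)))
      if (min(dist(m)) > 0) return(m)
    }
  })
}

#' Parameters of the synthetic neural-data generator
#'
#' @param mechanism Which model representation is embedded in the sensor
#'   patterns: `"prediction_error"` or `"sharpened"`.
#' @param n_subjects Number of simulated participants (default 19).
#' @param n_sensors Number of sensors (default 40).
#' @param n_reps Stimulus repetitions sharing the signal but not the noise
#'   (default 3).
#' @param n_timepoints,t_start,dt Sampling grid in ms (default 26 samples
#'   every 20 ms from -100 ms, relative to Syl2 onset).
#' @param window Response window (ms) inside which the item's embedded
#'   pattern is active (default 100-300 ms).
#' @param snr Signal amplitude relative to unit sensor noise (default 0.5).
#' @param seed Integer seed.
#' @return A list of class `neural_gen_params`.
#' @export
neural_gen_params <- function(mechanism = c("prediction_error", "sharpened"),
                              n_subjects = 19, n_sensors = 40, n_reps = 3,
                              n_timepoints = 26, t_start = -100, dt = 20,
                              window = c(100, 300), snr = 0.5, seed = 0) {
  mechanism <- match.arg(mechanism)
  stopifnot(snr > 0, n_subjects >= 2, n_sensors >= 2, n_reps >= 1)
  times <- t_start + dt * (seq_len(n_timepoints) - 1)
  if (window[1] < min(times) || window[2] > max(times)) {
    abort("response window must lie within the epoch",
          class = "cohortpe_bad_params")
  }
  structure(list(mechanism = mechanism, n_subjects = n_subjects,
                 n_sensors = n_sensors, n_reps = n_reps, times = times,
                 window = window, snr = snr, seed = seed),
            class = "neural_gen_params")
}

#' Generate a synthetic sensor dataset embedding a model representation
#'
#' Each item's divergence-point model representation (per the chosen
#' mechanism) is projected through a fixed random linear embedding into
#' sensor space, scaled so the average embedded pattern has unit norm,
#' switched on with a smooth bump inside the response window, multiplied by
#' `snr`, and buried in independent unit-Gaussian sensor noise. Repetitions
#' share the signal, not the noise. Outside the window the data are pure
#' noise.
#'
#' @param lexicon,evidence,design As for [run_condition_simulation()].
#' @param params A [neural_gen_params()] object.
#' @return A [neural_dataset()] with attributes `mechanism`, `snr` and
#'   `gen_params`.
#' @export
generate_neural_dataset <- function(lexicon, evidence, design,
                                    params = neural_gen_params()) {
  stopifnot(inherits(params, "neural_gen_params"))
  sim <- run_condition_simulation(lexicon, evidence, design)
  reprs <- sim$representations[[params$mechanism]]
  n_items <- nrow(reprs)
  times <- params$times
  prof <- ifelse(times >= params$window[1] & times <= params$window[2],
                 sin(pi * (times - params$window[1]) /
                       (params$window[2] - params$window[1])),
                 0)
  with_seed(params$seed, {
    embed <- matrix(rnorm(ncol(reprs) * params$n_sensors) / sqrt(ncol(reprs)),
                    nrow = ncol(reprs))
    patterns <- reprs %*% embed
    patterns <- patterns / mean(sqrt(rowSums(patterns^2)))
    signal <- array(0, c(n_items, params$n_sensors, length(times)))
    for (tp in seq_along(times)) {
      signal[, , tp] <- params$snr * prof[tp] * patterns
    }
    data <- array(NA_real_, c(params$n_subjects, n_items, params$n_reps,
                              params$n_sensors, length(times)))
    for (s in seq_len(params$n_subjects)) {
      for (r in seq_len(params$n_reps)) {
        data[s, , r, , ] <- signal +
          array(rnorm(n_items * params$n_sensors * length(times)),
                dim(signal))
      }
    }
    ds <- neural_dataset(data, times, design)
    attr(ds, "mechanism") <- params$mechanism
    attr(ds, "snr") <- params$snr
    attr(ds, "gen_params") <- params
    ds
  })
}

#' Small frozen design for examples and unit tests
#'
#' Two sets with one word per strength and Syl2 type: 4 items per condition,
#' fixed seed.
#'
#' @return As [generate_lexicon()].
#' @export
fixture_design <- function() {
  generate_lexicon(design_params(n_sets = 2, words_per_syl2 = 1, seed = 42))
}
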