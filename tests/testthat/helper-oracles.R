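# Shared fixtures and independent oracle implementations used across the
# test files. Oracles are written in the most direct (slow) style possible
# so that agreement with the package implementations is informative.

# Small hand-written lexicon: "bingo" is the only word with first syllable
# /b I N/; /t a N/ has three positive-frequency continuers (tango, tangle,
# and the monosyllable tang, which matches because its full form equals the
# syllable) while "tank" extends past /t a N/ without a boundary and so does
# not match.
toy_lexicon <- function() {
  as_lexicon(tibble::tibble(
    word = c("bingo", "tango", "tangle", "tang", "tank"),
    transcription = c("b I N - g @U", "t a N - g @U", "t a N - g l=",
                      "t a N", "t a N k"),
    frequency = c(210, 7, 69, 58, 60)
  ))
}

# Uniform-confusability evidence matrix over a lexicon's inventory with a
# dominant diagonal; handy when any valid evidence matrix will do.
toy_evidence <- function(lexicon, temperature = 1) {
  inv <- segment_inventory(lexicon)
  d <- matrix(2, length(inv), length(inv), dimnames = list(inv, inv))
  diag(d) <- 0
  softmax_evidence(d, temperature)
}

# Brute-force Bayes: enumerate every word, multiply evidence entries one by
# one, normalise by the explicit sum.
oracle_posterior <- function(lexicon, evidence, heard) {
  prior <- lexicon$frequency / sum(lexicon$frequency)
  lik <- vapply(lexicon$segments, function(s) {
    if (length(heard) == 0) return(1)
    if (length(s) < length(heard)) return(0)
    p <- 1
    for (k in seq_along(heard)) p <- p * evidence[heard[k], s[k]]
    p
  }, numeric(1))
  w <- prior * lik
  w / sum(w)
}

# Brute-force next-segment prediction from an explicit posterior.
oracle_prediction <- function(lexicon, posterior, heard) {
  inv <- segment_inventory(lexicon)
  pred <- stats::setNames(numeric(length(inv)), inv)
  for (i in seq_len(nrow(lexicon))) {
    s <- lexicon$segments[[i]]
    if (length(s) > length(heard)) {
      nxt <- s[length(heard) + 1]
      pred[nxt] <- pred[nxt] + posterior[i]
    }
  }
  pred
}

# Exhaustive-recursion Levenshtein distance over label vectors.
oracle_levenshtein <- function(a, b) {
  if (length(a) == 0) return(length(b))
  if (length(b) == 0) return(length(a))
  min(oracle_levenshtein(a[-1], b) + 1,
      oracle_levenshtein(a, b[-1]) + 1,
      oracle_levenshtein(a[-1], b[-1]) + (a[1] != b[1]))
}

# Direct-formula Euclidean RDM.
oracle_euclidean <- function(patterns) {
  n <- nrow(patterns)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- sqrt(sum((patterns[i, ] - patterns[j, ])^2))
    }
  }
  m
}

# Direct-formula crossnobis: average over ordered fold pairs of the
# cross-validated Mahalanobis form, one pair at a time.
oracle_crossnobis <- function(folds, sigma = NULL) {
  n_items <- nrow(folds[[1]])
  n_feat <- ncol(folds[[1]])
  if (is.null(sigma)) sigma <- diag(n_feat)
  prec <- solve(sigma)
  m <- matrix(0, n_items, n_items)
  n_pairs <- 0
  for (a in seq_along(folds)) {
    for (b in seq_along(folds)) {
      if (a == b) next
      for (i in seq_len(n_items)) {
        for (j in seq_len(n_items)) {
          da <- folds[[a]][i, ] - folds[[a]][j, ]
          db <- folds[[b]][i, ] - folds[[b]][j, ]
          m[i, j] <- m[i, j] + drop(t(da) %*% prec %*% db)
        }
      }
      n_pairs <- n_pairs + 1
    }
  }
  m / n_pairs
}

# Small deterministic design + lexicon for simulator-level tests.
small_setup <- function(temperature = default_temperature()) {
  gen <- fixture_design()
  features <- generate_segment_features(gen$params)
  d <- segment_distance_matrix(features, boundary = boundary_token(gen$lexicon))
  list(lexicon = gen$lexicon, design = gen$design, features = features,
       evidence = softmax_evidence(d, temperature), params = gen$params)
}
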