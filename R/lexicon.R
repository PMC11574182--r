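#' Build a lexicon from a data frame
#'
#' A lexicon is a tibble with one row per word, carrying its segment-level
#' phonetic transcription (with an interleaved syllable-boundary token) and a
#' usage-frequency count. All stimulus-design statistics (conditional syllable
#' probability, surprisal, entropy) and the recognition simulator operate on
#' this object.
#'
#' Homophones (distinct words with identical transcriptions) are allowed and
#' kept as separate rows; their frequencies add within cohorts.
#' Zero-frequency words are allowed but contribute nothing to frequency-ratio
#' probabilities or to word priors.
#'
#' @param x A data frame with columns `word` (character, unique),
#'   `transcription` (character; space-separated segment labels with the
#'   boundary token marking syllable joins, e.g. `"b I N - g @U"`) and
#'   `frequency` (non-negative numeric).
#' @param inventory Optional character vector of allowed segment labels (the
#'   boundary token is appended if absent). When `NULL`, the inventory is
#'   inferred from the transcriptions.
#' @param boundary The syllable-boundary token. Default `"-"`.
#'
#' @return A tibble of class `cohort_lexicon` with an added list-column
#'   `segments`, and attributes `inventory` and `boundary`.
#' @export
#' @examples
#' lex <- as_lexicon(tibble::tibble(
#'   word = c("bingo", "tango", "tangle"),
#'   transcription = c("b I N - g @U", "t a N - g @U", "t a N - g l="),
#'   frequency = c(210, 7, 69)
#' ))
#' conditional_syllable_probability(lex, "t a N", "g @U")
as_lexicon <- function(x, inventory = NULL, boundary = "-") {
  x <- tibble::as_tibble(x)
  required <- c("word", "transcription", "frequency")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("lexicon is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cohortpe_bad_lexicon")
  }
  if (anyDuplicated(x$word)) {
    abort("lexicon words must be unique", class = "cohortpe_bad_lexicon")
  }
  if (any(!is.finite(x$frequency)) || any(x$frequency < 0)) {
    abort("frequencies must be finite and >= 0", class = "cohortpe_bad_lexicon")
  }
  segs <- strsplit(x$transcription, " +")
  lens <- lengths(segs)
  if (any(lens == 0)) {
    abort("every word needs a non-empty transcription",
          class = "cohortpe_bad_lexicon")
  }
  bad_edge <- vapply(segs, function(s) {
    s[1] == boundary || s[length(s)] == boundary
  }, logical(1))
  if (any(bad_edge)) {
    abort(paste0("boundary token may not start or end a transcription: ",
                 paste(x$word[bad_edge], collapse = ", ")),
          class = "cohortpe_bad_lexicon")
  }
  used <- unique(unlist(segs))
  if (is.null(inventory)) {
    inventory <- sort(setdiff(used, boundary))
  } else {
    if (anyDuplicated(inventory)) {
      abort("inventory labels must be unique", class = "cohortpe_bad_lexicon")
    }
    unknown <- setdiff(used, c(inventory, boundary))
    if (length(unknown) > 0) {
      abort(paste0("transcriptions use segment label(s) not in the inventory: ",
                   paste(unknown, collapse = ", ")),
            class = "cohortpe_unknown_segment")
    }
    inventory <- setdiff(inventory, boundary)
  }
  x$segments <- segs
  structure(x,
            class = c("cohort_lexicon", class(x)),
            inventory = c(inventory, boundary),
            boundary = boundary)
}

#' Segment inventory of a lexicon
#'
#' @param lexicon A `cohort_lexicon`.
#' @return Character vector of segment labels; the boundary token is the last
#'   element.
#' @export
segment_inventory <- function(lexicon) attr(lexicon, "inventory")

#' @rdname segment_inventory
#' @export
boundary_token <- function(lexicon) attr(lexicon, "boundary")

#' Read / write a lexicon file
#'
#' The on-disk format is tab-separated text with header
#' `word  transcription  frequency`; the transcription column holds
#' space-separated segment labels with `-` marking syllable boundaries.
#'
#' @param file Path.
#' @param inventory_file Optional path to a text file with one segment label
#'   per line. When present the reader is strict and rejects transcriptions
#'   using unknown labels; otherwise the inventory is inferred.
#' @inheritParams as_lexicon
#' @return `read_lexicon()` returns a `cohort_lexicon`; `write_lexicon()`
#'   returns `file` invisibly.
#' @export
read_lexicon <- function(file, inventory_file = NULL, boundary = "-") {
  x <- utils::read.delim(file, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric"))
  inv <- if (!is.null(inventory_file)) readLines(inventory_file) else NULL
  as_lexicon(x, inventory = inv, boundary = boundary)
}

#' @rdname read_lexicon
#' @param lexicon A `cohort_lexicon`.
#' @export
write_lexicon <- function(lexicon, file) {
  utils::write.table(
    as.data.frame(lexicon)[, c("word", "transcription", "frequency")],
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Accept either a character vector of labels or a single space-separated
# string; returns the label vector.
parse_segments <- function(x) {
  if (length(x) == 1) {
    if (!nzchar(trimws(x))) return(character(0))
    if (grepl(" ", x)) x <- strsplit(trimws(x), " +")[[1]]
  }
  as.character(x)
}

check_known_segments <- function(lexicon, segments, what = "segment sequence") {
  unknown <- setdiff(segments, segment_inventory(lexicon))
  if (length(unknown) > 0) {
    abort(paste0(what, " contains unknown segment label(s): ",
                 paste(unknown, collapse = ", ")),
          class = "cohortpe_unknown_segment")
  }
  invisible(segments)
}

# Syllables of a transcription: list of segment runs between boundary tokens.
split_syllables <- function(segments, boundary) {
  idx <- cumsum(segments == boundary)
  keep <- segments != boundary
  unname(split(segments[keep], idx[keep]))
}

#' Words whose first syllable matches exactly
#'
#' Matching follows the syllabified-transcription rule used for stimulus
#' selection: a word matches `syl1` when the segments before its first
#' syllable boundary equal `syl1` exactly. A monosyllable therefore matches
#' only when its full form equals `syl1` (so "tang" /t a N/ matches /t a N/
#' while "tank" /t a N k/ does not).
#'
#' @param lexicon A `cohort_lexicon`.
#' @param syl1 First-syllable segments (character vector or space-separated
#'   string); must not contain the boundary token.
#' @return The matching rows of `lexicon` (a `cohort_lexicon`).
#' @export
first_syllable_cohort <- function(lexicon, syl1) {
  syl1 <- parse_segments(syl1)
  if (length(syl1) == 0) abort("syl1 must be non-empty",
                               class = "cohortpe_bad_syllable")
  bnd <- boundary_token(lexicon)
  if (bnd %in% syl1) abort("syl1 may not contain the boundary token",
                           class = "cohortpe_bad_syllable")
  check_known_segments(lexicon, syl1, "syl1")
  hit <- vapply(lexicon$segments, function(s) {
    first <- split_syllables(s, bnd)[[1]]
    identical(first, syl1)
  }, logical(1))
  lexicon[hit, ]
}

# nth syllable (or NULL) of each cohort entry
nth_syllable <- function(lexicon, n) {
  bnd <- boundary_token(lexicon)
  lapply(lexicon$segments, function(s) {
    syl <- split_syllables(s, bnd)
    if (length(syl) >= n) syl[[n]] else NULL
  })
}

#' Conditional probability of a second syllable given the first
#'
#' Frequency-ratio estimate: the summed frequency of words matching both
#' syllables divided by the summed frequency of words matching the first
#' syllable (exact syllabified matching, see [first_syllable_cohort()]).
#'
#' @inheritParams first_syllable_cohort
#' @param syl2 Second-syllable segments.
#' @return A probability in `[0, 1]`.
#' @export
conditional_syllable_probability <- function(lexicon, syl1, syl2) {
  syl2 <- parse_segments(syl2)
  if (length(syl2) == 0) abort("syl2 must be non-empty",
                               class = "cohortpe_bad_syllable")
  cohort <- first_syllable_cohort(lexicon, syl1)
  denom <- sum(cohort$frequency)
  if (nrow(cohort) == 0 || denom <= 0) {
    abort("conditional probability undefined: no (positive-frequency) word matches syl1",
          class = "cohortpe_undefined_conditional")
  }
  syl2s <- nth_syllable(cohort, 2)
  hit <- vapply(syl2s, function(s) !is.null(s) && identical(s, syl2), logical(1))
  sum(cohort$frequency[hit]) / denom
}

#' Attested second-syllable continuations and their probabilities
#'
#' @inheritParams first_syllable_cohort
#' @return A tibble with columns `syl2` (space-separated label string) and
#'   `probability`, summing to at most 1 (less when some cohort words are
#'   monosyllabic and so attest no second syllable).
#' @export
syllable_continuations <- function(lexicon, syl1) {
  cohort <- first_syllable_cohort(lexicon, syl1)
  denom <- sum(cohort$frequency)
  if (nrow(cohort) == 0 || denom <= 0) {
    abort("no (positive-frequency) word matches syl1",
          class = "cohortpe_undefined_conditional")
  }
  syl2s <- nth_syllable(cohort, 2)
  keep <- !vapply(syl2s, is.null, logical(1))
  key <- vapply(syl2s[keep], paste, character(1), collapse = " ")
  tibble::tibble(syl2 = key, frequency = cohort$frequency[keep]) |>
    dplyr::group_by(.data$syl2) |>
    dplyr::summarise(probability = sum(.data$frequency) / denom,
                     .groups = "drop")
}

#' Syllable surprisal
#'
#' Negative log of the conditional syllable probability. A zero probability
#' yields `Inf` rather than an error.
#'
#' @inheritParams conditional_syllable_probability
#' @param base Logarithm base; natural log by default, use `2` for bits.
#' @return Non-negative value (possibly `Inf`).
#' @export
syllable_surprisal <- function(lexicon, syl1, syl2, base = exp(1)) {
  p <- conditional_syllable_probability(lexicon, syl1, syl2)
  if (p == 0) return(Inf)
  -log(p, base = base)
}

#' Predictive entropy over second-syllable continuations
#'
#' Shannon entropy `-sum p log p` of the conditional distribution over
#' attested continuations of `syl1`. Zero exactly when a single continuation
#' carries all the probability.
#'
#' @inheritParams syllable_surprisal
#' @return Non-negative entropy in the chosen base.
#' @export
syllable_entropy <- function(lexicon, syl1, base = exp(1)) {
  p <- syllable_continuations(lexicon, syl1)$probability
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log(p, base = base))
}

#' Words whose transcription starts with the heard segments
#'
#' Position-for-position prefix match over the full transcription, boundary
#' tokens included; this is the matching rule the incremental simulator uses.
#' The empty prefix matches every word; an empty result (no word is
#' consistent with the input) is the pseudoword case and is not an error.
#'
#' @param lexicon A `cohort_lexicon`.
#' @param heard_segments Heard segments (may include boundary tokens);
#'   character vector or space-separated string. May be empty.
#' @return The matching rows of `lexicon`.
#' @export
prefix_cohort <- function(lexicon, heard_segments) {
  heard <- parse_segments(heard_segments)
  if (length(heard) == 0) return(lexicon)
  check_known_segments(lexicon, heard, "heard_segments")
  n <- length(heard)
  hit <- vapply(lexicon$segments, function(s) {
    length(s) >= n && identical(s[seq_len(n)], heard)
  }, logical(1))
  lexicon[hit, ]
}
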